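#' Optimizer configuration for RBMO / IRBMO
#'
#' Bundles the run parameters of the red-billed blue magpie optimizer and its
#' improved variant: population size, problem dimension, box bounds, iteration
#' budget, the two branch-switch probabilities and the group-size ranges used
#' by the foraging updates.
#'
#' @param dim problem dimension D.
#' @param pop_size number of search agents N (at least 4: the elite pool keeps
#'   the top three agents plus their mean, so a fourth agent must exist).
#' @param lower,upper box bounds; scalars are recycled over dimensions.
#' @param max_iter iteration budget T.
#' @param behavior_switch probability S in \[0,1\] choosing between the two
#'   update rules inside each IRBMO behavior.
#' @param rbmo_switch probability p in \[0,1\] choosing the small-group versus
#'   large-group rule in the RBMO search and prey behaviors.
#' @param small_group_range integer range the small foraging-group size is
#'   drawn from (default 2..5).
#' @param large_group_min lower end of the large-group size range; the upper
#'   end is always the population size (default 10, truncated to N).
#' @param seed optional integer seed; when set, a run is fully reproducible.
#' @return an object of class \code{rbmo_config}.
#' @export
rbmo_config <- function(dim, pop_size = 30, lower = 0, upper = 1,
                        max_iter = 100, behavior_switch = 0.5,
                        rbmo_switch = 0.5, small_group_range = c(2L, 5L),
                        large_group_min = 10L, seed = NULL) {
  if (!is.numeric(dim) || length(dim) != 1L || dim < 1)
    stop("'dim' must be a positive integer")
  dim <- as.integer(dim)
  if (!is.numeric(pop_size) || length(pop_size) != 1L || pop_size < 4)
    stop("'pop_size' must be an integer >= 4 (elite pool needs top-3 plus at least one other agent)")
  pop_size <- as.integer(pop_size)
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(lower > upper)) stop("'lower' must be <= 'upper' in every dimension")
  if (max_iter < 1) stop("'max_iter' must be a positive integer")
  if (behavior_switch < 0 || behavior_switch > 1)
    stop("'behavior_switch' must lie in [0, 1]")
  if (rbmo_switch < 0 || rbmo_switch > 1)
    stop("'rbmo_switch' must lie in [0, 1]")
  small_group_range <- as.integer(small_group_range)
  if (length(small_group_range) != 2L || small_group_range[1] < 2L ||
      small_group_range[1] > small_group_range[2])
    stop("'small_group_range' must be an increasing integer pair starting at >= 2")
  structure(list(pop_size = pop_size, dim = dim, lower = lower, upper = upper,
                 max_iter = as.integer(max_iter),
                 behavior_switch = behavior_switch,
                 rbmo_switch = rbmo_switch,
                 small_group_range = small_group_range,
                 large_group_min = as.integer(large_group_min),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "rbmo_config")
}

#' Conditioning factor schedule
#'
#' The step-size schedule \eqn{CF = (1 - t/T)^{2t/T}} used by the prey and
#' compensation updates: equal to 1 at the first iteration, strictly
#' decreasing, and 0 at the final iteration, so late moves contract towards
#' their anchors.
#'
#' @param t current iteration, 0 <= t <= T.
#' @param T_max iteration budget T > 0.
#' @return a value in \[0, 1\].
#' @export
cf_factor <- function(t, T_max) {
  if (T_max <= 0) stop("'T_max' must be positive")
  if (any(t < 0) || any(t > T_max)) stop("'t' must lie in [0, T_max]")
  u <- t / T_max
  (1 - u)^(2 * u)
}

# Mantegna scale sigma_u for a given stability exponent beta
levy_sigma <- function(beta) {
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Heavy-tailed Lévy-flight step
#'
#' Draws a Lévy-stable step by Mantegna's two-Gaussian construction:
#' \eqn{u / |v|^{1/\beta}} with \eqn{u \sim N(0, \sigma_u^2)},
#' \eqn{v \sim N(0, 1)}. Heavy tails let the collaborative-hunt update make
#' occasional long jumps that escape local optima.
#'
#' @param n number of draws.
#' @param beta stability exponent in (1, 2\]; default 1.5.
#' @return numeric vector of n steps.
#' @export
levy_step <- function(n = 1L, beta = 1.5) {
  if (beta <= 1 || beta > 2) stop("'beta' must lie in (1, 2]")
  u <- stats::rnorm(n, sd = levy_sigma(beta))
  v <- stats::rnorm(n)
  u / abs(v)^(1 / beta)
}

# clamp a position back into the box (boundary correction rule)
clamp <- function(x, lower, upper) pmin(pmax(x, lower), upper)

#' Greedy memory selection
#'
#' Storage behavior: keep whichever of the incumbent and the candidate has
#' the lower fitness (minimization); exact ties retain the incumbent, so the
#' best-so-far trajectory is monotone non-increasing.
#'
#' @param position_old,fit_old incumbent position and fitness.
#' @param position_new,fit_new candidate position and fitness.
#' @return list with elements \code{position}, \code{fitness},
#'   \code{accepted} (TRUE when the candidate replaced the incumbent).
#' @export
greedy_select <- function(position_old, fit_old, position_new, fit_new) {
  if (!is.finite(fit_old) || !is.finite(fit_new))
    stop("greedy_select: fitness values must be finite")
  if (fit_new < fit_old)
    list(position = position_new, fitness = fit_new, accepted = TRUE)
  else
    list(position = position_old, fitness = fit_old, accepted = FALSE)
}

# Elite pool: the 3 lowest-fitness rows of X plus their mean (4 x D matrix)
elite_pool <- function(X, fitness) {
  top <- order(fitness)[1:3]
  rbind(X[top, , drop = FALSE], colMeans(X[top, , drop = FALSE]))
}

# --- individual update rules; draws are passed in so the algebra is testable ---

# small/large-group foraging move: X_i + rand * (group mean - X_rs)
rbmo_search_step <- function(x_i, group_mean, x_rs, rand) {
  x_i + rand * (group_mean - x_rs)
}

# prey move anchored at the food (incumbent best): X_food + CF*rand*(mean - X_rs)
rbmo_prey_step <- function(x_food, group_mean, x_rs, rand, cf) {
  x_food + cf * rand * (group_mean - x_rs)
}

# elite search, mean-guided branch: X1 + rand * (X_eq - X_R1)
elite_mean_step <- function(x_best, x_eq, x_r1, rand) {
  x_best + rand * (x_eq - x_r1)
}

# elite search, Brownian branch: RS_draw + rb * rand * (X_best - X_R1)
elite_brownian_step <- function(rs_draw, rb, rand, x_best, x_r1) {
  rs_draw + rb * rand * (x_best - x_r1)
}

# collaborative hunt, Cauchy encirclement: X_best + cv * (X_eq - X_i)
hunt_cauchy_step <- function(x_best, cv, x_eq, x_i) {
  x_best + cv * (x_eq - x_i)
}

# collaborative hunt, Levy re-encirclement: (RS - X_best)*levy + rand*RS*L
hunt_levy_step <- function(rs_draw, x_best, levy, rand, L) {
  (rs_draw - x_best) * levy + rand * rs_draw * L
}

# memory compensation, abundant-food branch: X_i + CF*(RS + rand*(ub-lb))*E
compensation_elite_step <- function(x_i, cf, rs_draw, rand, lower, upper, E) {
  x_i + cf * (rs_draw + rand * (upper - lower)) * E
}

# memory compensation, reserve branch: X_i + (A*(1-rand)+rand)*(X_idx1 - X_idx2)
compensation_reserve_step <- function(x_i, A, rand, x_idx1, x_idx2) {
  x_i + (A * (1 - rand) + rand) * (x_idx1 - x_idx2)
}

# draw a foraging group: small (n in small_group_range) with prob p, else
# large (m in [large_group_min, N]); members without replacement, the
# reference agent X_rs from the whole population
draw_group <- function(config) {
  N <- config$pop_size
  if (stats::runif(1) < config$rbmo_switch) {
    lo <- config$small_group_range[1]; hi <- min(config$small_group_range[2], N)
    size <- if (lo >= hi) lo else sample(lo:hi, 1L)
  } else {
    lo <- min(config$large_group_min, N)
    size <- if (lo >= N) N else sample(lo:N, 1L)
  }
  list(members = sample.int(N, size), rs = sample.int(N, 1L))
}

#' Run the RBMO or IRBMO optimizer
#'
#' Minimizes an objective over the box \code{[lower, upper]^D}. RBMO iterates
#' group foraging (search), food-anchored prey moves, and greedy storage;
#' IRBMO replaces these with elite search (mean-guided or Brownian), a
#' collaborative hunt (Cauchy encirclement or Lévy re-encirclement), greedy
#' memory storage, and a food-abundance compensation move with a second
#' greedy acceptance. Every candidate is clamped to the box before
#' evaluation, and greedy selection guarantees a monotone non-increasing
#' best-fitness curve.
#'
#' @param objective function of a position vector returning a finite scalar
#'   to minimize. It may optionally accept a second argument, the index of
#'   the agent being evaluated (used by stateful binary wrappers).
#' @param config an \code{\link{rbmo_config}}.
#' @param variant \code{"irbmo"} (default) or \code{"rbmo"}.
#' @return an object of class \code{rbmo_run}: best position, best fitness,
#'   the per-iteration best-fitness curve (length \code{max_iter + 1},
#'   starting at the post-initialization best), evaluation count, variant
#'   and config.
#' @examples
#' sphere <- function(x) sum(x^2)
#' cfg <- rbmo_config(dim = 5, pop_size = 20, lower = -5, upper = 5,
#'                    max_iter = 50, seed = 1)
#' run <- run_optimizer(sphere, cfg, variant = "irbmo")
#' run$best_fitness
#' @export
run_optimizer <- function(objective, config, variant = c("irbmo", "rbmo")) {
  variant <- match.arg(variant)
  stopifnot(inherits(config, "rbmo_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  N <- config$pop_size; D <- config$dim; T_max <- config$max_iter
  lb <- config$lower; ub <- config$upper
  takes_agent <- length(formals(objective)) >= 2L
  n_evals <- 0L
  eval_fn <- function(x, i) {
    n_evals <<- n_evals + 1L
    f <- if (takes_agent) objective(x, i) else objective(x)
    if (!is.numeric(f) || length(f) != 1L || !is.finite(f))
      stop("objective returned a non-finite or non-scalar value at agent ", i)
    f
  }

  X <- matrix(stats::runif(N * D), N, D)
  X <- sweep(sweep(X, 2, ub - lb, `*`), 2, lb, `+`)
  fitness <- vapply(seq_len(N), function(i) eval_fn(X[i, ], i), numeric(1))
  best_i <- which.min(fitness)
  best_pos <- X[best_i, ]; best_fit <- fitness[best_i]
  curve <- numeric(T_max + 1L); curve[1L] <- best_fit

  S <- config$behavior_switch
  for (t in seq_len(T_max)) {
    cf <- cf_factor(t, T_max)
    A <- 1 - t / T_max  # food abundance: elite-led early, reserve-led late
    for (i in seq_len(N)) {
      if (variant == "irbmo") {
        pool <- elite_pool(X, fitness)
        x_eq <- pool[4L, ]
        r1 <- sample.int(N, 1L)
        y <- if (stats::runif(1) < S)
          elite_mean_step(best_pos, x_eq, X[r1, ], stats::runif(1))
        else
          elite_brownian_step(pool[sample.int(4L, 1L), ], stats::rnorm(D),
                              stats::runif(1), best_pos, X[r1, ])
        y <- clamp(y, lb, ub)
        z <- if (stats::runif(1) < S)
          hunt_cauchy_step(best_pos, stats::rcauchy(1), x_eq, y)
        else
          hunt_levy_step(pool[sample.int(4L, 1L), ], best_pos,
                         levy_step(1L), stats::runif(1), stats::runif(1))
        z <- clamp(z, lb, ub)
        sel <- greedy_select(X[i, ], fitness[i], z, eval_fn(z, i))
        X[i, ] <- sel$position; fitness[i] <- sel$fitness

        pool <- elite_pool(X, fitness)
        w <- if (A > stats::runif(1))
          compensation_elite_step(X[i, ], cf, pool[sample.int(4L, 1L), ],
                                  stats::runif(1), lb, ub, stats::rnorm(1))
        else
          compensation_reserve_step(X[i, ], A, stats::runif(1),
                                    X[sample.int(N, 1L), ],
                                    X[sample.int(N, 1L), ])
        w <- clamp(w, lb, ub)
        sel <- greedy_select(X[i, ], fitness[i], w, eval_fn(w, i))
        X[i, ] <- sel$position; fitness[i] <- sel$fitness
      } else {
        g <- draw_group(config)
        y <- rbmo_search_step(X[i, ], colMeans(X[g$members, , drop = FALSE]),
                              X[g$rs, ], stats::runif(1))
        y <- clamp(y, lb, ub)
        sel <- greedy_select(X[i, ], fitness[i], y, eval_fn(y, i))
        X[i, ] <- sel$position; fitness[i] <- sel$fitness

        g <- draw_group(config)
        z <- rbmo_prey_step(best_pos, colMeans(X[g$members, , drop = FALSE]),
                            X[g$rs, ], stats::runif(1), cf)
        z <- clamp(z, lb, ub)
        sel <- greedy_select(X[i, ], fitness[i], z, eval_fn(z, i))
        X[i, ] <- sel$position; fitness[i] <- sel$fitness
      }
      if (fitness[i] < best_fit) {
        best_fit <- fitness[i]; best_pos <- X[i, ]
      }
    }
    curve[t + 1L] <- best_fit
  }

  structure(list(best_position = best_pos, best_fitness = best_fit,
                 curve = curve, n_evals = n_evals, variant = variant,
                 config = config),
            class = "rbmo_run")
}

#' @export
print.rbmo_run <- function(x, ...) {
  cat(sprintf("%s run: D = %d, N = %d, T = %d\n", toupper(x$variant),
              x$config$dim, x$config$pop_size, x$config$max_iter))
  cat(sprintf("  best fitness: %.6g (%d objective evaluations)\n",
              x$best_fitness, x$n_evals))
  invisible(x)
}
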