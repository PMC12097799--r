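test_that("configuration validation rejects degenerate settings", {
  expect_error(rbmo_config(dim = 5, pop_size = 3), "pop_size")
  expect_error(rbmo_config(dim = 2, lower = 1, upper = 0), "lower")
  expect_error(rbmo_config(dim = 2, behavior_switch = 1.5), "behavior_switch")
  expect_error(rbmo_config(dim = 2, rbmo_switch = -0.1), "rbmo_switch")
  expect_error(rbmo_config(dim = 0), "dim")
  expect_s3_class(rbmo_config(dim = 5), "rbmo_config")
})

test_that("conditioning factor has the right endpoints and decays strictly", {
  expect_identical(cf_factor(0, 100), 1)
  expect_identical(cf_factor(100, 100), 0)
  expect_equal(cf_factor(50, 100), 0.5)
  ts <- 1:99
  expect_true(all(diff(cf_factor(ts, 100)) < 0))
  expect_true(all(cf_factor(0:100, 100) >= 0 & cf_factor(0:100, 100) <= 1))
  expect_error(cf_factor(5, 0), "positive")
  expect_error(cf_factor(11, 10), "t")
})

test_that("Levy step has the Mantegna scale, determinism and heavy tails", {
  expect_equal(rbmofs:::levy_sigma(1.5), 0.696575, tolerance = 1e-4)
  expect_error(levy_step(1, beta = 1), "beta")
  expect_error(levy_step(1, beta = 2.5), "beta")
  set.seed(11); a <- levy_step(50)
  set.seed(11); b <- levy_step(50)
  expect_identical(a, b)
  set.seed(12)
  draws <- levy_step(1e5)
  tail_emp <- mean(abs(draws) > 10)
  # a Gaussian of the same scale (sigma_u ~ 0.70) puts essentially no mass
  # beyond 10; the Levy-stable tail keeps a visible fraction there
  tail_gauss <- 2 * stats::pnorm(10, sd = rbmofs:::levy_sigma(1.5),
                                 lower.tail = FALSE)
  expect_lt(tail_gauss, 1e-12)
  expect_gt(tail_emp, 1e-3)
})

test_that("update rules collapse to their fixed points when draws vanish", {
  # group foraging
  xs <- c(0.4, 0.6)
  expect_equal(rbmofs:::rbmo_search_step(xs, xs, xs, 0.7), xs)   # collapsed swarm
  expect_equal(rbmofs:::rbmo_search_step(c(1, 2), c(9, 9), c(5, 5), 0), c(1, 2))
  got <- rbmofs:::clamp(
    rbmofs:::rbmo_search_step(c(0, 0), c(0.5, 0.5), c(1, 1), 1), 0, 1)
  expect_equal(got, c(0, 0))  # (-0.5,-0.5) clamped up to the lower bound
  # prey anchored at the food
  food <- c(0.3, 0.9)
  expect_equal(rbmofs:::rbmo_prey_step(food, c(1, 1), c(0, 0), 0.8, cf = 0), food)
  expect_equal(rbmofs:::rbmo_prey_step(food, c(1, 1), c(0, 0), 0, cf = 0.5), food)
  expect_equal(rbmofs:::rbmo_prey_step(c(1, 1), c(0, 0), c(0.5, 0.5), 1, 0.5),
               c(0.75, 0.75))
  # elite search
  x1 <- c(1, 0)
  expect_equal(rbmofs:::elite_mean_step(x1, c(0.5, 0.5), c(0.5, 0.5), 0.9), x1)
  expect_equal(rbmofs:::clamp(
    rbmofs:::elite_mean_step(x1, c(0.5, 0.5), c(0, 1), 0.5), 0, 1), c(1, 0))
  rs <- c(0.2, 0.8)
  expect_equal(rbmofs:::elite_brownian_step(rs, 0, 0.5, c(1, 1), c(0, 0)), rs)
  # collaborative hunt
  best <- c(0.6, 0.4)
  expect_equal(rbmofs:::hunt_cauchy_step(best, 0, c(1, 1), c(0, 0)), best)
  expect_equal(rbmofs:::hunt_cauchy_step(best, 5, c(0.3, 0.3), c(0.3, 0.3)), best)
  expect_equal(rbmofs:::clamp(
    rbmofs:::hunt_levy_step(best, best, 2.3, 0, 0.7), 0.1, 1), c(0.1, 0.1))
  # memory compensation
  xi <- c(0.5, 0.5)
  expect_equal(rbmofs:::compensation_reserve_step(xi, 0.4, 0.3,
                                                  c(0.9, 0.1), c(0.9, 0.1)), xi)
  expect_equal(rbmofs:::compensation_elite_step(xi, 0, rs, 0.5, 0, 1, 1.7), xi)
})

test_that("greedy selection keeps the lower fitness and ties keep the incumbent", {
  a <- c(1, 1); b <- c(2, 2)
  expect_equal(greedy_select(a, 0.5, b, 0.3)$position, b)
  expect_equal(greedy_select(a, 0.3, b, 0.5)$position, a)
  tie <- greedy_select(a, 0.4, b, 0.4)
  expect_equal(tie$position, a)
  expect_false(tie$accepted)
  expect_error(greedy_select(a, NaN, b, 0.1), "finite")
  expect_error(greedy_select(a, 0.1, b, Inf), "finite")
})

test_that("runs are seed-reproducible, stay in bounds and improve monotonically", {
  sphere <- function(x) sum(x^2)
  for (variant in c("irbmo", "rbmo")) {
    cfg <- rbmo_config(dim = 4, pop_size = 8, lower = -2, upper = 3,
                       max_iter = 25, seed = 99)
    lo <- Inf; hi <- -Inf
    watcher <- function(x) {
      lo <<- min(lo, x); hi <<- max(hi, x); sum(x^2)
    }
    r1 <- run_optimizer(watcher, cfg, variant)
    r2 <- run_optimizer(sphere, cfg, variant)
    expect_identical(r1$curve, r2$curve)
    expect_identical(r1$best_position, r2$best_position)
    expect_true(all(diff(r1$curve) <= 0))
    expect_gte(lo, -2); expect_lte(hi, 3)
    expect_length(r1$curve, 26L)
  }
})

test_that("IRBMO reliably minimizes the sphere function", {
  sphere <- function(x) sum(x^2)
  hits <- vapply(1:20, function(s) {
    cfg <- rbmo_config(dim = 5, pop_size = 30, lower = -100, upper = 100,
                       max_iter = 100, seed = s)
    run_optimizer(sphere, cfg, "irbmo")$best_fitness < 1e-3
  }, logical(1))
  expect_gte(sum(hits), 19L)
})
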