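#' Two-sided Wilcoxon rank-sum p-value
#'
#' Compares two independent run samples. Tie-free samples with a combined
#' size of at most 12 use the exact null distribution; larger or tied
#' samples use the normal approximation with tie correction. Two samples
#' whose values are all identical cannot be ranked against each other and
#' return \code{NaN} (the degenerate no-difference marker).
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return two-sided p-value, or \code{NaN} for identical constant samples.
#' @export
wilcoxon_rank_sum <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop("both samples must be non-empty")
  combined <- c(sample_a, sample_b)
  if (length(unique(combined)) == 1L) return(NaN)
  has_ties <- anyDuplicated(combined) > 0L
  if (!has_ties && length(combined) <= 12L)
    stats::wilcox.test(sample_a, sample_b, exact = TRUE)$p.value
  else
    suppressWarnings(stats::wilcox.test(sample_a, sample_b, exact = FALSE,
                                        correct = TRUE)$p.value)
}

#' Win/tie/loss bookkeeping across problems
#'
#' For each problem, runs the rank-sum test between the reference and the
#' competitor samples: a tie when the test is not significant at
#' \code{alpha} (or degenerate), otherwise a win or loss for the reference
#' decided by comparing sample means in the stated direction.
#'
#' @param reference_runs,competitor_runs lists of per-problem numeric run
#'   samples (same length and order).
#' @param alpha significance level (default 0.05).
#' @param direction \code{"min"} when lower values are better (fitness),
#'   \code{"max"} when higher values are better (accuracy).
#' @return list with counts \code{win}, \code{tie}, \code{loss} and a
#'   per-problem data frame \code{decisions} (p-value and outcome).
#' @export
win_tie_loss <- function(reference_runs, competitor_runs, alpha = 0.05,
                         direction = c("min", "max")) {
  direction <- match.arg(direction)
  if (length(reference_runs) != length(competitor_runs))
    stop("run lists must have the same length")
  outcome <- character(length(reference_runs))
  pvals <- numeric(length(reference_runs))
  for (i in seq_along(reference_runs)) {
    p <- wilcoxon_rank_sum(reference_runs[[i]], competitor_runs[[i]])
    pvals[i] <- p
    outcome[i] <- if (is.nan(p) || p >= alpha) "tie" else {
      better <- mean(reference_runs[[i]]) < mean(competitor_runs[[i]])
      if (direction == "max") better <- !better
      if (better) "win" else "loss"
    }
  }
  nms <- names(reference_runs)
  if (is.null(nms)) nms <- paste0("problem", seq_along(reference_runs))
  list(win = sum(outcome == "win"), tie = sum(outcome == "tie"),
       loss = sum(outcome == "loss"),
       decisions = data.frame(problem = nms, p_value = pvals,
                              outcome = outcome))
}

#' Friedman mean-rank comparison
#'
#' Ranks the algorithms within every problem (rank 1 = best, mid-ranks for
#' ties) and averages the ranks over problems; the induced ordering is the
#' headline comparison. The Friedman chi-square statistic and its p-value
#' are reported alongside when at least two problems are available.
#'
#' @param table numeric matrix or data frame, rows = problems, columns =
#'   algorithms.
#' @param direction \code{"min"} when lower metric values are better
#'   (default), \code{"max"} otherwise.
#' @return an object of class \code{friedman_ranks}: per-algorithm
#'   \code{mean_ranks}, the within-problem \code{ranks} matrix, the overall
#'   \code{ordering} (best first), and \code{statistic} / \code{p_value}
#'   (NA with a single problem).
#' @export
friedman_mean_ranks <- function(table, direction = c("min", "max")) {
  direction <- match.arg(direction)
  table <- as.matrix(table)
  if (ncol(table) < 2) stop("need at least 2 algorithms to rank")
  if (nrow(table) < 1) stop("need at least 1 problem")
  vals <- if (direction == "max") -table else table
  ranks <- t(apply(vals, 1, rank))
  mean_ranks <- colMeans(ranks)
  if (nrow(table) >= 2) {
    ft <- stats::friedman.test(vals)
    statistic <- unname(ft$statistic); p_value <- ft$p.value
  } else {
    statistic <- NA_real_; p_value <- NA_real_
  }
  nms <- colnames(table)
  if (is.null(nms)) nms <- paste0("alg", seq_len(ncol(table)))
  names(mean_ranks) <- nms
  structure(list(mean_ranks = mean_ranks, ranks = ranks,
                 ordering = nms[order(mean_ranks)],
                 statistic = statistic, p_value = p_value),
            class = "friedman_ranks")
}

#' @export
print.friedman_ranks <- function(x, ...) {
  cat("Friedman mean ranks (1 = best):\n")
  print(round(x$mean_ranks, 3))
  cat("ordering:", paste(x$ordering, collapse = " > "), "\n")
  if (!is.na(x$p_value))
    cat(sprintf("chi-square = %.4g, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Relative improvement of one algorithm over a baseline
#'
#' Per problem, \code{100 * (baseline - improved) / baseline} on a
#' lower-is-better metric, plus the arithmetic mean across problems.
#' A zero baseline yields \code{NA} for that problem and is excluded from
#' the overall mean.
#'
#' @param baseline,improved numeric vectors of per-problem means (same
#'   length; names of \code{baseline} are kept as problem names).
#' @return an object of class \code{improvement_rate}: data frame
#'   \code{per_problem} and scalar \code{overall} (mean percentage).
#' @export
improvement_rate <- function(baseline, improved) {
  if (length(baseline) != length(improved))
    stop("'baseline' and 'improved' must have the same length")
  pct <- ifelse(baseline == 0, NA_real_,
                100 * (baseline - improved) / baseline)
  nms <- names(baseline)
  if (is.null(nms)) nms <- paste0("problem", seq_along(baseline))
  structure(list(per_problem = data.frame(problem = nms,
                                          baseline = as.numeric(baseline),
                                          improved = as.numeric(improved),
                                          improvement_pct = as.numeric(pct)),
                 overall = mean(pct, na.rm = TRUE)),
            class = "improvement_rate")
}

#' @export
print.improvement_rate <- function(x, ...) {
  print(x$per_problem, digits = 6, row.names = FALSE)
  cat(sprintf("overall mean improvement: %.2f%%\n", x$overall))
  invisible(x)
}
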