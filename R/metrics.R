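#' One-vs-rest confusion counts
#'
#' Tabulates TP, FP, TN, FN for a chosen positive class.
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param positive the class counted as positive.
#' @return list with integer elements \code{TP}, \code{FP}, \code{TN},
#'   \code{FN}.
#' @export
confusion_counts <- function(true_labels, predicted_labels, positive) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  tp <- sum(true_labels == positive & predicted_labels == positive)
  fp <- sum(true_labels != positive & predicted_labels == positive)
  fn <- sum(true_labels == positive & predicted_labels != positive)
  tn <- sum(true_labels != positive & predicted_labels != positive)
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Confusion-matrix rate metrics
#'
#' Accuracy (TP+TN)/(TP+TN+FP+FN), sensitivity TP/(TP+FN), specificity
#' TN/(FP+TN), precision TP/(TP+FP), recall (= sensitivity) and
#' F-score 2*Pre*Rec/(Pre+Rec). A 0/0 ratio is undefined and reported as
#' \code{NA}; averaging utilities exclude such values.
#'
#' @param counts a list with \code{TP}, \code{FP}, \code{TN}, \code{FN}.
#' @return named numeric vector of the six metrics.
#' @export
rate_metrics <- function(counts) {
  total <- counts$TP + counts$TN + counts$FP + counts$FN
  if (total == 0) stop("rate_metrics: no observations")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  acc <- (counts$TP + counts$TN) / total
  sens <- ratio(counts$TP, counts$TP + counts$FN)
  spec <- ratio(counts$TN, counts$FP + counts$TN)
  prec <- ratio(counts$TP, counts$TP + counts$FP)
  f <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_
       else 2 * prec * sens / (prec + sens)
  c(accuracy = acc, sensitivity = sens, specificity = spec,
    precision = prec, recall = sens, f_score = f)
}

# default positive class: the minority class of the truth vector
minority_class <- function(labels) {
  tab <- table(labels)
  names(tab)[which.min(tab)]
}

#' Classification metrics for binary or multi-class predictions
#'
#' Binary problems report the one-vs-rest metrics of the positive class
#' (minority class by default). Problems with three or more classes report
#' the macro average of the per-class one-vs-rest sensitivity, specificity,
#' precision and F-score; accuracy is always the plain fraction correct.
#' Undefined (0/0) per-class values are excluded from the macro average.
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @param positive positive class for the binary case; ignored with three
#'   or more classes.
#' @return list with \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, \code{precision}, \code{f_score} and the
#'   \code{positive} class used (\code{NA} for macro averages).
#' @export
multiclass_metrics <- function(true_labels, predicted_labels,
                               positive = NULL) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  true_labels <- factor(true_labels)
  classes <- levels(true_labels)
  if (length(classes) < 2) stop("need at least 2 classes")
  acc <- mean(as.character(true_labels) == as.character(predicted_labels))
  if (length(classes) == 2) {
    if (is.null(positive)) positive <- minority_class(true_labels)
    m <- rate_metrics(confusion_counts(true_labels, predicted_labels, positive))
    return(list(accuracy = acc, sensitivity = unname(m["sensitivity"]),
                specificity = unname(m["specificity"]),
                precision = unname(m["precision"]),
                f_score = unname(m["f_score"]), positive = positive))
  }
  per <- vapply(classes, function(cl)
    rate_metrics(confusion_counts(true_labels, predicted_labels, cl)),
    numeric(6))
  macro <- rowMeans(per, na.rm = TRUE)
  list(accuracy = acc, sensitivity = unname(macro["sensitivity"]),
       specificity = unname(macro["specificity"]),
       precision = unname(macro["precision"]),
       f_score = unname(macro["f_score"]), positive = NA_character_)
}

# one summary row from a fitted model
run_record <- function(fit) {
  data.frame(seed = if (is.null(fit$seed)) NA_integer_ else fit$seed,
             fitness = fit$best_fitness,
             accuracy = fit$metrics$accuracy,
             sensitivity = fit$metrics$sensitivity,
             specificity = fit$metrics$specificity,
             f_score = fit$metrics$f_score,
             n_selected = fit$n_selected)
}

#' Aggregate independent feature-selection runs
#'
#' Means and sample (n-1) standard deviations of every metric over a set of
#' runs, plus the average selected-feature count both as a raw count and as
#' a fraction of the total feature number. Undefined (\code{NA}) metric
#' values are excluded from their averages.
#'
#' @param records data frame of per-run metrics with columns
#'   \code{fitness}, \code{accuracy}, \code{sensitivity},
#'   \code{specificity}, \code{f_score}, \code{n_selected} (one row per
#'   run), or a list of \code{rbmofs_fit} objects.
#' @param n_features total number of features M of the dataset.
#' @return an object of class \code{study_summary}: a data frame of
#'   \code{mean} and \code{sd} per metric, with \code{n_runs} and
#'   \code{n_features} attached.
#' @export
aggregate_runs <- function(records, n_features) {
  if (is.list(records) && !is.data.frame(records) &&
      all(vapply(records, inherits, logical(1), "rbmofs_fit")))
    records <- do.call(rbind, lapply(records, run_record))
  if (nrow(records) == 0) stop("no run records to aggregate")
  cols <- c("fitness", "accuracy", "sensitivity", "specificity", "f_score",
            "n_selected")
  mn <- vapply(cols, function(c) mean(records[[c]], na.rm = TRUE), numeric(1))
  sdv <- vapply(cols, function(c) {
    v <- records[[c]][!is.na(records[[c]])]
    if (length(v) < 2) 0 else stats::sd(v)
  }, numeric(1))
  out <- data.frame(metric = c(cols, "feat_ratio"),
                    mean = c(mn, mn["n_selected"] / n_features),
                    sd = c(sdv, sdv["n_selected"] / n_features))
  rownames(out) <- NULL
  structure(out, class = c("study_summary", "data.frame"),
            n_runs = nrow(records), n_features = n_features)
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("summary over %d runs (%d features):\n", attr(x, "n_runs"),
              attr(x, "n_features")))
  print.data.frame(x, digits = 5, row.names = FALSE)
  invisible(x)
}
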