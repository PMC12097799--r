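#' Wrapper-fitness configuration
#'
#' Parameters of the wrapper objective: the weight on classification error
#' versus subset size, the number of KNN neighbours, the train fraction of
#' the stratified split, and what to do with an empty candidate mask.
#'
#' @param alpha weight on classification error in \[0, 1\] (default 0.99;
#'   the remaining 0.01 weights the selected-feature ratio, giving a mild
#'   parsimony pressure).
#' @param k_neighbors number of neighbours for the KNN wrapper (default 5).
#' @param train_fraction fraction of each class used for training
#'   (default 0.75).
#' @param empty_mask_policy \code{"penalty"} assigns fitness 1 to an empty
#'   mask; \code{"repair"} sets one uniformly chosen bit before evaluating.
#' @return an object of class \code{fitness_config}.
#' @export
fitness_config <- function(alpha = 0.99, k_neighbors = 5L,
                           train_fraction = 0.75,
                           empty_mask_policy = c("penalty", "repair")) {
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  if (k_neighbors < 1) stop("'k_neighbors' must be >= 1")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("'train_fraction' must lie in (0, 1)")
  structure(list(alpha = alpha, k_neighbors = as.integer(k_neighbors),
                 train_fraction = train_fraction,
                 empty_mask_policy = match.arg(empty_mask_policy)),
            class = "fitness_config")
}

# subset a labeled dataset by row index, keeping factor levels
dataset_subset <- function(data, idx) {
  list(features = data$features[idx, , drop = FALSE],
       labels = factor(data$labels[idx], levels = levels(data$labels)))
}

#' Stratified train/test split
#'
#' Splits a dataset so that each class contributes
#' \code{round(train_fraction * class size)} samples to the training set
#' (kept off the boundary so both sides retain every class).
#'
#' @param data a \code{\link{labeled_dataset}}.
#' @param train_fraction fraction of each class used for training.
#' @return list with \code{train} and \code{test} (each a list of
#'   \code{features} and \code{labels}) and the index vectors
#'   \code{train_idx}, \code{test_idx}.
#' @export
split_dataset <- function(data, train_fraction = 0.75) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (any(table(data$labels) < 2))
    stop("every class needs at least 2 samples to split")
  # largest-remainder allocation: per-class counts stay within one sample of
  # train_fraction * class size while the total matches round(fraction * n)
  sizes <- table(data$labels)
  target <- train_fraction * as.numeric(sizes)
  base <- floor(target)
  extra <- round(train_fraction * length(data$labels)) - sum(base)
  if (extra > 0) {
    give <- order(target - base, decreasing = TRUE)[seq_len(extra)]
    base[give] <- base[give] + 1L
  }
  base <- pmin(pmax(base, 1L), as.numeric(sizes) - 1L)
  train_idx <- integer(0)
  for (ci in seq_along(sizes)) {
    idx <- which(data$labels == names(sizes)[ci])
    train_idx <- c(train_idx, sample(idx, base[ci]))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(data$labels), train_idx)
  list(train = dataset_subset(data, train_idx),
       test = dataset_subset(data, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

# min-max scaling parameters fitted on the training features only
fit_scaler <- function(train_features) {
  mins <- apply(train_features, 2, min)
  maxs <- apply(train_features, 2, max)
  den <- maxs - mins
  den[den == 0] <- 1  # constant column scales to 0
  list(mins = mins, den = den)
}

apply_scaler <- function(features, scaler) {
  sweep(sweep(features, 2, scaler$mins), 2, scaler$den, "/")
}

#' KNN prediction over a feature subset
#'
#' Predicts test labels by majority vote among the k nearest training
#' samples (Euclidean distance over the selected features, min-max scaled
#' to \[0,1\] using training-set ranges only). Deterministic tie rules:
#' equal distances are broken by the lower training-row index, and a tied
#' vote goes to the tied class with the smallest aggregate neighbour
#' distance.
#'
#' @param train,test lists with \code{features} (numeric matrix) and, for
#'   \code{train}, \code{labels} (factor); as produced by
#'   \code{\link{split_dataset}}.
#' @param mask 0/1 or logical vector selecting features; \code{NULL} selects
#'   all.
#' @param k number of neighbours.
#' @return factor of predicted labels with the training levels.
#' @export
knn_predict <- function(train, test, mask = NULL, k = 5L) {
  if (is.null(mask)) mask <- rep(1L, ncol(train$features))
  sel <- which(as.logical(mask))
  if (length(sel) == 0) stop("knn_predict: the feature mask is empty")
  scaler <- fit_scaler(train$features)
  A <- apply_scaler(train$features, scaler)[, sel, drop = FALSE]
  B <- apply_scaler(test$features, scaler)[, sel, drop = FALSE]
  knn_predict_scaled(A, train$labels, B, k)
}

# core KNN on already-scaled, already-masked matrices
knn_predict_scaled <- function(A, train_labels, B, k) {
  k <- min(k, nrow(A))
  d2 <- outer(rowSums(B^2), rowSums(A^2), "+") - 2 * tcrossprod(B, A)
  d2[d2 < 0] <- 0
  lab_int <- as.integer(train_labels)
  n_lev <- nlevels(train_labels)
  out <- integer(nrow(B))
  for (r in seq_len(nrow(B))) {
    ord <- order(d2[r, ], seq_len(ncol(d2)))[seq_len(k)]
    votes <- tabulate(lab_int[ord], nbins = n_lev)
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      # vote tie: tied class with smallest total neighbour distance wins
      agg <- vapply(top, function(cl)
        sum(sqrt(d2[r, ord[lab_int[ord] == cl]])), numeric(1))
      top <- top[which.min(agg)]
    }
    out[r] <- top[1L]
  }
  factor(levels(train_labels)[out], levels = levels(train_labels))
}

#' Wrapper fitness of a feature mask
#'
#' Scores a mask by
#' \code{alpha * (1 - test accuracy) + (1 - alpha) * n_selected / n_features},
#' using a KNN classifier trained on the training split. An empty mask is
#' handled by the configured policy: fitness 1 (penalty) or a single random
#' bit set before evaluation (repair).
#'
#' @param mask 0/1 or logical feature mask.
#' @param train,test split halves as produced by \code{\link{split_dataset}}.
#' @param config a \code{\link{fitness_config}}.
#' @return the scalar fitness (lower is better), with the evaluated
#'   \code{mask} and test \code{accuracy} attached as attributes.
#' @export
evaluate_mask <- function(mask, train, test, config = fitness_config()) {
  mask <- as.integer(as.logical(mask))
  if (sum(mask) == 0) {
    if (config$empty_mask_policy == "penalty")
      return(structure(1, mask = mask, accuracy = NA_real_))
    mask[sample.int(length(mask), 1L)] <- 1L
  }
  pred <- knn_predict(train, test, mask, config$k_neighbors)
  acc <- mean(pred == test$labels)
  fit <- config$alpha * (1 - acc) +
    (1 - config$alpha) * sum(mask) / length(mask)
  structure(fit, mask = mask, accuracy = acc)
}

#' Select features with the RBMO / IRBMO wrapper
#'
#' Fits a binary wrapper feature-selection model: a swarm of continuous
#' agents explores \code{[0,1]^D}, each position is binarized to a feature
#' mask (fixed threshold or an S-/V-shaped transfer function), and each mask
#' is scored by a KNN classifier on a stratified hold-out split, trading
#' classification error against subset size. The best mask ever evaluated is
#' returned together with its hold-out metrics and the convergence curve.
#'
#' @param x a \code{\link{labeled_dataset}}, or a numeric feature matrix /
#'   data frame (then \code{labels} is required), or a formula
#'   (\code{label ~ .}) with \code{data}.
#' @param labels class labels when \code{x} is a matrix or data frame.
#' @param variant \code{"irbmo"} (default) or \code{"rbmo"}.
#' @param transfer binarization rule: \code{"threshold"} (default),
#'   \code{"s1"}..\code{"s4"}, \code{"v1"}..\code{"v4"}, or a
#'   \code{\link{transfer_spec}}.
#' @param pop_size,max_iter swarm size and iteration budget (defaults 30
#'   and 100, the standard evaluation protocol).
#' @param alpha,k,train_fraction,empty_mask_policy wrapper-fitness settings,
#'   see \code{\link{fitness_config}}.
#' @param seed integer seed making the whole run reproducible (split, swarm
#'   and binarization draws).
#' @param positive positive class for the binary metrics; defaults to the
#'   minority class of the test split.
#' @param ... passed to methods.
#' @return an object of class \code{rbmofs_fit} with \code{print},
#'   \code{summary}, \code{coef}, \code{predict} and \code{plot} methods.
#' @examples
#' d <- generate_synthetic(n_samples = 120, n_informative = 2, n_noise = 6,
#'                         class_sep = 3, seed = 7)
#' fit <- select_features(d, pop_size = 10, max_iter = 15, seed = 7)
#' fit
#' coef(fit)
#' @export
select_features <- function(x, ...) UseMethod("select_features")

#' @rdname select_features
#' @export
select_features.default <- function(x, labels, ...) {
  select_features(labeled_dataset(x, labels), ...)
}

#' @rdname select_features
#' @param data data frame holding the formula variables.
#' @export
select_features.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data)
  labels <- stats::model.response(mf)
  feats <- mf[, -1, drop = FALSE]
  select_features(labeled_dataset(feats, labels), ...)
}

#' @rdname select_features
#' @export
select_features.labeled_dataset <- function(x, variant = c("irbmo", "rbmo"),
                                            transfer = "threshold",
                                            pop_size = 30, max_iter = 100,
                                            alpha = 0.99, k = 5,
                                            train_fraction = 0.75,
                                            empty_mask_policy = "penalty",
                                            seed = NULL, positive = NULL,
                                            ...) {
  variant <- match.arg(variant)
  spec <- as_transfer_spec(transfer)
  fcfg <- fitness_config(alpha = alpha, k_neighbors = k,
                         train_fraction = train_fraction,
                         empty_mask_policy = empty_mask_policy)
  if (!is.null(seed)) set.seed(seed)
  split <- split_dataset(x, train_fraction)
  D <- ncol(x$features)

  # scaling depends only on the training rows, never on a mask: fit once
  scaler <- fit_scaler(split$train$features)
  A_full <- apply_scaler(split$train$features, scaler)
  B_full <- apply_scaler(split$test$features, scaler)
  train_labels <- split$train$labels
  test_labels <- split$test$labels

  cache <- new.env(parent = emptyenv())  # mask -> fitness memo
  score_mask <- function(mask) {
    key <- paste(mask, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    sel <- which(mask == 1L)
    pred <- knn_predict_scaled(A_full[, sel, drop = FALSE], train_labels,
                               B_full[, sel, drop = FALSE], fcfg$k_neighbors)
    acc <- mean(pred == test_labels)
    fit <- fcfg$alpha * (1 - acc) + (1 - fcfg$alpha) * length(sel) / D
    cache[[key]] <- fit
    fit
  }

  # V-shaped transfers flip a persistent per-agent mask; seed it from the
  # threshold rule on first evaluation
  v_masks <- matrix(NA_integer_, pop_size, D)
  best_mask <- NULL
  best_mask_fit <- Inf
  objective <- function(pos, agent) {
    bits <- if (spec$family == "v") {
      cur <- v_masks[agent, ]
      if (anyNA(cur)) cur <- threshold_binarize(pos)
      b <- apply_transfer(pos, spec, current_bits = cur)
      v_masks[agent, ] <<- b
      b
    } else apply_transfer(pos, spec)
    if (sum(bits) == 0L) {
      if (fcfg$empty_mask_policy == "penalty") return(1)
      bits[sample.int(D, 1L)] <- 1L
    }
    f <- score_mask(bits)
    if (f < best_mask_fit) {
      best_mask_fit <<- f
      best_mask <<- bits
    }
    f
  }

  cfg <- rbmo_config(dim = D, pop_size = pop_size, lower = 0, upper = 1,
                     max_iter = max_iter)
  run <- run_optimizer(objective, cfg, variant = variant)

  mask <- best_mask
  names(mask) <- x$feature_names
  sel <- which(mask == 1L)
  pred <- knn_predict_scaled(A_full[, sel, drop = FALSE], train_labels,
                             B_full[, sel, drop = FALSE], fcfg$k_neighbors)
  metrics <- multiclass_metrics(test_labels, pred, positive = positive)

  structure(list(call = match.call(), variant = variant, transfer = spec,
                 mask = mask, selected = x$feature_names[sel],
                 n_selected = length(sel), best_fitness = best_mask_fit,
                 curve = run$curve, n_evals = run$n_evals,
                 metrics = metrics, fitness_config = fcfg, seed = seed,
                 split = list(train_idx = split$train_idx,
                              test_idx = split$test_idx),
                 train = split$train, feature_names = x$feature_names,
                 class_labels = levels(x$labels)),
            class = "rbmofs_fit")
}

#' @export
print.rbmofs_fit <- function(x, ...) {
  tf <- if (x$transfer$family == "threshold") "threshold"
        else paste0(toupper(x$transfer$family), x$transfer$variant)
  cat(sprintf("%s wrapper feature selection (%s binarization)\n",
              toupper(x$variant), tf))
  cat(sprintf("  selected %d of %d features; best fitness %.6f\n",
              x$n_selected, length(x$mask), x$best_fitness))
  cat(sprintf("  hold-out accuracy %.4f\n", x$metrics$accuracy))
  invisible(x)
}

#' @export
summary.rbmofs_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.rbmofs_fit")
}

#' @export
print.summary.rbmofs_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("  selected features:", paste(f$selected, collapse = ", "), "\n")
  m <- f$metrics
  cat(sprintf("  sensitivity %.4f | specificity %.4f | F-score %.4f\n",
              m$sensitivity, m$specificity, m$f_score))
  cat(sprintf("  objective evaluations: %d (k = %d, alpha = %.2f)\n",
              f$n_evals, f$fitness_config$k_neighbors,
              f$fitness_config$alpha))
  invisible(x)
}

#' @export
coef.rbmofs_fit <- function(object, ...) object$mask

#' Predict classes for new samples from a fitted feature-selection model
#'
#' Classifies new rows with the KNN rule over the selected features, using
#' the training split and scaling stored in the fit.
#'
#' @param object an \code{rbmofs_fit}.
#' @param newdata numeric matrix or data frame with the training feature
#'   columns (matched by name when present).
#' @param ... unused.
#' @return factor of predicted class labels.
#' @export
predict.rbmofs_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) &&
      all(object$feature_names %in% colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  if (ncol(newdata) != length(object$mask))
    stop("'newdata' must have the ", length(object$mask),
         " training feature columns")
  knn_predict(object$train, list(features = newdata), object$mask,
              object$fitness_config$k_neighbors)
}

#' Plot the convergence curve of a feature-selection run
#'
#' @param x an \code{rbmofs_fit}.
#' @param ... passed to \code{plot}.
#' @export
plot.rbmofs_fit <- function(x, ...) {
  graphics::plot(seq_along(x$curve) - 1L, x$curve, type = "s",
                 xlab = "iteration", ylab = "best fitness",
                 main = sprintf("%s convergence", toupper(x$variant)), ...)
  invisible(x)
}
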