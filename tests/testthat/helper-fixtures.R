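# fixtures built in code; no files shipped

# tiny deterministic train/test split for KNN checks
toy_split <- function() {
  train <- list(features = matrix(c(0, 0,
                                    0, 1,
                                    1, 1), 3, 2, byrow = TRUE),
                labels = factor(c("A", "A", "B"), levels = c("A", "B")))
  test <- list(features = matrix(c(0.9, 1.0), 1, 2),
               labels = factor("B", levels = c("A", "B")))
  list(train = train, test = test)
}

# a split where every test point coincides with a class-"A" training point,
# so KNN with k = 1 is perfectly accurate for any non-empty mask
separable_split <- function() {
  tr <- matrix(c(0, 0, 0, 0.1, 1, 1, 1, 0.9), 4, 2, byrow = TRUE)
  te <- tr
  list(train = list(features = tr,
                    labels = factor(c("A", "A", "B", "B"))),
       test = list(features = te,
                   labels = factor(c("A", "A", "B", "B"))))
}

# naive KNN with the package's tie rules, written as a double loop:
# the independent oracle for knn_predict
knn_oracle <- function(train, test, mask, k) {
  sel <- which(as.logical(mask))
  mins <- apply(train$features, 2, min)
  maxs <- apply(train$features, 2, max)
  den <- maxs - mins; den[den == 0] <- 1
  sc <- function(m) sweep(sweep(m, 2, mins), 2, den, "/")
  A <- sc(train$features)[, sel, drop = FALSE]
  B <- sc(test$features)[, sel, drop = FALSE]
  out <- character(nrow(B))
  for (r in seq_len(nrow(B))) {
    d <- sqrt(colSums((t(A) - B[r, ])^2))
    ord <- order(d, seq_along(d))[seq_len(min(k, length(d)))]
    votes <- table(factor(train$labels[ord], levels = levels(train$labels)))
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      agg <- sapply(top, function(cl) sum(d[ord][train$labels[ord] == cl]))
      top <- top[which.min(agg)]
    }
    out[r] <- top[1]
  }
  factor(out, levels = levels(train$labels))
}

# exhaustive-permutation two-sided rank-sum p-value for tie-free samples
wilcoxon_oracle <- function(a, b) {
  n_a <- length(a); n <- n_a + length(b)
  ranks <- rank(c(a, b))
  w_obs <- sum(ranks[seq_len(n_a)])
  sums <- combn(n, n_a, sum)
  p_lo <- mean(sums <= w_obs)
  p_hi <- mean(sums >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}
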