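test_that("stratified split keeps class proportions and is reproducible", {
  d <- labeled_dataset(matrix(rnorm(200), 100, 2),
                       rep(c("a", "b"), each = 50))
  set.seed(5); sp <- split_dataset(d, 0.75)
  expect_length(sp$train_idx, 75L)
  expect_length(sp$test_idx, 25L)
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), 1:100)
  tr_tab <- table(sp$train$labels)
  expect_true(all(abs(tr_tab - 37.5) <= 1))
  set.seed(5); sp2 <- split_dataset(d, 0.75)
  expect_identical(sp$train_idx, sp2$train_idx)
  # unbalanced classes stay within one sample of the target fraction
  d2 <- labeled_dataset(matrix(rnorm(60), 30, 2), rep(c("a", "b"), c(21, 9)))
  set.seed(1); sp3 <- split_dataset(d2, 0.75)
  expect_true(abs(sum(sp3$train$labels == "a") - 0.75 * 21) <= 1)
  expect_true(abs(sum(sp3$train$labels == "b") - 0.75 * 9) <= 1)
  bad <- list(features = matrix(0, 3, 2),
              labels = factor(c("a", "a", "b")))
  class(bad) <- "labeled_dataset"
  expect_error(split_dataset(bad), "at least 2 samples")
})

test_that("KNN prediction honours distances, majority votes and tie rules", {
  ts <- toy_split()
  # k = 3 over three training points: majority class A
  expect_identical(as.character(knn_predict(ts$train, ts$test, k = 3)), "A")
  # a single training point labels everything
  one <- list(features = matrix(c(0.2, 0.2), 1, 2),
              labels = factor("B", levels = c("A", "B")))
  expect_identical(as.character(knn_predict(one, ts$test, k = 1)), "B")
  # k = 1 on a coincident point returns that point's label
  expect_identical(
    as.character(knn_predict(ts$train,
                             list(features = matrix(c(1, 1), 1, 2)), k = 1)),
    "B")
  expect_error(knn_predict(ts$train, ts$test, mask = c(0, 0), k = 1), "empty")
})

test_that("KNN matches a brute-force oracle on random problems", {
  set.seed(21)
  for (case in 1:20) {
    n_tr <- sample(8:20, 1); n_te <- sample(3:8, 1)
    D <- sample(2:4, 1); k <- sample(c(1, 3, 5), 1)
    train <- list(features = matrix(round(rnorm(n_tr * D), 1), n_tr, D),
                  labels = factor(sample(c("x", "y", "z"), n_tr, TRUE)))
    test <- list(features = matrix(round(rnorm(n_te * D), 1), n_te, D))
    mask <- rep(1, D); mask[sample(D, D - sample(D, 1))] <- 0
    if (sum(mask) == 0) mask[1] <- 1
    expect_identical(knn_predict(train, test, mask, k),
                     knn_oracle(train, test, mask, k))
  }
})

test_that("mask fitness combines error and subset size as configured", {
  sp <- separable_split()
  cfg <- fitness_config(alpha = 0.99, k_neighbors = 1)
  # perfect accuracy with all features costs only the size term
  f_all <- evaluate_mask(c(1, 1), sp$train, sp$test, cfg)
  expect_equal(as.numeric(f_all), 0.01 * 1.0)
  # fewer features with the same accuracy strictly reduce fitness
  f_one <- evaluate_mask(c(1, 0), sp$train, sp$test, cfg)
  expect_equal(as.numeric(f_one), 0.01 * 0.5)
  expect_lt(f_one, f_all)
  # the alpha-weighted error formula at a constructed accuracy: predictions
  # are (A, A, B, B), so all-"B" truth scores exactly 0.5
  flip <- sp$test
  flip$labels <- factor(rep("B", 4), levels = c("A", "B"))
  f <- evaluate_mask(c(1, 1), sp$train, flip, cfg)
  expect_equal(as.numeric(f), 0.99 * 0.5 + 0.01 * 1.0)
  # empty-mask policies
  expect_equal(as.numeric(evaluate_mask(c(0, 0), sp$train, sp$test, cfg)), 1)
  rep_cfg <- fitness_config(alpha = 0.99, k_neighbors = 1,
                            empty_mask_policy = "repair")
  set.seed(2)
  f_rep <- evaluate_mask(c(0, 0), sp$train, sp$test, rep_cfg)
  expect_equal(sum(attr(f_rep, "mask")), 1L)
  expect_lt(as.numeric(f_rep), 1)
})

test_that("scaling is fitted on the training half only", {
  set.seed(30)
  train <- list(features = matrix(rnorm(40), 20, 2),
                labels = factor(sample(c("a", "b"), 20, TRUE)))
  test <- list(features = matrix(rnorm(16, mean = 50), 8, 2))
  p1 <- knn_predict(train, test, k = 3)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  p2 <- knn_predict(train, list(features = test$features[perm, ]), k = 3)
  expect_identical(p1[perm], p2)
})

test_that("select_features is reproducible and its curve never rises", {
  d <- generate_synthetic(n_samples = 80, n_informative = 2, n_noise = 4,
                          class_sep = 3, seed = 9)
  f1 <- select_features(d, pop_size = 8, max_iter = 10, seed = 42)
  f2 <- select_features(d, pop_size = 8, max_iter = 10, seed = 42)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$best_fitness, f2$best_fitness)
  expect_identical(f1$curve, f2$curve)
  expect_true(all(diff(f1$curve) <= 0))
  expect_gte(f1$n_selected, 1L)
})

test_that("a perfectly separating feature is found almost always", {
  d <- generate_synthetic(n_samples = 120, n_informative = 1, n_noise = 7,
                          class_sep = 6, seed = 3)
  hits <- vapply(1:10, function(s) {
    fit <- select_features(d, variant = "irbmo", pop_size = 30,
                           max_iter = 100, seed = s)
    fit$metrics$accuracy == 1
  }, logical(1))
  expect_gte(sum(hits), 9L)
})

test_that("the fitted model supports the standard S3 interface", {
  d <- generate_synthetic(n_samples = 80, n_informative = 2, n_noise = 4,
                          class_sep = 3, seed = 9)
  fit <- select_features(d, pop_size = 8, max_iter = 10, seed = 1)
  expect_s3_class(fit, "rbmofs_fit")
  cf <- coef(fit)
  expect_named(cf, d$feature_names)
  expect_true(all(cf %in% 0:1))
  expect_output(print(fit), "IRBMO wrapper feature selection")
  expect_output(print(summary(fit)), "selected features")
  preds <- predict(fit, d$features)
  expect_s3_class(preds, "factor")
  expect_length(preds, 80L)
  expect_identical(levels(preds), d$class_labels)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
  # formula and matrix interfaces agree with the dataset interface
  df <- as.data.frame(d$features)
  df$y <- d$labels
  fit_f <- select_features(y ~ ., data = df, pop_size = 8, max_iter = 10,
                           seed = 1)
  expect_identical(unname(coef(fit_f)), unname(coef(fit)))
  fit_m <- select_features(d$features, d$labels, pop_size = 8, max_iter = 10,
                           seed = 1)
  expect_identical(coef(fit_m), coef(fit))
})
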