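test_that("delimited loader imputes, coerces and respects the label column", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("f1,f2,class",
               "1.0,4.0,a",
               "2.0,,a",
               "3.0,6.0,b",
               "4.0,8.0,b"), path)
  d <- load_dataset(path, label_column = "class")
  expect_equal(dim(d$features), c(4L, 2L))
  expect_equal(d$features[2, "f2"], 6)      # median of 4, 6, 8
  expect_identical(levels(d$labels), c("a", "b"))
  d_idx <- load_dataset(path, label_column = 3)
  expect_identical(d_idx$features, d$features)
  expect_identical(d_idx$labels, d$labels)
  expect_error(load_dataset(path, label_column = "missing"), "not found")

  semi <- tempfile(fileext = ".txt")
  writeLines(c("f1;f2;y", "1;2;a", "3;4;b", "5;6;a", "7;8;b"), semi)
  expect_equal(ncol(load_dataset(semi)$features), 2L)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("f1,f2,y", "1,low,a", "2,high,b", "3,low,a", "4,low,b"), bad)
  expect_error(load_dataset(bad), "'f2'")

  nolab <- tempfile(fileext = ".csv")
  writeLines(c("f1,f2,y", "1,2,a", "3,4,", "5,6,b", "7,8,a", "9,0,b"), nolab)
  expect_equal(nrow(load_dataset(nolab)$features), 4L)  # missing label dropped
})

test_that("ARFF files load through the attribute header", {
  path <- tempfile(fileext = ".arff")
  writeLines(c("@relation toy",
               "@attribute f1 numeric",
               "@attribute f2 numeric",
               "@attribute class {a,b}",
               "@data",
               "1.0,2.0,a",
               "2.0,1.0,b",
               "3.0,4.0,a",
               "4.0,3.0,b"), path)
  d <- load_dataset(path, label_column = "class")
  expect_equal(dim(d$features), c(4L, 2L))
  expect_identical(as.character(d$labels), c("a", "b", "a", "b"))
})

test_that("write/load round-trips a dataset exactly", {
  d <- generate_synthetic(n_samples = 30, n_informative = 2, n_noise = 3,
                          seed = 8)
  path <- tempfile(fileext = ".csv")
  write_dataset(d, path)
  d2 <- load_dataset(path, label_column = "label")
  expect_equal(unname(d2$features), unname(d$features), tolerance = 1e-12)
  expect_identical(as.character(d2$labels), as.character(d$labels))
  expect_identical(d2$feature_names, d$feature_names)
})

test_that("the synthetic generator plants the advertised structure", {
  d <- generate_synthetic(n_samples = 200, n_informative = 5, n_redundant = 3,
                          n_noise = 12, seed = 1)
  expect_equal(dim(d$features), c(200L, 20L))
  expect_identical(sum(d$informative), 5L)
  expect_identical(names(d$informative)[d$informative],
                   paste0("inf", 1:5))
  d2 <- generate_synthetic(n_samples = 200, n_informative = 5, n_redundant = 3,
                           n_noise = 12, seed = 1)
  expect_identical(d$features, d2$features)
  expect_identical(d$labels, d2$labels)
  expect_error(generate_synthetic(n_informative = 0), "n_informative")
  expect_error(generate_synthetic(label_noise = 0.5), "label_noise")
})

test_that("class separation controls feature-label correlation", {
  null <- generate_synthetic(n_samples = 1e4, n_informative = 4, n_noise = 4,
                             class_sep = 0, label_noise = 0, seed = 2)
  y <- as.integer(null$labels == "pos")
  cors <- apply(null$features, 2, cor, y = y)
  expect_true(all(abs(cors) < 0.05))
  # with separation, informative columns dominate noise columns
  wins <- vapply(1:20, function(s) {
    d <- generate_synthetic(n_samples = 200, n_informative = 3, n_noise = 10,
                            class_sep = 2, seed = s)
    yy <- as.integer(d$labels == "pos")
    cc <- abs(apply(d$features, 2, cor, y = yy))
    mean(cc[1:3]) > mean(cc[4:13])
  }, logical(1))
  expect_identical(sum(wins), 20L)
})

test_that("redundant features track the informative block", {
  d <- generate_synthetic(n_samples = 500, n_informative = 3, n_redundant = 2,
                          n_noise = 2, class_sep = 1, seed = 6)
  r2 <- summary(lm(d$features[, "red1"] ~ d$features[, 1:3]))$r.squared
  expect_gt(r2, 0.9)
})
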