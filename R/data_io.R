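#' Labeled classification dataset
#'
#' Lightweight container for a tabular classification problem: a numeric
#' feature matrix, a factor of class labels, and the column names.
#'
#' @param features numeric matrix (samples x features) or data frame of
#'   numeric columns.
#' @param labels vector of class labels, coerced to factor with levels in
#'   order of first appearance.
#' @param feature_names optional column names; defaults to existing names or
#'   \code{X1..Xp}.
#' @return an object of class \code{labeled_dataset} with elements
#'   \code{features}, \code{labels}, \code{feature_names}, \code{class_labels}.
#' @export
labeled_dataset <- function(features, labels, feature_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (nrow(features) != length(labels))
    stop("'features' and 'labels' must have the same number of rows")
  if (ncol(features) < 2) stop("need at least 2 features")
  if (anyNA(features)) stop("'features' must not contain missing values")
  labels <- factor(labels, levels = unique(as.character(labels)))
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  if (any(table(labels) < 2)) stop("every class needs at least 2 samples")
  if (is.null(feature_names)) feature_names <- colnames(features)
  if (is.null(feature_names)) feature_names <- paste0("X", seq_len(ncol(features)))
  colnames(features) <- feature_names
  structure(list(features = features, labels = labels,
                 feature_names = feature_names,
                 class_labels = levels(labels)),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled dataset: %d samples, %d features, %d classes (%s)\n",
              nrow(x$features), ncol(x$features), length(x$class_labels),
              paste(x$class_labels, collapse = ", ")))
  invisible(x)
}

# guess the field separator of a delimited text file (comma/semicolon/tab)
detect_delimiter <- function(path) {
  line <- readLines(path, n = 1L)
  counts <- vapply(c(",", ";", "\t"),
                   function(d) lengths(regmatches(line, gregexpr(d, line, fixed = TRUE))),
                   integer(1))
  if (all(counts == 0))
    stop("could not detect the delimiter of '", path,
         "'; pass 'delimiter' explicitly")
  c(",", ";", "\t")[which.max(counts)]
}

#' Load a delimited or ARFF classification table
#'
#' Reads a UCI/KEEL-style table (CSV with comma, semicolon or tab, or ARFF)
#' into a \code{\link{labeled_dataset}}. Rows with a missing label are
#' dropped; missing numeric feature values are imputed with the column
#' median; a feature column that cannot be coerced to numeric raises an
#' error naming the column.
#'
#' @param path file to read; files ending in \code{.arff} go through
#'   \code{foreign::read.arff}, everything else through a delimited reader.
#' @param label_column name or index of the class-label column; defaults to
#'   the last column.
#' @param delimiter field separator; auto-detected among comma, semicolon
#'   and tab when \code{NULL}.
#' @return a \code{\link{labeled_dataset}}.
#' @export
load_dataset <- function(path, label_column = NULL, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.arff$", path, ignore.case = TRUE)) {
    df <- foreign::read.arff(path)
  } else {
    if (is.null(delimiter)) delimiter <- detect_delimiter(path)
    df <- utils::read.table(path, header = TRUE, sep = delimiter,
                            stringsAsFactors = FALSE, check.names = FALSE)
  }
  if (is.null(label_column)) label_column <- ncol(df)
  lab_idx <- if (is.character(label_column)) {
    m <- match(label_column, names(df))
    if (is.na(m)) stop("label column '", label_column, "' not found")
    m
  } else {
    if (label_column < 1 || label_column > ncol(df))
      stop("label column index out of range")
    as.integer(label_column)
  }
  labels <- df[[lab_idx]]
  keep <- !is.na(labels) & labels != ""
  df <- df[keep, , drop = FALSE]
  labels <- labels[keep]
  feats <- df[, -lab_idx, drop = FALSE]
  for (j in seq_along(feats)) {
    col <- feats[[j]]
    if (!is.numeric(col)) {
      was_na <- is.na(col) | col == "" | col == "?"
      num <- suppressWarnings(as.numeric(as.character(col)))
      if (any(is.na(num) & !was_na))
        stop("feature column '", names(feats)[j],
             "' cannot be coerced to numeric")
      num[was_na] <- NA_real_
      feats[[j]] <- num
    }
  }
  m <- as.matrix(feats)
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (any(nas)) m[nas, j] <- stats::median(m[, j], na.rm = TRUE)
  }
  labeled_dataset(m, labels, feature_names = names(feats))
}

#' Write a dataset as CSV
#'
#' Writes features plus a final \code{label} column; \code{load_dataset}
#' on the result reproduces the dataset exactly.
#'
#' @param data a \code{\link{labeled_dataset}}.
#' @param path output file.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "labeled_dataset"))
  df <- as.data.frame(data$features)
  df$label <- as.character(data$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic classification dataset with planted structure
#'
#' Builds a two-class dataset whose columns fall into three known groups:
#' informative features drawn from class-conditional Gaussians whose means
#' are \code{class_sep} apart (unit variance), redundant features that are
#' random linear combinations of the informative ones plus small Gaussian
#' noise (sd 0.1), and pure-noise features independent of the label. Labels
#' are balanced between the two classes and then flipped independently with
#' probability \code{label_noise}. The returned object records which columns
#' are informative, so feature-selection runs can be scored against ground
#' truth.
#'
#' @param n_samples number of rows.
#' @param n_informative number of class-separating columns (>= 1).
#' @param n_redundant number of linear-combination columns.
#' @param n_noise number of label-independent columns.
#' @param class_sep distance between the class-conditional means of each
#'   informative feature, in units of its standard deviation.
#' @param label_noise probability in \[0, 0.5) of flipping each label.
#' @param seed optional integer seed.
#' @return a \code{\link{labeled_dataset}} with an extra element
#'   \code{informative}: a logical vector marking the informative columns.
#' @export
generate_synthetic <- function(n_samples = 300, n_informative = 5,
                               n_redundant = 0, n_noise = 15,
                               class_sep = 2, label_noise = 0, seed = NULL) {
  if (n_informative < 1) stop("'n_informative' must be at least 1")
  if (n_redundant < 0 || n_noise < 0) stop("feature counts must be >= 0")
  if (label_noise < 0 || label_noise >= 0.5)
    stop("'label_noise' must lie in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  y <- rep_len(c(0L, 1L), n_samples)
  mu <- ifelse(y == 1L, class_sep / 2, -class_sep / 2)
  inf <- matrix(stats::rnorm(n_samples * n_informative), n_samples) + mu
  red <- if (n_redundant > 0) {
    W <- matrix(stats::rnorm(n_informative * n_redundant), n_informative)
    inf %*% W + matrix(stats::rnorm(n_samples * n_redundant, sd = 0.1), n_samples)
  } else NULL
  noi <- if (n_noise > 0)
    matrix(stats::rnorm(n_samples * n_noise), n_samples) else NULL
  X <- cbind(inf, red, noi)
  colnames(X) <- c(sprintf("inf%d", seq_len(n_informative)),
                   if (n_redundant > 0) sprintf("red%d", seq_len(n_redundant)),
                   if (n_noise > 0) sprintf("noise%d", seq_len(n_noise)))
  if (label_noise > 0) {
    flip <- stats::runif(n_samples) < label_noise
    y[flip] <- 1L - y[flip]
  }
  out <- labeled_dataset(X, factor(ifelse(y == 1L, "pos", "neg"),
                                   levels = c("neg", "pos")))
  out$informative <- c(rep(TRUE, n_informative),
                       rep(FALSE, n_redundant + n_noise))
  names(out$informative) <- colnames(X)
  out
}
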