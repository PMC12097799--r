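#' Read a flat key-value configuration file
#'
#' Parses lines of the form \code{key = value}; blank lines and lines
#' starting with \code{#} are ignored. Values stay character; the caller
#' coerces.
#'
#' @param path file to read.
#' @return named list of character values.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    out[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
  }
  out
}

#' Run a multi-dataset, multi-optimizer feature-selection study
#'
#' Reproduces the standard evaluation protocol: for every combination of
#' dataset, optimizer variant and transfer function, performs \code{n_runs}
#' independent feature-selection runs (run seed = \code{seed} + run index -
#' 1; each run redraws its stratified split), and writes per-run records,
#' mean/sd summaries and convergence curves as CSV. With two or more
#' optimizers it also writes a comparison report: the mean-fitness table,
#' rank-sum win/tie/loss of the first optimizer against each other, and
#' Friedman mean ranks.
#'
#' @param datasets a \code{\link{labeled_dataset}} or a (optionally named)
#'   list of them.
#' @param optimizers character vector of variants among \code{"irbmo"},
#'   \code{"rbmo"}; the first is the reference of the win/tie/loss report.
#' @param transfers character vector of transfer-function names
#'   (default \code{"threshold"}).
#' @param pop_size,max_iter,n_runs protocol parameters (defaults 30 agents,
#'   100 iterations, 30 runs).
#' @param seed base seed of the run-seed schedule.
#' @param alpha,k,train_fraction wrapper-fitness settings.
#' @param out_dir output directory, created if needed; checked to be
#'   writable before any run starts.
#' @param verbose print one line per run.
#' @return invisibly, a list with the per-run \code{records} data frame,
#'   the per-combination \code{summaries}, and the \code{comparison}
#'   (NULL with a single optimizer and transfer).
#' @export
run_experiment <- function(datasets, optimizers = c("irbmo", "rbmo"),
                           transfers = "threshold", pop_size = 30,
                           max_iter = 100, n_runs = 30, seed = 1,
                           alpha = 0.99, k = 5, train_fraction = 0.75,
                           out_dir = NULL, verbose = FALSE) {
  if (inherits(datasets, "labeled_dataset")) datasets <- list(datasets)
  if (is.null(names(datasets)) || any(!nzchar(names(datasets))))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  if (n_runs < 1) stop("'n_runs' must be >= 1")
  write_out <- !is.null(out_dir)
  if (write_out) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (file.access(out_dir, 2) != 0)
      stop("output directory is not writable: ", out_dir)
  }

  all_records <- NULL
  summaries <- list()
  log_rows <- NULL
  combos <- expand.grid(optimizer = optimizers, transfer = transfers,
                        stringsAsFactors = FALSE)

  for (ds_name in names(datasets)) {
    data <- datasets[[ds_name]]
    for (ci in seq_len(nrow(combos))) {
      opt <- combos$optimizer[ci]; tf <- combos$transfer[ci]
      tag <- sprintf("%s_%s_%s", ds_name, opt, tf)
      recs <- vector("list", n_runs)
      curves <- matrix(NA_real_, max_iter + 1L, n_runs)
      for (r in seq_len(n_runs)) {
        run_seed <- seed + r - 1L
        t0 <- proc.time()[["elapsed"]]
        fit <- select_features(data, variant = opt, transfer = tf,
                               pop_size = pop_size, max_iter = max_iter,
                               alpha = alpha, k = k,
                               train_fraction = train_fraction,
                               seed = run_seed)
        dur <- proc.time()[["elapsed"]] - t0
        recs[[r]] <- cbind(dataset = ds_name, optimizer = opt,
                           transfer = tf, run = r, run_record(fit))
        curves[, r] <- fit$curve
        log_rows <- rbind(log_rows,
                          data.frame(dataset = ds_name, optimizer = opt,
                                     transfer = tf, run = r,
                                     seed = run_seed,
                                     duration_sec = round(dur, 3),
                                     best_fitness = fit$best_fitness))
        if (verbose)
          message(sprintf("[%s] run %d/%d seed %d fitness %.6f (%.1fs)",
                          tag, r, n_runs, run_seed, fit$best_fitness, dur))
      }
      recs <- do.call(rbind, recs)
      all_records <- rbind(all_records, recs)
      summaries[[tag]] <- aggregate_runs(recs, ncol(data$features))
      if (write_out) {
        utils::write.csv(recs, file.path(out_dir, paste0(tag, "_runs.csv")),
                         row.names = FALSE)
        utils::write.csv(cbind(as.data.frame(summaries[[tag]])),
                         file.path(out_dir, paste0(tag, "_summary.csv")),
                         row.names = FALSE)
        curve_df <- data.frame(iteration = 0:max_iter, curves)
        names(curve_df) <- c("iteration", paste0("run", seq_len(n_runs)))
        utils::write.csv(curve_df,
                         file.path(out_dir, paste0(tag, "_curves.csv")),
                         row.names = FALSE)
      }
    }
  }

  comparison <- NULL
  arms <- unique(paste(all_records$optimizer, all_records$transfer, sep = "_"))
  if (length(arms) >= 2) {
    # mean-fitness table: problems x algorithm arms
    mean_tab <- sapply(arms, function(a) sapply(names(datasets), function(d) {
      sub <- all_records[paste(all_records$optimizer, all_records$transfer,
                               sep = "_") == a & all_records$dataset == d, ]
      mean(sub$fitness)
    }))
    mean_tab <- matrix(mean_tab, nrow = length(datasets),
                       dimnames = list(names(datasets), arms))
    ref <- arms[1]
    wtl <- lapply(arms[-1], function(a) {
      ref_runs <- lapply(names(datasets), function(d)
        all_records$fitness[all_records$dataset == d &
          paste(all_records$optimizer, all_records$transfer, sep = "_") == ref])
      cmp_runs <- lapply(names(datasets), function(d)
        all_records$fitness[all_records$dataset == d &
          paste(all_records$optimizer, all_records$transfer, sep = "_") == a])
      names(ref_runs) <- names(cmp_runs) <- names(datasets)
      win_tie_loss(ref_runs, cmp_runs, direction = "min")
    })
    names(wtl) <- arms[-1]
    fr <- friedman_mean_ranks(mean_tab, direction = "min")
    comparison <- list(mean_fitness = mean_tab, win_tie_loss = wtl,
                       friedman = fr, reference = ref)
    if (write_out) {
      utils::write.csv(data.frame(dataset = rownames(mean_tab), mean_tab),
                       file.path(out_dir, "comparison_mean_fitness.csv"),
                       row.names = FALSE)
      wtl_df <- do.call(rbind, lapply(names(wtl), function(a)
        data.frame(competitor = a, win = wtl[[a]]$win, tie = wtl[[a]]$tie,
                   loss = wtl[[a]]$loss)))
      utils::write.csv(wtl_df, file.path(out_dir, "comparison_wtl.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(algorithm = names(fr$mean_ranks),
                                  mean_rank = as.numeric(fr$mean_ranks)),
                       file.path(out_dir, "comparison_friedman.csv"),
                       row.names = FALSE)
    }
  }
  if (write_out)
    utils::write.csv(log_rows, file.path(out_dir, "experiment_log.csv"),
                     row.names = FALSE)

  invisible(list(records = all_records, summaries = summaries,
                 comparison = comparison))
}
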