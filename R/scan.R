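#' Configuration for a sample-size scan
#'
#' Defaults reproduce the study protocol: every sample size from 15 to the
#' dataset size in steps of one, 100 Monte-Carlo iterations each, a 70/30
#' sex-stratified split, 10-fold cross-validated elastic net with alpha 0.5.
#'
#' @param n_min,n_max,n_step Sample-size grid (n_max defaults to the dataset
#'   size at run time when `NULL`).
#' @param iterations Monte-Carlo iterations per grid point.
#' @param alpha,train_fraction,cv_folds,lambda_rule Passed to [fit_clock()] /
#'   [stratified_split()].
#' @param base_seed Integer; per-(n, iteration) seeds are derived from it with
#'   [derive_seed()], so grid points are order-independent.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(n_min = 15, n_max = NULL, n_step = 1, iterations = 100,
                        alpha = 0.5, train_fraction = 0.7, cv_folds = 10,
                        lambda_rule = "min", base_seed = 1) {
  if (iterations < 1) stopf("iterations must be >= 1")
  if (n_min < cv_folds + 2) {
    stopf("n_min (%d) must be >= cv_folds + 2 (%d)", n_min, cv_folds + 2)
  }
  structure(
    list(n_min = as.integer(n_min),
         n_max = if (is.null(n_max)) NULL else as.integer(n_max),
         n_step = as.integer(n_step), iterations = as.integer(iterations),
         alpha = alpha, train_fraction = train_fraction,
         cv_folds = as.integer(cv_folds), lambda_rule = lambda_rule,
         base_seed = as.integer(base_seed)),
    class = "scan_config"
  )
}

#' Draw a sex-stratified subsample
#'
#' Selects `n` distinct samples whose sex composition matches the dataset's
#' own sex proportions to within one sample. If a sex class is exhausted the
#' shortfall is filled from the remaining pool with a warning.
#'
#' @param ds A `methylation_dataset`.
#' @param n Subsample size, `<= n_samples(ds)`.
#' @param seed Integer seed; the subsample is deterministic given the seed.
#' @return Sorted integer vector of `n` sample indices.
#' @export
subsample_stratified <- function(ds, n, seed = 1) {
  N <- n_samples(ds)
  if (n > N) stopf("requested n = %d exceeds dataset size %d", n, N)
  if (n == N) return(seq_len(N))
  idx_f <- which(ds$sexes == "F")
  idx_m <- which(ds$sexes == "M")
  n_f <- floor(n * length(idx_f) / N + 0.5)
  n_m <- n - n_f
  with_seed(seed, {
    if (n_f > length(idx_f) || n_m > length(idx_m)) {
      warnf("a sex class is exhausted at n = %d; topping up from remaining pool", n)
      n_f <- min(n_f, length(idx_f))
      n_m <- min(n - n_f, length(idx_m))
      n_f <- n - n_m
    }
    sort(c(sample(idx_f, n_f), sample(idx_m, n_m)))
  })
}

# One Monte-Carlo unit: stratified split of `indices`, CV elastic-net fit on
# the training part, evaluation on the held-out part. Shared by the
# sample-size scan and the window-scan baseline so both measure the same
# protocol.
mc_cycle <- function(ds, indices, seed, train_fraction, alpha, cv_folds,
                     lambda_rule, ref_max_age) {
  sp <- stratified_split(ds, train_fraction, seed = seed + 1L, indices = indices)
  model <- fit_clock(ds, sp$train_indices, alpha = alpha, cv_folds = cv_folds,
                     seed = seed + 2L, lambda_rule = lambda_rule)
  pred <- predict_ages(model, ds, sp$test_indices)
  evaluate_predictions(pred, ds$ages[sp$test_indices], ref_max_age,
                       n_selected_cpgs = length(model$coefficients))
}

#' Run the Monte-Carlo sample-size scan
#'
#' For each sample size `n` on the grid and each iteration: draw a stratified
#' subsample of size `n`, split it 70/30 preserving the sex ratio, fit the
#' cross-validated elastic-net clock on the training part, and evaluate
#' Pearson r, MAE, relative MAE (percent of the full dataset's oldest age) and
#' the number of selected CpGs on the held-out part. Iterations that fail
#' (degenerate subsamples) are recorded as `NA` rows; more than 10% failures
#' at any grid point aborts with diagnostics.
#'
#' @param ds A `methylation_dataset`.
#' @param cfg A [scan_config()].
#' @param progress Print a dot per grid point (default FALSE).
#' @return An object of class `samplesize_scan`: list with `metrics` (long
#'   data.frame: `n`, `iteration`, `r`, `mae`, `relative_mae_pct`, `n_cpgs`)
#'   and `config`.
#' @export
run_samplesize_scan <- function(ds, cfg = scan_config(), progress = FALSE) {
  stopifnot(inherits(cfg, "scan_config"))
  N <- n_samples(ds)
  n_max <- if (is.null(cfg$n_max)) N else min(cfg$n_max, N)
  grid <- seq(cfg$n_min, n_max, by = cfg$n_step)
  if (length(grid) == 0) stopf("empty sample-size grid")
  ref_max_age <- max(ds$ages)

  rows <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    n <- grid[gi]
    out <- matrix(NA_real_, cfg$iterations, 4)
    for (k in seq_len(cfg$iterations)) {
      seed_nk <- derive_seed(cfg$base_seed, n, k)
      res <- tryCatch({
        idx <- subsample_stratified(ds, n, seed = seed_nk)
        m <- mc_cycle(ds, idx, seed_nk, cfg$train_fraction, cfg$alpha,
                      cfg$cv_folds, cfg$lambda_rule, ref_max_age)
        c(m$pearson_r, m$mae, m$relative_mae_pct, m$n_selected_cpgs)
      }, error = function(e) NULL)
      if (!is.null(res)) out[k, ] <- res
    }
    failed <- sum(is.na(out[, 2]))
    if (failed > 0.1 * cfg$iterations) {
      stopf("%d/%d iterations failed at n = %d", failed, cfg$iterations, n)
    }
    rows[[gi]] <- data.frame(n = n, iteration = seq_len(cfg$iterations),
                             r = out[, 1], mae = out[, 2],
                             relative_mae_pct = out[, 3], n_cpgs = out[, 4])
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  structure(list(metrics = do.call(rbind, rows),
                 config = cfg, grid = grid, reference_max_age = ref_max_age),
            class = "samplesize_scan")
}

#' @export
print.samplesize_scan <- function(x, ...) {
  cat(sprintf("samplesize_scan: %d grid points (n = %d..%d), %d iterations each\n",
              length(x$grid), min(x$grid), max(x$grid), x$config$iterations))
  invisible(x)
}

#' Summarise a sample-size scan
#'
#' Per grid point: arithmetic mean of the iteration correlations, an empirical
#' central percentile interval of the correlations at `interval_level`, and
#' means of MAE and selected-CpG counts. Failed (`NA`) iterations are excluded;
#' a grid point with no successful iteration is an error.
#'
#' @param scan A `samplesize_scan`.
#' @param interval_level Central interval level in percent (default 95).
#' @return A data.frame with columns `n`, `mean_r`, `r_ci_low`, `r_ci_high`,
#'   `mean_mae`, `mean_relative_mae_pct`, `mean_n_cpgs`, `n_ok`.
#' @export
summarize_scan <- function(scan, interval_level = 95) {
  stopifnot(inherits(scan, "samplesize_scan"))
  if (interval_level <= 0 || interval_level >= 100) {
    stopf("interval_level must be in (0, 100)")
  }
  probs <- c((100 - interval_level) / 200, 1 - (100 - interval_level) / 200)
  m <- scan$metrics
  out <- lapply(split(m, m$n), function(d) {
    ok <- !is.na(d$mae)
    if (!any(ok)) stopf("all iterations failed at n = %d", d$n[1])
    r <- d$r[ok & !is.na(d$r)]
    ci <- if (length(r)) stats::quantile(r, probs, names = FALSE, type = 7)
          else c(NA_real_, NA_real_)
    data.frame(n = d$n[1],
               mean_r = if (length(r)) mean(r) else NA_real_,
               r_ci_low = ci[1], r_ci_high = ci[2],
               mean_mae = mean(d$mae[ok]),
               mean_relative_mae_pct = mean(d$relative_mae_pct[ok]),
               mean_n_cpgs = mean(d$n_cpgs[ok]),
               n_ok = sum(ok))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a sample-size scan as long-format TSV plus config JSON
#'
#' The canonical interchange between pipeline stages: a long table
#' (`n`, `iteration`, `r`, `mae`, `relative_mae_pct`, `n_cpgs`) and a JSON
#' sidecar (`<path>.config.json`) carrying the scan configuration and the
#' reference maximum age, so a scan can be re-loaded and analysed without
#' re-running the Monte Carlo.
#'
#' @param scan A `samplesize_scan`.
#' @param path TSV path; the sidecar is written next to it.
#' @return `read_scan_metrics` returns the restored `samplesize_scan`.
#' @export
write_scan_metrics <- function(scan, path) {
  stopifnot(inherits(scan, "samplesize_scan"))
  data.table::fwrite(scan$metrics, path, sep = "\t", na = "NA", quote = FALSE)
  side <- unclass(scan$config)
  side$reference_max_age <- scan$reference_max_age
  jsonlite::write_json(side, paste0(path, ".config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(scan)
}

#' @rdname write_scan_metrics
#' @export
read_scan_metrics <- function(path) {
  if (!file.exists(path)) stopf("scan file not found: %s", path)
  metrics <- data.table::fread(path, data.table = FALSE)
  side_path <- paste0(path, ".config.json")
  if (!file.exists(side_path)) stopf("scan config sidecar not found: %s", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  ref <- side$reference_max_age
  side$reference_max_age <- NULL
  cfg <- structure(side, class = "scan_config")
  structure(list(metrics = metrics, config = cfg,
                 grid = sort(unique(metrics$n)), reference_max_age = ref),
            class = "samplesize_scan")
}
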