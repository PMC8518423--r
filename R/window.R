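#' Enumerate sliding removal windows over the age-sorted sample order
#'
#' Samples are ordered by increasing age (ties broken by sample id) and a
#' contiguous block of `k = round(removal_fraction * N)` samples is removed at
#' every start position `s = 0 .. N - k` (0-based), giving `N - k + 1` windows.
#'
#' @param N Total sample count.
#' @param removal_fraction Fraction of samples to remove, in (0, 1).
#' @param min_retained Minimum trainable retained count (default 15).
#' @return A data.frame with columns `start` (0-based) and `k`.
#' @export
enumerate_windows <- function(N, removal_fraction, min_retained = 15) {
  if (removal_fraction <= 0 || removal_fraction >= 1) {
    stopf("removal_fraction must be in (0, 1)")
  }
  k <- round(removal_fraction * N)
  if (k < 1) stopf("removal_fraction %.2f removes no sample at N = %d",
                   removal_fraction, N)
  if (N - k < min_retained) {
    feasible <- max(0, 1 - min_retained / N)
    stopf(paste0("fraction %.2f retains only %d samples (min %d); ",
                 "fractions up to ~%.2f are feasible"),
          removal_fraction, N - k, min_retained, feasible)
  }
  data.frame(start = 0:(N - k), k = k)
}

# Age-sorted sample order, ties broken by sample id (stable, reproducible).
age_order <- function(ds) order(ds$ages, ds$sample_ids)

#' Cohen's d of a window MAE against the full-data baseline
#'
#' `d = (mae - baseline_mean) / baseline_sd`, signed: positive when the
#' reduced-data model is worse than the full-data model.
#'
#' @param mae Window mean absolute error (same age units as the baseline).
#' @param baseline_mean,baseline_sd Mean and SD of the full-data iteration MAE
#'   distribution; `baseline_sd` must be positive.
#' @return Signed effect size (vectorised over `mae`).
#' @export
cohens_d <- function(mae, baseline_mean, baseline_sd) {
  if (baseline_sd <= 0) stopf("baseline_sd must be > 0")
  (mae - baseline_mean) / baseline_sd
}

#' Sliding-window age-range-removal scan
#'
#' Quantifies how a clock degrades when a contiguous age range is absent from
#' calibration. First a baseline: `baseline_iterations` standard full-data
#' cycles (stratified 70/30 split, CV elastic net, test-set MAE) give the
#' reference MAE distribution. Then for each removal fraction and each window
#' position over the age-sorted order, the clock is trained on all retained
#' samples (lambda chosen by internal CV) and, under the default
#' `evaluate_on = "removed"`, evaluated on the removed window itself — pure
#' extrapolation onto the missing age range. `evaluate_on = "holdout"` instead
#' evaluates on a 30% sex-stratified holdout of the retained samples.
#' Relative MAE uses the full dataset's oldest age as reference. Fractions
#' that would retain fewer than `min_retained` samples are recorded as
#' infeasible (all-NA) with a warning rather than aborting the scan.
#'
#' @param ds A `methylation_dataset`.
#' @param fractions Removal fractions (default 0.1-0.9 by 0.1).
#' @param iterations Monte-Carlo iterations per window (default 10; windows
#'   are additionally averaged over positions by the slide itself).
#' @param alpha,cv_folds,train_fraction,lambda_rule Model settings as in
#'   [fit_clock()] / [stratified_split()].
#' @param base_seed Integer seed; per-task seeds are derived.
#' @param baseline_iterations Full-data cycles for the baseline (default 100).
#' @param evaluate_on `"removed"` (default) or `"holdout"`.
#' @param min_retained Minimum trainable retained count (default 15).
#' @param progress Print a dot per fraction (default FALSE).
#' @return An object of class `window_scan`: list with `baseline` (`values`,
#'   `mean`, `sd`), `windows` (data.frame: `fraction`, `start`, `k`,
#'   `mean_mae`, `relative_mae_pct`, `d`, `n_iter`), `infeasible_fractions`,
#'   `N`, `evaluate_on`, `reference_max_age`.
#' @export
run_window_scan <- function(ds, fractions = seq(0.1, 0.9, by = 0.1),
                            iterations = 10, alpha = 0.5, cv_folds = 10,
                            train_fraction = 0.7, lambda_rule = "min",
                            base_seed = 1, baseline_iterations = 100,
                            evaluate_on = c("removed", "holdout"),
                            min_retained = 15, progress = FALSE) {
  evaluate_on <- match.arg(evaluate_on)
  N <- n_samples(ds)
  ref_max_age <- max(ds$ages)
  ord <- age_order(ds)

  # same unit and seed derivation as run_samplesize_scan at n = N, so the
  # baseline is exactly a full-data sample-size iteration restricted to MAE
  base_vals <- vapply(seq_len(baseline_iterations), function(k) {
    seed_k <- derive_seed(base_seed, N, k)
    mc_cycle(ds, seq_len(N), seed_k, train_fraction, alpha, cv_folds,
             lambda_rule, ref_max_age)$mae
  }, numeric(1))
  baseline <- list(values = base_vals, mean = mean(base_vals),
                   sd = stats::sd(base_vals))

  rows <- list()
  infeasible <- numeric(0)
  for (f in fractions) {
    wins <- tryCatch(enumerate_windows(N, f, min_retained = min_retained),
                     error = function(e) NULL)
    if (is.null(wins)) {
      warnf("removal fraction %.2f infeasible (retained < %d); recorded as NA",
            f, min_retained)
      infeasible <- c(infeasible, f)
      next
    }
    k <- wins$k[1]
    frac_rows <- lapply(wins$start, function(s) {
      removed <- ord[(s + 1):(s + k)]
      retained <- ord[-((s + 1):(s + k))]
      maes <- vapply(seq_len(iterations), function(it) {
        seed_it <- derive_seed(base_seed, round(1000 * f), s + 1L, it)
        tryCatch({
          if (evaluate_on == "removed") {
            model <- fit_clock(ds, retained, alpha = alpha,
                               cv_folds = cv_folds, seed = seed_it,
                               lambda_rule = lambda_rule)
            pred <- predict_ages(model, ds, removed)
            mean(abs(pred - ds$ages[removed]))
          } else {
            sp <- stratified_split(ds, train_fraction, seed = seed_it,
                                   indices = retained)
            model <- fit_clock(ds, sp$train_indices, alpha = alpha,
                               cv_folds = cv_folds, seed = seed_it + 2L,
                               lambda_rule = lambda_rule)
            pred <- predict_ages(model, ds, sp$test_indices)
            mean(abs(pred - ds$ages[sp$test_indices]))
          }
        }, error = function(e) NA_real_)
      }, numeric(1))
      ok <- !is.na(maes)
      mean_mae <- if (any(ok)) mean(maes[ok]) else NA_real_
      data.frame(fraction = f, start = s, k = k, mean_mae = mean_mae,
                 relative_mae_pct = 100 * mean_mae / ref_max_age,
                 d = if (is.na(mean_mae)) NA_real_ else
                   cohens_d(mean_mae, baseline$mean, baseline$sd),
                 n_iter = sum(ok))
    })
    rows <- c(rows, frac_rows)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  structure(
    list(baseline = baseline,
         windows = if (length(rows)) do.call(rbind, rows) else
           data.frame(fraction = numeric(0), start = integer(0), k = integer(0),
                      mean_mae = numeric(0), relative_mae_pct = numeric(0),
                      d = numeric(0), n_iter = integer(0)),
         fractions = fractions, infeasible_fractions = infeasible,
         N = N, evaluate_on = evaluate_on, reference_max_age = ref_max_age),
    class = "window_scan"
  )
}

#' @export
print.window_scan <- function(x, ...) {
  cat(sprintf(
    "window_scan: N = %d, %d window rows over fractions {%s}, evaluated on %s\n",
    x$N, nrow(x$windows), paste(x$fractions, collapse = ", "), x$evaluate_on))
  cat(sprintf("  baseline MAE %.3f (sd %.3f) over %d full-data iterations\n",
              x$baseline$mean, x$baseline$sd, length(x$baseline$values)))
  invisible(x)
}

#' Compliant position ranges per removal fraction and effect size
#'
#' A window complies at level `d` when its Cohen's d (MAE increase over the
#' full-data baseline, in baseline-SD units) is at most `d`; compliance is
#' one-sided, so improvements never violate it. For each (fraction, d) the
#' range runs from the earliest compliant window's first removed position to
#' the latest compliant window's last removed position, expressed as percent
#' of the age-sorted order (1-based boundaries: `100*(start+1)/N` and
#' `100*(start+k)/N`); `NA` when no window complies or the fraction was
#' infeasible. Default levels are Cohen's small/medium/large (0.20/0.50/0.80).
#'
#' @param scan A `window_scan`.
#' @param d_levels Effect-size levels.
#' @return A data.frame: `fraction`, `d_level`, `min_pct`, `max_pct`.
#' @export
window_stability_ranges <- function(scan, d_levels = c(0.20, 0.50, 0.80)) {
  stopifnot(inherits(scan, "window_scan"))
  if (is.null(scan$baseline) || !is.finite(scan$baseline$sd)) {
    stopf("scan lacks a valid baseline")
  }
  N <- scan$N
  out <- list()
  for (f in scan$fractions) {
    w <- scan$windows[scan$windows$fraction == f, , drop = FALSE]
    for (dl in d_levels) {
      if (nrow(w) == 0) {
        out[[length(out) + 1]] <- data.frame(fraction = f, d_level = dl,
                                             min_pct = NA_real_, max_pct = NA_real_)
        next
      }
      compliant <- which(!is.na(w$d) & w$d <= dl)
      if (!length(compliant)) {
        out[[length(out) + 1]] <- data.frame(fraction = f, d_level = dl,
                                             min_pct = NA_real_, max_pct = NA_real_)
      } else {
        first <- w[compliant[1], ]
        last <- w[compliant[length(compliant)], ]
        out[[length(out) + 1]] <- data.frame(
          fraction = f, d_level = dl,
          min_pct = 100 * (first$start + 1) / N,
          max_pct = 100 * (last$start + last$k) / N)
      }
    }
  }
  do.call(rbind, out)
}

#' Format compliant ranges as a wide, publication-style table
#'
#' Rows are removal percentages, columns min/max percent per effect-size
#' level; undefined entries carry the literal string `"NA"`.
#'
#' @param ranges Output of [window_stability_ranges()].
#' @param digits Rounding for the percentage columns (default 1).
#' @return A character data.frame.
#' @export
format_window_ranges <- function(ranges, digits = 1) {
  fmt <- function(x) ifelse(is.na(x), "NA", formatC(round(x, digits),
                                                    format = "f", digits = digits))
  fractions <- sort(unique(ranges$fraction))
  d_levels <- sort(unique(ranges$d_level))
  out <- data.frame(removal_pct = 100 * fractions)
  for (dl in d_levels) {
    sub <- ranges[ranges$d_level == dl, ]
    sub <- sub[match(fractions, sub$fraction), ]
    out[[sprintf("min_pct_d%.2f", dl)]] <- fmt(sub$min_pct)
    out[[sprintf("max_pct_d%.2f", dl)]] <- fmt(sub$max_pct)
  }
  out
}
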