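#' Estimate the plateau ("true") correlation of a scan trajectory
#'
#' The true correlation is where the mean test-set correlation stops
#' increasing with sample size. It is estimated as the mean of `mean_r` over
#' the largest `tail_points` grid points, with a plateau diagnostic: the
#' least-squares slope of `mean_r` against `n` over that tail, flagged as not
#' plateaued when the slope exceeds 5e-4 per sample (the trajectory is then
#' still rising at the largest available n and the estimate is a lower bound).
#'
#' @param summary A [summarize_scan()] data.frame.
#' @param tail_points Number of largest grid points to average (default 10).
#' @return A list of class `true_correlation`: `r_true`, `tail_slope`,
#'   `plateaued`, `tail_points`.
#' @export
estimate_true_correlation <- function(summary, tail_points = 10) {
  if (tail_points < 1) stopf("tail_points must be >= 1")
  if (tail_points > nrow(summary)) {
    stopf("tail_points (%d) exceeds grid size (%d)", tail_points, nrow(summary))
  }
  tail_df <- summary[order(summary$n), ][seq(nrow(summary) - tail_points + 1,
                                             nrow(summary)), ]
  r_true <- mean(tail_df$mean_r)
  slope <- if (tail_points >= 2) {
    unname(stats::coef(stats::lm(mean_r ~ n, data = tail_df))[2])
  } else 0
  structure(list(r_true = r_true, tail_slope = slope,
                 plateaued = slope <= 5e-4, tail_points = tail_points),
            class = "true_correlation")
}

#' @export
print.true_correlation <- function(x, ...) {
  cat(sprintf("r_true = %.4f (tail of %d points, slope %.2g/sample, %s)\n",
              x$r_true, x$tail_points, x$tail_slope,
              if (x$plateaued) "plateaued" else "NOT plateaued"))
  invisible(x)
}

# Central percentile interval of the iteration correlations at one grid point.
central_interval <- function(r, percentile) {
  lo <- (100 - percentile) / 200
  stats::quantile(r, c(lo, 1 - lo), names = FALSE, type = 7)
}

#' Point of stability of the correlation trajectory
#'
#' The corridor of stability is the interval `[max(-1, r_true - w),
#' min(1, r_true + w)]`. The point of stability is the smallest grid sample
#' size from which the correlation distribution enters the corridor and never
#' leaves it: under the default `"envelope"` criterion, the central
#' `percentile` interval of the iteration correlations must lie inside the
#' corridor at every grid point `n' >= n`; under `"fraction"`, at least
#' `percentile`% of iterations must fall inside the corridor at every
#' `n' >= n`.
#'
#' @param scan A `samplesize_scan`.
#' @param r_true Plateau correlation (see [estimate_true_correlation()]).
#' @param w Corridor half-width, > 0.
#' @param percentile Confidence level in percent, in (0, 100).
#' @param method `"envelope"` (default) or `"fraction"`.
#' @return The point-of-stability sample size, or `NA` if the corridor is
#'   never permanently entered.
#' @export
point_of_stability <- function(scan, r_true, w, percentile = 95,
                               method = c("envelope", "fraction")) {
  method <- match.arg(method)
  if (w <= 0) stopf("corridor width must be > 0")
  if (percentile <= 0 || percentile >= 100) stopf("percentile must be in (0, 100)")
  lo <- max(-1, r_true - w)
  hi <- min(1, r_true + w)
  m <- scan$metrics
  inside <- vapply(scan$grid, function(n) {
    r <- m$r[m$n == n & !is.na(m$r)]
    if (!length(r)) return(FALSE)
    if (method == "envelope") {
      ci <- central_interval(r, percentile)
      ci[1] >= lo && ci[2] <= hi
    } else {
      mean(r >= lo & r <= hi) >= percentile / 100
    }
  }, logical(1))
  # smallest n such that every n' >= n is inside
  ok_from <- rev(cumprod(rev(inside))) == 1
  if (!any(ok_from)) return(NA_integer_)
  as.integer(scan$grid[which(ok_from)[1]])
}

#' Corridor-of-stability table over widths and percentiles
#'
#' Computes the plateau correlation once, then the point of stability for the
#' cross product of corridor widths and percentile levels. Defaults follow
#' Cohen's small/medium/large effect-size widths (0.10, 0.15, 0.20) and the
#' 80/90/95% levels, giving a nine-row table.
#'
#' @param scan A `samplesize_scan`.
#' @param widths Corridor half-widths.
#' @param percentiles Confidence levels in percent.
#' @param tail_points Tail length for [estimate_true_correlation()].
#' @param method Passed to [point_of_stability()].
#' @return A list of class `stability_result`: `r_true` (a `true_correlation`)
#'   and `table` (data.frame: `width`, `percentile`, `pos_n`, `r_true`,
#'   `plateau_flag`).
#' @export
stability_table <- function(scan, widths = c(0.10, 0.15, 0.20),
                            percentiles = c(80, 90, 95), tail_points = 10,
                            method = "envelope") {
  if (!length(widths) || !length(percentiles)) {
    stopf("widths and percentiles must be non-empty")
  }
  summ <- summarize_scan(scan)
  rt <- estimate_true_correlation(summ, tail_points = tail_points)
  tab <- expand.grid(percentile = percentiles, width = widths,
                     KEEP.OUT.ATTRS = FALSE)[, c("width", "percentile")]
  tab$pos_n <- vapply(seq_len(nrow(tab)), function(i) {
    p <- point_of_stability(scan, rt$r_true, tab$width[i], tab$percentile[i],
                            method = method)
    if (is.na(p)) NA_integer_ else as.integer(p)
  }, integer(1))
  tab$r_true <- rt$r_true
  tab$plateau_flag <- if (rt$plateaued) "plateaued" else "not_plateaued"
  structure(list(r_true = rt, table = tab, method = method),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  print(x$r_true)
  tab <- x$table
  tab$pos_n[is.na(tab$pos_n)] <- NA
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a stability table as TSV
#'
#' `NA` points of stability are written as the literal string `"NA"`.
#'
#' @param result A `stability_result`.
#' @param path Output path.
#' @export
write_stability_table <- function(result, path) {
  data.table::fwrite(result$table, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(result)
}
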