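# Fixtures and independent oracles used across the suite. Oracles are written
# from first principles and never call the code paths they check.

# Small deterministic dataset built directly (not via the simulator).
tiny_dataset <- function(n = 20, p = 5, seed = 1, age_range = c(10, 50)) {
  set.seed(seed)
  ages <- seq(age_range[1], age_range[2], length.out = n)
  sexes <- rep_len(c("F", "M"), n)
  betas <- matrix(round(runif(n * p), 6), n, p)
  # first CpG tracks age so clocks have something to find
  betas[, 1] <- round((ages - age_range[1]) / diff(age_range), 6)
  methylation_dataset(betas, ages, sexes,
                      sample_ids = sprintf("S%02d", seq_len(n)),
                      cpg_ids = paste0("cg", seq_len(p)))
}

# Build a samplesize_scan object directly from a grid and an
# iterations-by-grid matrix of correlations (for stability-module tests).
fake_scan <- function(grid, r_matrix, mae_matrix = NULL, cpgs_matrix = NULL) {
  iterations <- nrow(r_matrix)
  if (is.null(mae_matrix)) mae_matrix <- matrix(1, iterations, length(grid))
  if (is.null(cpgs_matrix)) cpgs_matrix <- matrix(10, iterations, length(grid))
  metrics <- do.call(rbind, lapply(seq_along(grid), function(i) {
    data.frame(n = grid[i], iteration = seq_len(iterations),
               r = r_matrix[, i], mae = mae_matrix[, i],
               relative_mae_pct = mae_matrix[, i], n_cpgs = cpgs_matrix[, i])
  }))
  structure(list(metrics = metrics,
                 config = scan_config(n_min = min(grid), n_max = max(grid),
                                      iterations = iterations),
                 grid = grid, reference_max_age = 100),
            class = "samplesize_scan")
}

# Build a window_scan object directly from per-window mean MAEs.
fake_window_scan <- function(N, fraction, mean_maes, baseline_mean = 2,
                             baseline_sd = 0.5) {
  k <- round(fraction * N)
  stopifnot(length(mean_maes) == N - k + 1)
  windows <- data.frame(fraction = fraction, start = 0:(N - k), k = k,
                        mean_mae = mean_maes,
                        relative_mae_pct = mean_maes,
                        d = (mean_maes - baseline_mean) / baseline_sd,
                        n_iter = 1L)
  structure(list(baseline = list(values = numeric(0), mean = baseline_mean,
                                 sd = baseline_sd),
                 windows = windows, fractions = fraction,
                 infeasible_fractions = numeric(0), N = N,
                 evaluate_on = "removed", reference_max_age = 100),
            class = "window_scan")
}

# Brute-force two-sided KS distance between the ECDF of x and the
# Uniform(min(x), max(x)) CDF, by enumeration over the sorted points.
brute_ks_uniform <- function(x) {
  x <- sort(x)
  n <- length(x)
  cdf <- (x - x[1]) / (x[n] - x[1])
  max(pmax(abs(seq_len(n) / n - cdf), abs((seq_len(n) - 1) / n - cdf)))
}

# Independent linear-interpolation percentile of sorted values (the
# "sort-and-index" estimator with h = (n - 1) * p).
brute_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(x[n])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

# Pearson correlation from first principles (raw sums only).
brute_cor <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Elastic-net stationarity (KKT) violation of a fitted clock at its chosen
# lambda, from the subgradient conditions of the solved objective: predictors
# centred and (optionally) scaled to unit 1/n-variance, response scaled to
# unit 1/n-variance (the reference solver's documented gaussian scaling, which
# divides the L2 penalty term by sd(y) on the original response scale).
# Returns max over coefficients of the stationarity violation, plus the
# intercept condition |mean residual|.
kkt_violation <- function(ds, train, model, standardize = TRUE) {
  x <- ds$betas[train, , drop = FALSE]
  y <- ds$ages[train]
  n <- nrow(x)
  beta <- stats::setNames(numeric(ncol(x)), colnames(x))
  beta[names(model$coefficients)] <- model$coefficients
  mu <- colMeans(x)
  sdx <- if (standardize) sqrt(colMeans(sweep(x, 2, mu)^2)) else rep(1, ncol(x))
  sy <- sqrt(mean((y - mean(y))^2))
  xs <- sweep(sweep(x, 2, mu), 2, sdx, "/")
  bs <- beta * sdx
  r <- y - model$intercept - as.numeric(x %*% beta)
  grad <- as.numeric(crossprod(xs, r)) / n
  lam <- model$lambda
  alpha <- model$alpha
  viol <- vapply(seq_along(beta), function(j) {
    if (bs[j] != 0) {
      abs(grad[j] - lam * (alpha * sign(bs[j]) + (1 - alpha) * bs[j] / sy))
    } else {
      max(0, abs(grad[j]) - lam * alpha)
    }
  }, numeric(1))
  max(c(viol, abs(mean(r))))
}

# Brute-force point of stability: for every grid n, recheck envelope
# containment at all larger n using the independent percentile oracle.
brute_pos <- function(scan, r_true, w, percentile) {
  lo_p <- (100 - percentile) / 200
  corridor <- c(max(-1, r_true - w), min(1, r_true + w))
  inside <- vapply(scan$grid, function(n) {
    r <- scan$metrics$r[scan$metrics$n == n]
    r <- r[!is.na(r)]
    brute_percentile(r, lo_p) >= corridor[1] &&
      brute_percentile(r, 1 - lo_p) <= corridor[2]
  }, logical(1))
  for (i in seq_along(scan$grid)) {
    if (all(inside[i:length(inside)])) return(scan$grid[i])
  }
  NA_integer_
}
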