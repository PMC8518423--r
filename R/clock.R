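#' Sex-stratified train/test split
#'
#' Within each sex, `floor(train_fraction * n_sex + 0.5)` samples are assigned
#' to training at random. If the resulting global training count differs from
#' `round(train_fraction * N)`, one sample of the larger sex is moved (chosen
#' by the seeded RNG), so stratification is preserved to within one sample.
#'
#' @param ds A `methylation_dataset`.
#' @param train_fraction Fraction of samples to train on, in (0, 1).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param indices Optional subset of sample indices to partition (defaults to
#'   all samples), so subsampled Monte-Carlo iterations reuse the same code.
#' @return A list of class `split_plan` with disjoint, covering
#'   `train_indices` and `test_indices` (indices into `ds`).
#' @export
stratified_split <- function(ds, train_fraction = 0.7, seed = 1,
                             indices = seq_len(n_samples(ds))) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stopf("train_fraction must be in (0, 1)")
  }
  sexes <- ds$sexes[indices]
  counts <- table(factor(sexes, levels = c("F", "M")))
  if (any(counts < 2)) {
    stopf("sex class '%s' has fewer than 2 samples", names(counts)[counts < 2][1])
  }
  n_total <- length(indices)
  target_total <- round(train_fraction * n_total)

  with_seed(seed, {
    train <- integer(0)
    for (s in names(counts)) {
      idx_s <- indices[sexes == s]
      n_train_s <- floor(train_fraction * length(idx_s) + 0.5)
      train <- c(train, sample(idx_s, n_train_s))
    }
    if (length(train) != target_total) {
      larger <- names(counts)[which.max(counts)]
      pool_larger <- indices[sexes == larger]
      if (length(train) > target_total) {
        drop <- sample(intersect(train, pool_larger), length(train) - target_total)
        train <- setdiff(train, drop)
      } else {
        add <- sample(setdiff(pool_larger, train), target_total - length(train))
        train <- c(train, add)
      }
    }
    train <- sort(train)
    test <- setdiff(indices, train)
    if (length(train) == 0 || length(test) == 0) {
      stopf("split leaves an empty train or test set (n = %d)", n_total)
    }
    structure(list(train_indices = train, test_indices = test,
                   train_fraction = train_fraction),
              class = "split_plan")
  })
}

#' Fit an elastic-net epigenetic clock
#'
#' Minimises `(1/(2n)) * sum((age - b0 - x %*% b)^2) +
#' lambda * (alpha * ||b||_1 + (1 - alpha)/2 * ||b||_2^2)` over a 100-point
#' log-spaced lambda path down to `0.001 * lambda_max`, with predictors
#' standardised internally and coefficients reported on the original beta
#' scale. Lambda is chosen by k-fold cross-validation with seeded fold
#' assignment; folds are not sex-balanced. CpGs with zero variance in the
#' training split are dropped before fitting (standardisation undefined).
#'
#' @param ds A `methylation_dataset`.
#' @param train Integer indices of the training samples.
#' @param alpha Elastic-net mixing parameter in `[0, 1]` (0.5 by default:
#'   equal L1/L2 weighting, the standard epigenetic-clock setting).
#' @param cv_folds Number of cross-validation folds (default 10).
#' @param seed Integer seed driving fold assignment.
#' @param lambda_rule `"min"` (lambda at minimum mean CV error; default) or
#'   `"1se"` (largest lambda within one standard error of the minimum).
#' @param standardize Standardise predictors to unit variance before
#'   penalisation (default TRUE).
#' @return A list of class `clock_model`: `intercept`, `coefficients` (named
#'   numeric, nonzero entries only), `alpha`, `lambda`, `n_train`, `cv_folds`,
#'   `lambda_rule`, `n_dropped_cpgs`.
#' @export
fit_clock <- function(ds, train, alpha = 0.5, cv_folds = 10, seed = 1,
                      lambda_rule = c("min", "1se"), standardize = TRUE) {
  lambda_rule <- match.arg(lambda_rule)
  n_train <- length(train)
  if (cv_folds < 3) stopf("cv_folds must be >= 3")
  if (n_train < cv_folds) {
    stopf("training set (%d) smaller than cv_folds (%d)", n_train, cv_folds)
  }
  y <- ds$ages[train]
  if (length(unique(y)) < 2) stopf("constant age in training set")
  x <- ds$betas[train, , drop = FALSE]

  keep <- matrixStats_colVars(x) > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0) stopf("no CpG varies in the training set")

  with_seed(seed, {
    foldid <- sample(rep_len(seq_len(cv_folds), n_train))
    cv <- glmnet::cv.glmnet(
      x, y, alpha = alpha, foldid = foldid, family = "gaussian",
      nlambda = 100, lambda.min.ratio = 0.001,
      standardize = standardize, grouped = FALSE,
      thresh = 1e-10 # tight convergence so coefficients satisfy KKT to ~1e-4
    )
    lambda <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
    co <- stats::coef(cv, s = lambda)
    coefs <- as.numeric(co)[-1]
    names(coefs) <- rownames(co)[-1]
    coefs <- coefs[coefs != 0]
    structure(
      list(intercept = as.numeric(co[1]), coefficients = coefs,
           alpha = alpha, lambda = lambda, n_train = n_train,
           cv_folds = cv_folds, lambda_rule = lambda_rule,
           n_dropped_cpgs = n_dropped),
      class = "clock_model"
    )
  })
}

# colVars without extra dependencies; training matrices are modest
matrixStats_colVars <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  colSums(x^2) / n - mu^2
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf(
    "clock_model: %d CpGs | alpha = %.2f, lambda = %.4g (%s rule) | trained on %d samples\n",
    length(x$coefficients), x$alpha, x$lambda, x$lambda_rule, x$n_train))
  invisible(x)
}

#' Serialize / restore a clock model as JSON
#'
#' @param model A `clock_model`.
#' @param path File path to write to / read from.
#' @return `read_clock_model` returns the restored `clock_model`.
#' @export
write_clock_model <- function(model, path) {
  out <- unclass(model)
  out$coefficients <- as.list(out$coefficients) # named vectors lose names in JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname write_clock_model
#' @export
read_clock_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$coefficients <- unlist(raw$coefficients)
  if (is.null(raw$coefficients)) raw$coefficients <- stats::setNames(numeric(0), character(0))
  structure(raw, class = "clock_model")
}

#' Predict ages from a fitted clock
#'
#' `prediction_i = intercept + sum_j coef_j * beta_ij`.
#'
#' @param model A `clock_model`.
#' @param ds A `methylation_dataset` containing every CpG the model uses.
#' @param indices Sample indices to predict for (default: all).
#' @return Named numeric vector of predicted ages.
#' @export
predict_ages <- function(model, ds, indices = seq_len(n_samples(ds))) {
  cpgs <- names(model$coefficients)
  missing_cpg <- setdiff(cpgs, ds$cpg_ids)
  if (length(missing_cpg)) {
    stopf("model CpG '%s' absent from dataset", missing_cpg[1])
  }
  pred <- rep(model$intercept, length(indices))
  if (length(cpgs)) {
    pred <- pred + as.numeric(ds$betas[indices, cpgs, drop = FALSE] %*%
                                model$coefficients)
  }
  stats::setNames(pred, ds$sample_ids[indices])
}

#' Evaluate age predictions
#'
#' @param predicted,actual Equal-length numeric age vectors (length >= 2).
#' @param reference_max_age Oldest age in the reference dataset; the relative
#'   error is `100 * mae / reference_max_age`.
#' @param n_selected_cpgs Optional count of CpGs in the model that produced
#'   `predicted`, copied into the metrics.
#' @return A list of class `model_metrics`: `pearson_r` (`NA` when `actual` is
#'   constant, with a warning), `mae`, `relative_mae_pct`, `n_selected_cpgs`.
#' @export
evaluate_predictions <- function(predicted, actual, reference_max_age,
                                 n_selected_cpgs = NA_integer_) {
  if (length(predicted) != length(actual)) stopf("length mismatch")
  if (length(actual) < 2) stopf("need at least 2 observations")
  if (reference_max_age <= 0) stopf("reference_max_age must be positive")
  mae <- mean(abs(predicted - actual))
  if (stats::sd(actual) == 0) {
    warnf("actual ages are constant; Pearson r undefined")
    r <- NA_real_
  } else if (stats::sd(predicted) == 0) {
    r <- NA_real_
  } else {
    r <- stats::cor(predicted, actual)
  }
  structure(
    list(pearson_r = r, mae = mae,
         relative_mae_pct = 100 * mae / reference_max_age,
         n_selected_cpgs = as.integer(n_selected_cpgs)),
    class = "model_metrics"
  )
}
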