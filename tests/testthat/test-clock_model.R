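test_that("stratified splits hit exact per-sex counts", {
  ds100 <- tiny_dataset(n = 100, p = 2)
  sp <- stratified_split(ds100, 0.7, seed = 1)
  expect_length(sp$train_indices, 70)
  expect_length(sp$test_indices, 30)
  expect_equal(sum(ds100$sexes[sp$train_indices] == "F"), 35)
  expect_equal(sum(ds100$sexes[sp$train_indices] == "M"), 35)

  ds4 <- tiny_dataset(n = 4, p = 2)
  sp4 <- stratified_split(ds4, 0.5, seed = 2)
  expect_length(sp4$train_indices, 2)
  expect_setequal(ds4$sexes[sp4$train_indices], c("F", "M"))
})

test_that("splits partition the samples and stratify within one per sex", {
  for (case in list(c(30, 0.7, 1), c(45, 0.5, 2), c(101, 0.8, 3),
                    c(27, 0.3, 4), c(60, 0.66, 5))) {
    n <- case[1]; f <- case[2]; seed <- case[3]
    ds <- tiny_dataset(n = n, p = 2, seed = seed)
    sp <- stratified_split(ds, f, seed = seed)
    expect_length(intersect(sp$train_indices, sp$test_indices), 0)
    expect_setequal(c(sp$train_indices, sp$test_indices), seq_len(n))
    for (s in c("F", "M")) {
      n_s <- sum(ds$sexes == s)
      got <- sum(ds$sexes[sp$train_indices] == s)
      expect_lte(abs(got / n_s - f), 1 / n_s + 1e-12)
    }
    expect_identical(stratified_split(ds, f, seed = seed), sp)
  }
  one_sex <- methylation_dataset(matrix(runif(6), 3, 2), c(10, 20, 30),
                                 c("F", "F", "F"))
  expect_error(stratified_split(one_sex, 0.7, seed = 1), "fewer than 2")
})

test_that("fitted clocks satisfy elastic-net stationarity (KKT) conditions", {
  # 8-sample, 3-CpG instances, checked by an independent subgradient oracle
  for (seed in 1:5) {
    set.seed(seed)
    betas <- matrix(runif(24), 8, 3)
    ages <- round(20 + 60 * betas[, 1] + rnorm(8, 0, 3), 2)
    ages <- pmax(ages, 1)
    ds <- methylation_dataset(betas, ages, rep_len(c("F", "M"), 8))
    model <- fit_clock(ds, train = 1:8, alpha = 0.5, cv_folds = 4, seed = seed)
    expect_lt(kkt_violation(ds, 1:8, model), 1e-4)
  }
})

test_that("clocks record their configuration and recover a noise-free CpG", {
  # cg1 carries the age signal without noise; the other CpGs are age-free
  ds <- tiny_dataset(n = 60, p = 5, seed = 4)
  sp <- stratified_split(ds, 0.7, seed = 1)
  model <- fit_clock(ds, sp$train_indices, alpha = 0.5, cv_folds = 10, seed = 1)
  expect_equal(model$alpha, 0.5)
  expect_equal(model$cv_folds, 10)
  expect_equal(model$n_train, length(sp$train_indices))
  expect_true("cg1" %in% names(model$coefficients))
  pred <- predict_ages(model, ds, sp$test_indices)
  m <- evaluate_predictions(pred, ds$ages[sp$test_indices], max(ds$ages))
  expect_gt(m$pearson_r, 0.999)

  expect_identical(fit_clock(ds, sp$train_indices, seed = 7),
                   fit_clock(ds, sp$train_indices, seed = 7))
})

test_that("degenerate training inputs are rejected", {
  ds <- tiny_dataset(n = 12, p = 3)
  expect_error(fit_clock(ds, 1:5, cv_folds = 10), "smaller than cv_folds")
  expect_error(fit_clock(ds, 1:10, cv_folds = 2), "cv_folds must be >= 3")
  const <- methylation_dataset(matrix(runif(40), 20, 2),
                               c(rep(30, 19), 31), rep_len(c("F", "M"), 20))
  expect_error(fit_clock(const, 1:19, cv_folds = 5), "constant age")
})

test_that("predictions are the exact linear form", {
  ds <- tiny_dataset(n = 10, p = 4)
  const_model <- structure(
    list(intercept = 42, coefficients = setNames(numeric(0), character(0)),
         alpha = 0.5, lambda = 1, n_train = 10, cv_folds = 10,
         lambda_rule = "min", n_dropped_cpgs = 0L), class = "clock_model")
  expect_equal(unname(predict_ages(const_model, ds)), rep(42, 10))

  one <- const_model
  one$intercept <- 10
  one$coefficients <- c(cg1 = 20)
  ds1 <- ds
  ds1$betas[, "cg1"] <- 0.5
  expect_equal(unname(predict_ages(one, ds1)), rep(20, 10))

  # dot-product oracle on a random dense model
  set.seed(8)
  rnd <- const_model
  rnd$intercept <- 5
  rnd$coefficients <- setNames(rnorm(4), ds$cpg_ids)
  expected <- vapply(seq_len(10), function(i) {
    s <- 5
    for (j in seq_len(4)) s <- s + rnd$coefficients[j] * ds$betas[i, j]
    s
  }, numeric(1))
  expect_equal(unname(predict_ages(rnd, ds)), unname(expected),
               tolerance = 1e-12)

  bad <- const_model
  bad$coefficients <- c(cg99 = 1)
  expect_error(predict_ages(bad, ds), "cg99")
})

test_that("prediction metrics follow their definitions", {
  actual <- c(10, 20, 30, 40)
  m <- evaluate_predictions(actual, actual, 88)
  expect_equal(m$pearson_r, 1)
  expect_equal(m$mae, 0)
  expect_equal(m$relative_mae_pct, 0)

  shifted <- evaluate_predictions(actual + 2, actual, 88)
  expect_equal(shifted$mae, 2)
  expect_equal(shifted$pearson_r, 1)

  # mae 4.4 against reference max age 88 is a 5% relative error
  m2 <- evaluate_predictions(c(14.4, 15.6, 34.4, 35.6), c(10, 20, 30, 40), 88)
  expect_equal(m2$mae, 4.4)
  expect_equal(m2$relative_mae_pct, 5.0)

  expect_warning(mc <- evaluate_predictions(c(1, 2, 3), rep(5, 3), 88),
                 "constant")
  expect_true(is.na(mc$pearson_r))

  # r is invariant to positive affine transforms of the predictions
  set.seed(9)
  p <- rnorm(20); a <- rnorm(20)
  r0 <- evaluate_predictions(p, a, 88)$pearson_r
  r1 <- evaluate_predictions(3 * p + 7, a, 88)$pearson_r
  expect_equal(r0, r1, tolerance = 1e-12)
})

test_that("clock models serialize to JSON and back", {
  ds <- tiny_dataset(n = 30, p = 5)
  model <- fit_clock(ds, 1:21, cv_folds = 5, seed = 2)
  path <- tempfile(fileext = ".json")
  write_clock_model(model, path)
  back <- read_clock_model(path)
  expect_equal(back$intercept, model$intercept)
  expect_equal(back$coefficients, model$coefficients)
  expect_equal(back$lambda, model$lambda, tolerance = 1e-12)
  expect_equal(back$lambda_rule, model$lambda_rule)
  expect_equal(predict_ages(back, ds), predict_ages(model, ds))
})
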