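test_that("datasets round-trip through delimited files exactly", {
  ds <- tiny_dataset(n = 8, p = 3)
  mp <- tempfile(fileext = ".tsv")
  mdp <- tempfile(fileext = ".tsv")
  for (orientation in c("cpg_rows", "sample_rows")) {
    write_methylation_dataset(ds, mp, mdp, orientation = orientation)
    back <- read_methylation_dataset(mp, mdp, orientation = orientation)
    expect_identical(back$sample_ids, ds$sample_ids)
    expect_identical(back$cpg_ids, ds$cpg_ids)
    expect_identical(back$sexes, ds$sexes)
    expect_equal(back$ages, ds$ages)
    expect_identical(back$betas, ds$betas)
  }
})

test_that("samples are returned in metadata order and mismatches are named", {
  ds <- tiny_dataset(n = 6, p = 3)
  mp <- tempfile(fileext = ".tsv")
  mdp <- tempfile(fileext = ".tsv")
  write_methylation_dataset(ds, mp, mdp)
  meta <- read.delim(mdp)
  meta <- meta[rev(seq_len(nrow(meta))), ]
  write.table(meta, mdp, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- read_methylation_dataset(mp, mdp)
  expect_identical(back$sample_ids, rev(ds$sample_ids))
  expect_identical(back$betas, ds$betas[rev(ds$sample_ids), ])

  meta <- rbind(meta, data.frame(sample_id = "S9", age = 33, sex = "F"))
  write.table(meta, mdp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_methylation_dataset(mp, mdp), "S9")
})

test_that("malformed matrices are rejected with informative errors", {
  ds <- tiny_dataset(n = 5, p = 3)
  expect_error(
    methylation_dataset(ds$betas, ds$ages, ds$sexes,
                        sample_ids = rep("A", 5), cpg_ids = ds$cpg_ids),
    "duplicate sample id")
  b <- ds$betas
  b[2, 3] <- 1.5
  expect_error(methylation_dataset(b, ds$ages, ds$sexes), "outside")
  expect_error(methylation_dataset(ds$betas, rep(30, 5), ds$sexes), "distinct")
  expect_error(methylation_dataset(ds$betas, ds$ages, rep("unknown", 5)),
               "unrecognised sex")
  # values within 1e-9 of the interval are clamped, not rejected
  b <- ds$betas
  b[1, 1] <- 1 + 1e-10
  b[2, 2] <- -1e-10
  clamped <- methylation_dataset(b, ds$ages, ds$sexes)
  expect_equal(clamped$betas[1, 1], 1)
  expect_equal(clamped$betas[2, 2], 0)
})

test_that("CpGs with missing betas are dropped on read, with a warning", {
  ds <- tiny_dataset(n = 6, p = 4)
  b <- ds$betas
  b[3, 2] <- NA
  ds_na <- suppressWarnings(methylation_dataset(b, ds$ages, ds$sexes))
  mp <- tempfile(fileext = ".tsv")
  mdp <- tempfile(fileext = ".tsv")
  write_methylation_dataset(ds_na, mp, mdp)
  expect_warning(back <- read_methylation_dataset(mp, mdp), "1 CpG")
  expect_identical(back$cpg_ids, ds$cpg_ids[-2])
})

test_that("chromosome filtering removes exactly the excluded probes", {
  ds <- tiny_dataset(n = 6, p = 5)
  ann_none <- probe_annotation(ds$cpg_ids, rep("1", 5))
  expect_identical(filter_probes_by_chromosome(ds, ann_none, c("X", "Y")), ds)

  ann <- probe_annotation(ds$cpg_ids, c("1", "X", "2", "X", "3"))
  filtered <- filter_probes_by_chromosome(ds, ann, "X")
  expect_identical(filtered$cpg_ids, ds$cpg_ids[c(1, 3, 5)])
  expect_identical(filtered$betas, ds$betas[, c(1, 3, 5)])
  expect_identical(filtered$sample_ids, ds$sample_ids)

  # unannotated probes are retained with a warning
  ann_partial <- probe_annotation(ds$cpg_ids[1:3], c("X", "1", "1"))
  expect_warning(kept <- filter_probes_by_chromosome(ds, ann_partial, "X"),
                 "missing from annotation")
  expect_identical(kept$cpg_ids, ds$cpg_ids[2:5])

  ann_all <- probe_annotation(ds$cpg_ids, rep("X", 5))
  expect_error(filter_probes_by_chromosome(ds, ann_all, "X"), "every CpG")
})

test_that("chromosome filtering is idempotent and commutes over disjoint sets", {
  ds <- tiny_dataset(n = 6, p = 8)
  set.seed(4)
  ann <- probe_annotation(ds$cpg_ids, sample(c("1", "2", "X", "Y"), 8, TRUE))
  once <- filter_probes_by_chromosome(ds, ann, "X")
  expect_identical(filter_probes_by_chromosome(once, ann, "X"), once)
  xy1 <- filter_probes_by_chromosome(filter_probes_by_chromosome(ds, ann, "X"),
                                     ann, "Y")
  xy2 <- filter_probes_by_chromosome(filter_probes_by_chromosome(ds, ann, "Y"),
                                     ann, "X")
  xy3 <- filter_probes_by_chromosome(ds, ann, c("X", "Y"))
  expect_identical(xy1, xy2)
  expect_identical(xy1, xy3)
})

test_that("age distribution summary matches moment and KS oracles", {
  # symmetric ages: skewness exactly 0
  sym <- age_distribution_summary(c(10, 20, 30, 40, 50))
  expect_equal(sym$skewness, 0, tolerance = 1e-12)
  expect_equal(sym$range, c(10, 50))
  expect_equal(sym$n, 5)

  # i.i.d. uniform draws: excess kurtosis near -1.2
  set.seed(11)
  u <- runif(10000, 20, 80)
  summ <- age_distribution_summary(u)
  expect_lt(abs(summ$excess_kurtosis - (-1.2)), 0.1)
  expect_lt(abs(summ$skewness), 0.1)

  # KS statistic equals brute-force ECDF enumeration
  expect_equal(age_distribution_summary(c(10, 20, 30, 40))$uniform_ks_statistic,
               brute_ks_uniform(c(10, 20, 30, 40)))
  for (seed in 1:5) {
    set.seed(seed)
    x <- rbeta(30, 2, 5) * 60 + 10
    expect_equal(age_distribution_summary(x)$uniform_ks_statistic,
                 brute_ks_uniform(x), tolerance = 1e-12)
  }

  expect_error(age_distribution_summary(rep(5, 10)), "constant")
  expect_error(age_distribution_summary(c(1, 2)), "at least 3")
})
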