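#' Construct a methylation dataset
#'
#' The canonical in-memory container for a methylation study: a sample-by-CpG
#' matrix of beta values (methylation fractions in `[0, 1]`) together with
#' per-sample age and sex. All pipeline stages operate on this object.
#'
#' @param betas Numeric matrix, samples in rows, CpGs in columns, values in
#'   `[0, 1]`. Row and column names are taken from `sample_ids` / `cpg_ids`
#'   when those are given, else from `dimnames(betas)`.
#' @param ages Numeric vector of per-sample ages, finite and non-negative.
#' @param sexes Character vector of per-sample sex labels; `"F"`, `"female"`,
#'   `"M"`, `"male"` are accepted case-insensitively and normalised to
#'   `"F"`/`"M"`.
#' @param sample_ids,cpg_ids Unique identifier vectors; default to the
#'   dimnames of `betas`.
#' @param age_unit Free-text unit carried with the ages (e.g. `"years"`,
#'   `"weeks"`); never converted.
#' @return An object of class `methylation_dataset`: a list with elements
#'   `sample_ids`, `ages`, `sexes`, `cpg_ids`, `betas`, `age_unit`.
#' @export
methylation_dataset <- function(betas, ages, sexes, sample_ids = rownames(betas),
                                cpg_ids = colnames(betas), age_unit = "years") {
  betas <- as.matrix(betas)
  if (!is.numeric(betas)) stopf("beta matrix must be numeric")
  n <- nrow(betas)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  if (is.null(cpg_ids)) cpg_ids <- paste0("cg", seq_len(ncol(betas)))
  sample_ids <- as.character(sample_ids)
  cpg_ids <- as.character(cpg_ids)
  if (anyDuplicated(sample_ids)) {
    stopf("duplicate sample id: '%s'", sample_ids[duplicated(sample_ids)][1])
  }
  if (anyDuplicated(cpg_ids)) {
    stopf("duplicate CpG id: '%s'", cpg_ids[duplicated(cpg_ids)][1])
  }
  if (length(sample_ids) != n || length(ages) != n || length(sexes) != n) {
    stopf("sample_ids, ages, sexes and matrix rows must all have length %d", n)
  }
  ages <- as.numeric(ages)
  if (any(!is.finite(ages)) || any(ages < 0)) {
    stopf("all ages must be finite and >= 0")
  }
  if (length(unique(ages)) < 2) stopf("need at least 2 distinct ages")
  sexes <- normalize_sex(sexes)

  # values within 1e-9 of the unit interval are clamped; worse is an error
  tol <- 1e-9
  ok <- is.na(betas) | (betas >= -tol & betas <= 1 + tol)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stopf("beta value %g at (%s, %s) outside [0,1]",
          betas[bad[1], bad[2]], sample_ids[bad[1]], cpg_ids[bad[2]])
  }
  betas[betas < 0] <- 0
  betas[betas > 1] <- 1
  dimnames(betas) <- list(sample_ids, cpg_ids)

  structure(
    list(sample_ids = sample_ids, ages = ages, sexes = sexes,
         cpg_ids = cpg_ids, betas = betas, age_unit = age_unit),
    class = "methylation_dataset"
  )
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat(sprintf("methylation_dataset: %d samples x %d CpGs\n",
              length(x$sample_ids), length(x$cpg_ids)))
  cat(sprintf("  ages: %.3g-%.3g %s | sex: %d F, %d M\n",
              min(x$ages), max(x$ages), x$age_unit,
              sum(x$sexes == "F"), sum(x$sexes == "M")))
  invisible(x)
}

#' Number of samples in a methylation dataset
#' @param ds A `methylation_dataset`.
#' @export
n_samples <- function(ds) length(ds$sample_ids)

normalize_sex <- function(sexes) {
  s <- toupper(trimws(as.character(sexes)))
  s[s == "FEMALE"] <- "F"
  s[s == "MALE"] <- "M"
  bad <- !(s %in% c("F", "M"))
  if (any(bad)) stopf("unrecognised sex label '%s'", sexes[bad][1])
  s
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  data.table::fread(path, header = TRUE, data.table = FALSE, check.names = FALSE)
}

#' Read a methylation matrix and sample metadata from delimited files
#'
#' The matrix is a TSV/CSV with identifiers in the first column and the other
#' axis's identifiers as the header (series-matrix style when CpGs are rows);
#' gzip is handled transparently. Metadata must carry columns `sample_id`,
#' `age`, `sex`. Samples are returned in metadata order. CpGs with any missing
#' beta are dropped with a warning, and values within 1e-9 of `[0, 1]` are
#' clamped into it.
#'
#' @param matrix_path Path to the beta matrix.
#' @param metadata_path Path to the sample metadata table.
#' @param orientation `"cpg_rows"` (default; CpGs in rows, samples in columns)
#'   or `"sample_rows"`.
#' @param age_unit Free-text age unit recorded on the dataset.
#' @return A [methylation_dataset()].
#' @export
read_methylation_dataset <- function(matrix_path, metadata_path,
                                     orientation = c("cpg_rows", "sample_rows"),
                                     age_unit = "years") {
  orientation <- match.arg(orientation)
  meta <- read_table_auto(metadata_path)
  need <- c("sample_id", "age", "sex")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    stopf("metadata lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    stopf("duplicate sample id in metadata: '%s'",
          meta$sample_id[duplicated(meta$sample_id)][1])
  }

  tab <- read_table_auto(matrix_path)
  row_ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(!vapply(tab[-1], is.numeric, logical(1)))[1]
    cell <- which(is.na(suppressWarnings(as.numeric(tab[[bad + 1]]))) &
                    !is.na(tab[[bad + 1]]))[1]
    stopf("non-numeric beta value in column '%s', row %s",
          names(tab)[bad + 1], if (is.na(cell)) "?" else as.character(cell))
  }
  rownames(mat) <- row_ids

  if (orientation == "cpg_rows") mat <- t(mat)
  # now samples x CpGs
  matrix_samples <- rownames(mat)
  unknown <- setdiff(matrix_samples, meta$sample_id)
  if (length(unknown)) {
    stopf("matrix sample '%s' absent from metadata", unknown[1])
  }
  absent <- setdiff(meta$sample_id, matrix_samples)
  if (length(absent)) {
    stopf("metadata sample '%s' absent from matrix", absent[1])
  }
  mat <- mat[meta$sample_id, , drop = FALSE]

  drop <- colSums(is.na(mat)) > 0
  if (any(drop)) {
    warnf("dropping %d CpG(s) with missing beta values", sum(drop))
    mat <- mat[, !drop, drop = FALSE]
    if (ncol(mat) == 0) stopf("all CpGs had missing values")
  }

  methylation_dataset(mat, ages = meta$age, sexes = meta$sex,
                      sample_ids = meta$sample_id, age_unit = age_unit)
}

#' Write a methylation dataset to delimited files
#'
#' Inverse of [read_methylation_dataset()]: writes the beta matrix (CpGs in
#' rows by default) and a `sample_id`/`age`/`sex` metadata table.
#'
#' @inheritParams read_methylation_dataset
#' @param ds A `methylation_dataset`.
#' @export
write_methylation_dataset <- function(ds, matrix_path, metadata_path,
                                      orientation = c("cpg_rows", "sample_rows")) {
  orientation <- match.arg(orientation)
  mat <- if (orientation == "cpg_rows") t(ds$betas) else ds$betas
  id_col <- if (orientation == "cpg_rows") "cpg_id" else "sample_id"
  out <- data.table::data.table(id = rownames(mat))
  data.table::setnames(out, "id", id_col)
  out <- cbind(out, data.table::as.data.table(mat))
  data.table::fwrite(out, matrix_path, sep = "\t")
  data.table::fwrite(
    data.table::data.table(sample_id = ds$sample_ids, age = ds$ages, sex = ds$sexes),
    metadata_path, sep = "\t"
  )
  invisible(ds)
}

#' Read a probe annotation (CpG id to chromosome) table
#'
#' @param path TSV/CSV with columns `cpg_id` and `chromosome`.
#' @return Named character vector mapping CpG id to chromosome label.
#' @export
read_probe_annotation <- function(path) {
  tab <- read_table_auto(path)
  if (!all(c("cpg_id", "chromosome") %in% names(tab))) {
    stopf("annotation needs columns cpg_id, chromosome")
  }
  probe_annotation(tab$cpg_id, tab$chromosome)
}

#' Construct a probe annotation mapping
#'
#' @param cpg_ids Unique CpG identifiers.
#' @param chromosomes Non-empty chromosome labels, one per CpG.
#' @return Named character vector (names = CpG ids, values = chromosomes).
#' @export
probe_annotation <- function(cpg_ids, chromosomes) {
  cpg_ids <- as.character(cpg_ids)
  chromosomes <- as.character(chromosomes)
  if (length(cpg_ids) != length(chromosomes)) {
    stopf("cpg_ids and chromosomes must have equal length")
  }
  if (anyDuplicated(cpg_ids)) {
    stopf("duplicate CpG id in annotation: '%s'", cpg_ids[duplicated(cpg_ids)][1])
  }
  if (any(is.na(chromosomes) | chromosomes == "")) {
    stopf("chromosome labels must be non-empty")
  }
  stats::setNames(chromosomes, cpg_ids)
}

#' Remove probes annotated to excluded chromosomes
#'
#' Sex-chromosome probes are routinely removed before clock fitting so that
#' sex-linked methylation does not masquerade as an age signal. Probes absent
#' from the annotation are retained with a warning.
#'
#' @param ds A `methylation_dataset`.
#' @param ann A [probe_annotation()] (named character vector).
#' @param excluded Character set of chromosome labels to drop, e.g. `c("X", "Y")`.
#' @return The filtered `methylation_dataset`; sample order unchanged, CpG
#'   relative order preserved.
#' @export
filter_probes_by_chromosome <- function(ds, ann, excluded) {
  if (length(excluded) == 0) stopf("excluded chromosome set must be non-empty")
  chrom <- ann[ds$cpg_ids]
  unannotated <- is.na(chrom)
  if (any(unannotated)) {
    warnf("%d probe(s) missing from annotation; retained", sum(unannotated))
  }
  keep <- unannotated | !(chrom %in% excluded)
  if (!any(keep)) stopf("filtering would remove every CpG")
  if (all(keep)) return(ds)
  methylation_dataset(ds$betas[, keep, drop = FALSE], ds$ages, ds$sexes,
                      ds$sample_ids, ds$cpg_ids[keep], ds$age_unit)
}

#' Numeric summary of a dataset's age distribution
#'
#' Clock calibration behaves best when ages cover their range uniformly, so the
#' summary reports the sample skewness and excess kurtosis (moment estimators;
#' a uniform distribution has skewness 0 and excess kurtosis -1.2) and the
#' Kolmogorov-Smirnov distance between the empirical age CDF and the
#' Uniform(min age, max age) CDF.
#'
#' @param ds A `methylation_dataset`, or a numeric vector of ages.
#' @return A list of class `distribution_summary` with `n`, `skewness`,
#'   `excess_kurtosis`, `uniform_ks_statistic`, `range`.
#' @export
age_distribution_summary <- function(ds) {
  ages <- if (inherits(ds, "methylation_dataset")) ds$ages else as.numeric(ds)
  n <- length(ages)
  if (n < 3) stopf("need at least 3 samples to summarise the age distribution")
  rng <- range(ages)
  if (rng[1] == rng[2]) stopf("ages are constant; distribution undefined")
  ks <- suppressWarnings(
    stats::ks.test(ages, "punif", min = rng[1], max = rng[2])$statistic
  )
  structure(
    list(n = n,
         skewness = e1071::skewness(ages, type = 1),
         excess_kurtosis = e1071::kurtosis(ages, type = 1),
         uniform_ks_statistic = unname(ks),
         range = rng),
    class = "distribution_summary"
  )
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf(
    "n = %d | range %.3g-%.3g | skewness %.3f | excess kurtosis %.3f | KS vs uniform %.3f\n",
    x$n, x$range[1], x$range[2], x$skewness, x$excess_kurtosis,
    x$uniform_ks_statistic))
  invisible(x)
}
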