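#' Derive a reproducible per-task seed
#'
#' Mixes a base seed with integer task coordinates (e.g. grid sample size and
#' iteration number) into a single seed below 2^31, so that Monte-Carlo tasks
#' can be executed in any order — or in parallel — with identical results.
#'
#' @param base_seed Integer base seed for the whole run.
#' @param ... Further non-negative integers identifying the task.
#' @return A single integer seed in `[1, 2147483562]`.
#' @export
derive_seed <- function(base_seed, ...) {
  m <- 2147483563 # largest prime below 2^31 keeps products within double precision
  h <- as.numeric(base_seed) %% m
  for (v in c(...)) {
    h <- (h * 1000003 + (as.numeric(v) %% m)) %% m
  }
  as.integer(h) + 1L
}

# Internal: run `expr` with a locally-set RNG state, restoring the caller's.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Internal: stop() with sprintf-style formatting, no call in the condition.
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
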