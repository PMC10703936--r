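# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row variances without matrixStats; X is a numeric matrix.
row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1L)
}

# Deterministic child seed for a named stage, kept below 2^31.
# One root seed fans out into independent streams so a stage can be
# regenerated without replaying the ones before it.
child_seed <- function(seed, stream) {
  offs <- c(pathways = 11L, metadata = 29L, counts = 47L, split = 71L,
            cv = 101L, perm = 131L, resample = 151L, replicate = 173L)
  off <- offs[[stream]] %||% 199L
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

# Draw from Normal(mean, sd) truncated at zero (rejection sampling).
rnorm_trunc0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad) > 0L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x <= 0)
  }
  x
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
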