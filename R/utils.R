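# Internal helpers shared across modules.

.is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == round(x)
}

.is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

.is_prob <- function(x) .is_number(x) && x >= 0 && x <= 1

# Counter-based seed expansion: every stage draws from its own stream so
# pipeline stages are independently reproducible. Kept below 2^31 - 1.
.derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 7919 + counter * 104729) %% 2147483647)
}

# Truncated-normal sampling by resampling; sd = 0 collapses to the
# (range-clamped) mean.
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, lower <= upper)
  if (sd == 0) {
    return(rep(min(max(mean, lower), upper), n))
  }
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
    if (guard > 10000L) {
      stop("truncated-normal resampling failed to converge; ",
           "the truncation range excludes essentially all mass")
    }
  }
  out
}

# FNV-1a hash of a deparsed R object; used to stamp pipeline outputs with a
# short provenance fingerprint without external digest dependencies.
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
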