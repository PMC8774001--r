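## Internal helpers shared across modules.

## Derive a reproducible substream seed from a base seed and integer indices.
## Each (sample, stage) pair gets its own stream so adding a sample never
## perturbs the draws of earlier samples.  Kept below 2^31 - 1.
.substream <- function(seed, ...) {
  idx <- c(...)
  primes <- c(100003, 7919, 104729, 999331, 15485863)
  if (length(idx) > length(primes)) {
    stop("too many substream indices")
  }
  s <- (as.numeric(seed) + sum(as.numeric(idx) * primes[seq_along(idx)])) %%
    2147483647
  as.integer(s)
}

## Deterministic seed for a segmentation interval, independent of the
## recursion path (start/end are bin indices within the chromosome).
.intervalSeed <- function(seed, chromIdx, lo, hi, stage = 0) {
  .substream(seed, chromIdx, lo, hi, stage)
}

.mmLog <- function(fmt, ...) {
  if (isTRUE(getOption("mmscape.quiet", FALSE))) {
    return(invisible(NULL))
  }
  message(sprintf(paste0("INFO [mmscape] ", fmt), ...))
}

## MAD without the 1.4826 consistency constant: ranking is scale-invariant
## either way and the raw median absolute deviation is what the gene
## selection and signature thresholds are defined on.
.madRaw <- function(x) {
  stats::median(abs(x - stats::median(x)))
}

.isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
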