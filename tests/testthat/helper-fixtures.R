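## Shared fixtures: tiny genomes, toy coverage tracks and state profiles,
## all built in code. Generator output is silenced during tests.
options(mmscape.quiet = TRUE)

tinyGenome <- function() {
  makeGenome(c(chr1 = 10e6, chr2 = 6e6))
}

## BinnedCoverage from a plain count vector on one chromosome.
covFromCounts <- function(counts, sampleId = "s", binSize = 100,
                          chrom = "chr1") {
  n <- length(counts)
  binnedCoverage(sampleId, rep(chrom, n), (seq_len(n) - 1) * binSize,
                 seq_len(n) * binSize, counts, binSize)
}

## log2-ratio GRanges track from a numeric vector (NA = masked bin).
ratioTrack <- function(vals, chrom = "chr1", binSize = 100) {
  n <- length(vals)
  gr <- GenomicRanges::GRanges(
    rep(chrom, n),
    IRanges::IRanges((seq_len(n) - 1) * binSize + 1, seq_len(n) * binSize))
  S4Vectors::mcols(gr)$ratio <- vals
  gr
}

## SegmentProfile with given integer states; seg length 10 bins of 10 kb.
profileFromStates <- function(states, chrom = "chr1", sampleId = "s",
                              segBp = 1e5) {
  n <- length(states)
  tab <- data.frame(chrom = rep(chrom, n),
                    start = (seq_len(n) - 1) * segBp,
                    end = seq_len(n) * segBp,
                    state = as.integer(states))
  mmscape:::.profileFromStates(tab, sampleId)
}

## SegmentProfile spanning several chromosomes from a list of state vectors.
profileFromStateList <- function(stateList, sampleId = "s", segBp = 1e5) {
  tabs <- lapply(names(stateList), function(ch) {
    st <- stateList[[ch]]
    data.frame(chrom = ch, start = (seq_along(st) - 1) * segBp,
               end = seq_along(st) * segBp, state = as.integer(st))
  })
  mmscape:::.profileFromStates(do.call(rbind, tabs), sampleId)
}

## Minimal SvCallSet from a record data.frame with defaults filled in.
svSet <- function(df, sampleId = "s") {
  svCallSet(sampleId, df)
}

## Adjusted Rand index (tests compare clusterings up to label permutation).
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  ## contingency-based fallback
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  n <- length(a)
  idx <- s(tab)
  e <- s(rowSums(tab)) * s(colSums(tab)) / choose(n, 2)
  mx <- (s(rowSums(tab)) + s(colSums(tab))) / 2
  (idx - e) / (mx - e)
}
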