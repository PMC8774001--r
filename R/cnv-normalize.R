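#' Pool reference (normal) coverage profiles
#'
#' Sums per-bin counts across reference samples sharing one bin grid, the
#' equivalent of profiling against a pool of normal DNA when no matched
#' normal is available.
#'
#' @param references list of [BinnedCoverage-class] objects on one grid.
#' @return a [BinnedCoverage-class] with summed counts.
#' @export
poolReferences <- function(references) {
  if (!length(references)) {
    stop("at least one reference is required")
  }
  base <- references[[1L]]
  counts <- mcols(bins(base))$count
  for (r in references[-1L]) {
    if (!.sameGrid(base, r)) {
      stop("all references must share the same bin grid")
    }
    counts <- counts + mcols(bins(r))$count
  }
  gr <- bins(base)
  mcols(gr)$count <- counts
  new("BinnedCoverage", sampleId = "pooled_reference", bins = gr,
      binSize = binSize(base), totalReads = sum(counts))
}

#' Per-bin log2 tumor/normal coverage ratio
#'
#' Counts are first normalized to each sample's total read count, then the
#' per-bin log2 ratio of tumor to reference is taken:
#' `log2((t_b / T) / (r_b / R))`. Bins with a zero tumor or reference count
#' are masked (`NA`), not zero-filled, so they are excluded from the
#' segmentation statistics without breaking segment contiguity.
#'
#' @param tumor a [BinnedCoverage-class].
#' @param reference a [BinnedCoverage-class] on the identical bin grid
#'   (matched normal, or the output of [poolReferences()]).
#' @return a `GRanges` on the shared grid with a `ratio` metadata column
#'   (`NA` = masked).
#' @export
normalizeLog2Ratio <- function(tumor, reference) {
  if (!.sameGrid(tumor, reference)) {
    stop("tumor and reference must share the same bin grid")
  }
  tc <- mcols(bins(tumor))$count
  rc <- mcols(bins(reference))$count
  if (all(rc == 0)) {
    stop("reference counts are all zero")
  }
  ratio <- rep(NA_real_, length(tc))
  ok <- tc > 0 & rc > 0
  ratio[ok] <- log2((tc[ok] / totalReads(tumor)) /
                    (rc[ok] / totalReads(reference)))
  nMasked <- sum(!ok)
  if (nMasked) {
    .mmLog("normalizeLog2Ratio(%s): masked %d/%d zero-count bins",
           sampleId(tumor), nMasked, length(tc))
  }
  gr <- bins(tumor)
  mcols(gr) <- NULL
  mcols(gr)$ratio <- ratio
  gr
}
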