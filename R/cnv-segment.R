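## Recursive binary segmentation of per-bin log2 ratios, in the circular
## binary segmentation family: at each step the best two-sample t-statistic
## split of an interval is tested against a permutation null; accepted
## splits recurse into both flanks. Merging is implicit: if no split is
## accepted the interval stays one segment.

## Best split of x (no NAs): candidates leave >= minBins on each side.
## Returns list(stat = max |t|, idx = split after x[idx], leftmost on ties)
## or NULL when no candidate exists.
.bestSplit <- function(x, minBins) {
  n <- length(x)
  if (n < 2L * minBins) return(NULL)
  i <- minBins:(n - minBins)
  cs <- cumsum(x)
  cs2 <- cumsum(x * x)
  tot <- cs[n]
  tot2 <- cs2[n]
  mL <- cs[i] / i
  mR <- (tot - cs[i]) / (n - i)
  ssL <- cs2[i] - i * mL^2
  ssR <- (tot2 - cs2[i]) - (n - i) * mR^2
  sp2 <- pmax(ssL + ssR, 0) / (n - 2)
  den <- sqrt(sp2 * (1 / i + 1 / (n - i)))
  d <- abs(mL - mR)
  tt <- ifelse(den > 0, d / den, ifelse(d > 0, Inf, 0))
  best <- which.max(tt)   # leftmost on ties
  list(stat = tt[best], idx = i[best])
}

## Permutation acceptance of an observed split statistic: accept iff
## (#{perm >= obs}) / nPerm < alpha. The null scan lives in compiled code
## (src/permseg.cpp) with its own deterministic generator seeded per
## interval, so the decision does not depend on the recursion path and
## early exit leaves it unchanged.
.segRecurse <- function(vals, lo, hi, alpha, minBins, nPerm, seed,
                        chromIdx, bumpMax) {
  n <- hi - lo + 1L
  if (n < 2L * minBins) return(integer(0))
  x <- vals[lo:hi]
  sp <- .bestSplit(x, minBins)
  if (is.null(sp) || is.na(sp$stat)) return(integer(0))
  localSeed <- .intervalSeed(seed, chromIdx, lo, hi, 0L)
  if (.permSplitAccept(x, sp$stat, minBins, alpha, nPerm, localSeed)) {
    cut <- lo + sp$idx - 1L
    return(c(
      .segRecurse(vals, lo, cut, alpha, minBins, nPerm, seed, chromIdx,
                  bumpMax),
      cut,
      .segRecurse(vals, cut + 1L, hi, alpha, minBins, nPerm, seed,
                  chromIdx, bumpMax)))
  }
  ## single-changepoint test failed: look for a short isolated segment
  ## whose flanks share a mean (the two-changepoint member of the CBS
  ## family), restricted to widths <= bumpMax bins
  if (bumpMax >= minBins && n >= 2L * minBins) {
    bp <- .bestBumpSplit(x, minBins, as.integer(bumpMax))
    if (is.finite(bp$stat) || is.infinite(bp$stat)) {
      bumpSeed <- .intervalSeed(seed, chromIdx, lo, hi, 1L)
      if (bp$stat > 0 &&
          .permBumpAccept(x, bp$stat, minBins, as.integer(bumpMax),
                          alpha, nPerm, bumpSeed)) {
        cutA <- if (bp$a > 1L) lo + bp$a - 2L else integer(0)
        cutB <- if (bp$b < n) lo + bp$b - 1L else integer(0)
        cuts <- c(cutA, cutB)
        if (length(cuts)) {
          bounds <- c(lo - 1L, cuts, hi)
          out <- integer(0)
          for (s in seq_len(length(bounds) - 1L)) {
            out <- c(out, .segRecurse(vals, bounds[s] + 1L,
                                      bounds[s + 1L], alpha, minBins,
                                      nPerm, seed, chromIdx, bumpMax))
          }
          return(sort(c(out, cuts)))
        }
      }
    }
  }
  integer(0)
}

#' Segment a log2-ratio track into piecewise-constant copy-number segments
#'
#' Recursive binary splitting per chromosome: each candidate changepoint is
#' scored by the two-sample t-statistic between its flanks and the best
#' split is accepted when its permutation p-value falls below `alpha`; the
#' procedure recurses into both flanks. The segment log2 ratio is the mean
#' of its member (unmasked) bins. Masked bins contribute to no statistic but
#' segments still tile each chromosome end to end: boundaries fall at the
#' start of the first unmasked bin of the right-hand segment.
#'
#' @param ratios `GRanges` with a `ratio` metadata column, as produced by
#'   [normalizeLog2Ratio()].
#' @param alpha split significance threshold (default `1e-4`).
#' @param minBins minimum number of unmasked bins per segment (default 3).
#' @param nPermutations permutations per split test (default 1000).
#' @param seed integer seed for the permutation null; split decisions use a
#'   deterministic seed per tested interval, so decreasing `alpha` can only
#'   remove splits, never add them.
#' @param bumpMax when the single-changepoint test fails on an interval, a
#'   two-changepoint test additionally searches for an isolated segment of
#'   at most `bumpMax` bins whose flanks share a mean (the configuration a
#'   single split cannot see); 0 disables the second stage.
#' @param sampleId sample identifier stored in the profile.
#' @param baselinePloidy baseline copy number (default 2).
#' @return a [SegmentProfile-class] with `state = NA` (see [callStates()]).
#' @export
segmentProfile <- function(ratios, alpha = 1e-4, minBins = 3L,
                           nPermutations = 1000L, seed = 1L,
                           sampleId = "sample", baselinePloidy = 2,
                           bumpMax = 50L) {
  stopifnot(alpha > 0, minBins >= 1L, nPermutations >= 1L, bumpMax >= 0L)
  chroms <- unique(as.character(seqnames(ratios)))
  segs <- list()
  for (ci in seq_along(chroms)) {
    chrom <- chroms[ci]
    sel <- as.character(seqnames(ratios)) == chrom
    grc <- ratios[sel]
    ord <- order(start(grc))
    grc <- grc[ord]
    vals <- mcols(grc)$ratio
    ok <- which(!is.na(vals))
    if (!length(ok)) {
      warning("all bins masked on ", chrom, "; no segments emitted")
      next
    }
    v <- vals[ok]
    cuts <- .segRecurse(v, 1L, length(v), alpha, minBins, nPermutations,
                        seed, ci, bumpMax)
    bounds <- c(0L, sort(cuts), length(v))
    chromStart <- min(start(grc))
    chromEnd <- max(end(grc))
    for (s in seq_len(length(bounds) - 1L)) {
      memb <- ok[(bounds[s] + 1L):bounds[s + 1L]]
      segStart <- if (s == 1L) chromStart else start(grc)[ok[bounds[s] + 1L]]
      segEnd <- if (s == length(bounds) - 1L) {
        chromEnd
      } else {
        start(grc)[ok[bounds[s + 1L] + 1L]] - 1L
      }
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = chrom, start = segStart, end = segEnd,
        nBins = length(memb), log2Ratio = mean(vals[memb]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(segs)) {
    gr <- GRanges()
    mcols(gr)$nBins <- integer(0)
    mcols(gr)$log2Ratio <- numeric(0)
    mcols(gr)$state <- integer(0)
    return(new("SegmentProfile", sampleId = sampleId, segments = gr,
               baselinePloidy = baselinePloidy))
  }
  tab <- do.call(rbind, segs)
  gr <- GRanges(tab$chrom, IRanges(tab$start, tab$end))
  sq <- GenomeInfoDb::seqinfo(ratios)
  if (!any(is.na(GenomeInfoDb::seqlengths(sq)))) {
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(sq)
    GenomeInfoDb::seqinfo(gr) <- sq
  }
  mcols(gr)$nBins <- as.integer(tab$nBins)
  mcols(gr)$log2Ratio <- tab$log2Ratio
  mcols(gr)$state <- rep(NA_integer_, nrow(tab))
  new("SegmentProfile", sampleId = sampleId, segments = gr,
      baselinePloidy = baselinePloidy)
}

#' Call integer copy-number states from segment log2 ratios
#'
#' The state of a segment is the baseline ploidy scaled by the linear copy
#' ratio, rounded to the nearest integer and floored at zero:
#' `state = max(0, round(ploidy * 2^log2Ratio))`. A log2 ratio of ~5.06 on a
#' diploid baseline therefore maps to a 67-copy focal amplification.
#'
#' @param profile a [SegmentProfile-class].
#' @param baselinePloidy baseline copy number (default the profile's own).
#' @return the profile with its `state` metadata column filled in.
#' @export
callStates <- function(profile, baselinePloidy = NULL) {
  bp <- baselinePloidy %||% profile@baselinePloidy
  gr <- profile@segments
  lr <- mcols(gr)$log2Ratio
  if (any(!is.finite(lr))) {
    stop("all segment log2 ratios must be finite to call states")
  }
  mcols(gr)$state <- as.integer(pmax(0, round(bp * 2^lr)))
  new("SegmentProfile", sampleId = profile@sampleId, segments = gr,
      baselinePloidy = bp)
}

#' @rdname accessors
#' @export
setMethod("sampleId", "SegmentProfile", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("baselinePloidy", "SegmentProfile", function(x) x@baselinePloidy)

#' @rdname accessors
#' @export
setMethod("segmentTable", "SegmentProfile", function(x) {
  gr <- x@segments
  data.frame(sample = x@sampleId,
             chrom = as.character(seqnames(gr)),
             start = start(gr) - 1,    # 0-based half-open on output
             end = end(gr),
             nBins = mcols(gr)$nBins,
             log2Ratio = mcols(gr)$log2Ratio,
             state = mcols(gr)$state,
             stringsAsFactors = FALSE)
})

setMethod("show", "SegmentProfile", function(object) {
  gr <- object@segments
  called <- sum(!is.na(mcols(gr)$state))
  cat(sprintf(
    "SegmentProfile '%s': %d segment(s) on %d chromosome(s), %s\n",
    object@sampleId, length(gr),
    length(unique(as.character(seqnames(gr)))),
    if (called == length(gr) && length(gr)) "states called"
    else "states not called"))
})

## Build a SegmentProfile directly from a (chrom, start0, end, state) table,
## e.g. planted generator truth; log2Ratio derived from state.
.profileFromStates <- function(tab, sampleId, baselinePloidy = 2,
                               genome = NULL) {
  gr <- GRanges(tab$chrom, IRanges(tab$start + 1, tab$end))
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- chromNames(genome)
    GenomeInfoDb::seqinfo(gr) <- .seqinfo(genome)
  }
  mcols(gr)$nBins <- pmax(1L, as.integer(width(gr) %/% 1e4))
  mcols(gr)$log2Ratio <- log2(pmax(tab$state, 0.5) / baselinePloidy)
  mcols(gr)$state <- as.integer(tab$state)
  new("SegmentProfile", sampleId = sampleId, segments = gr,
      baselinePloidy = baselinePloidy)
}

#' Read / write segment profiles as TSV
#'
#' The "SEG-like" dialect: tab-separated columns `sample`, `chrom`, `start`,
#' `end`, `nBins`, `log2Ratio`, `state` with 0-based half-open coordinates.
#'
#' @param path file path.
#' @return `readSegmentsTsv` returns a list of [SegmentProfile-class], one
#'   per sample; `writeSegmentsTsv` returns `path` invisibly.
#' @export
readSegmentsTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  lapply(split(tab, tab$sample), function(st) {
    gr <- GRanges(st$chrom, IRanges(st$start + 1, st$end))
    mcols(gr)$nBins <- as.integer(st$nBins)
    mcols(gr)$log2Ratio <- st$log2Ratio
    mcols(gr)$state <- as.integer(st$state)
    new("SegmentProfile", sampleId = st$sample[1L], segments = gr,
        baselinePloidy = 2)
  })
}

#' @rdname readSegmentsTsv
#' @param profiles a [SegmentProfile-class] or list of them.
#' @export
writeSegmentsTsv <- function(profiles, path) {
  if (is(profiles, "SegmentProfile")) profiles <- list(profiles)
  tab <- do.call(rbind, lapply(profiles, segmentTable))
  tab$start <- sprintf("%.0f", tab$start)
  tab$end <- sprintf("%.0f", tab$end)
  tab$log2Ratio <- sprintf("%.6g", tab$log2Ratio)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
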