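#' Count copy-number state transitions on one chromosome
#'
#' Number of adjacent segment pairs on a chromosome whose integer states
#' differ -- the operational measure of oscillating copy-number states.
#'
#' @param profile a [SegmentProfile-class] with called states.
#' @param chrom chromosome name.
#' @return integer transition count (0 with a warning when the chromosome
#'   carries no segments).
#' @export
oscillationTransitions <- function(profile, chrom) {
  st <- .chromStates(profile, chrom)
  if (!length(st)) {
    warning("no segments on ", chrom, " for sample ", sampleId(profile))
    return(0L)
  }
  sum(diff(st) != 0L)
}

.chromStates <- function(profile, chrom) {
  gr <- profile@segments
  sel <- as.character(seqnames(gr)) == chrom
  st <- mcols(gr)$state[sel]
  if (any(is.na(st))) {
    stop("states not called for sample ", sampleId(profile))
  }
  st[order(start(gr)[sel])]
}

#' Sample-level amplification threshold
#'
#' The given percentile (linear interpolation) of the integer states of all
#' gained segments (state above baseline ploidy) in a sample -- the bar a
#' "major amplification" must clear in the SV-burden rule.
#'
#' @param profile a [SegmentProfile-class] with called states.
#' @param percentile percentile of the gained-state distribution (default
#'   90).
#' @return copy-number threshold, or `NA` (the no-amplification sentinel,
#'   meaning the sample cannot qualify as high-SV) when no segment is
#'   gained.
#' @export
amplificationThreshold <- function(profile, percentile = 90) {
  st <- mcols(profile@segments)$state
  if (any(is.na(st))) {
    stop("states not called for sample ", sampleId(profile))
  }
  gains <- st[st > profile@baselinePloidy]
  if (!length(gains)) {
    return(NA_real_)
  }
  unname(stats::quantile(gains, percentile / 100, type = 7))
}

#' Rule-based high/low SV-burden classification
#'
#' A sample is labelled `"high"` when (i) at least one chromosome shows at
#' least `oscillationMin` copy-number state transitions and (ii) its maximum
#' state reaches the sample's amplification threshold (the
#' `ampPercentile`-th percentile of gained states); otherwise `"low"`. The
#' returned evidence records every quantity entering the rule -- including
#' the alternative "distinct state values" reading of the oscillation
#' criterion -- so calls can be manually curated.
#'
#' @param profile a [SegmentProfile-class] with called states.
#' @param oscillationMin minimum state transitions on one chromosome
#'   (default 10).
#' @param ampPercentile percentile for [amplificationThreshold()] (default
#'   90).
#' @return an [SvBurdenLabel-class].
#' @export
classifySvBurden <- function(profile, oscillationMin = 10L,
                             ampPercentile = 90) {
  gr <- profile@segments
  if (!length(gr)) {
    stop("empty segment profile for sample ", sampleId(profile))
  }
  chroms <- unique(as.character(seqnames(gr)))
  trans <- vapply(chroms, function(ch) {
    sum(diff(.chromStates(profile, ch)) != 0L)
  }, integer(1))
  distinct <- vapply(chroms, function(ch) {
    length(unique(.chromStates(profile, ch)))
  }, integer(1))
  maxState <- max(mcols(gr)$state)
  thr <- amplificationThreshold(profile, ampPercentile)
  qualifying <- chroms[trans >= oscillationMin]
  high <- length(qualifying) > 0L && !is.na(thr) && maxState >= thr
  new("SvBurdenLabel",
      sampleId = sampleId(profile),
      label = if (high) "high" else "low",
      evidence = list(
        transitionsPerChrom = trans,
        distinctStatesPerChrom = distinct,
        maxState = maxState,
        ampThreshold = thr,
        oscillationMin = as.integer(oscillationMin),
        ampPercentile = ampPercentile,
        qualifyingChroms = qualifying))
}

#' @rdname accessors
#' @export
setMethod("sampleId", "SvBurdenLabel", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("burdenLabel", "SvBurdenLabel", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("burdenEvidence", "SvBurdenLabel", function(x) x@evidence)

setMethod("show", "SvBurdenLabel", function(object) {
  ev <- object@evidence
  cat(sprintf(
    "SvBurdenLabel '%s': %s (max transitions %d, max state %d, threshold %s)\n",
    object@sampleId, object@label,
    if (length(ev$transitionsPerChrom)) max(ev$transitionsPerChrom) else 0L,
    ev$maxState,
    if (is.na(ev$ampThreshold)) "none" else
      sprintf("%.1f", ev$ampThreshold)))
})

#' Chromothripsis candidate chromosomes of one sample
#'
#' Flags chromosomes showing all three chromothripsis features at once:
#' hypergeometric breakpoint enrichment (`p < enrichAlpha`), significant
#' breakpoint clustering (`p < clusterAlpha`) and at least `oscillationMin`
#' copy-number state transitions.
#'
#' @param profile a [SegmentProfile-class] with called states.
#' @param callSet an [SvCallSet-class] for the same sample.
#' @param genome a [GenomeBuild-class].
#' @param enrichAlpha breakpoint-enrichment threshold (default `1e-3`).
#' @param clusterAlpha clustering-test threshold (default 0.05).
#' @param oscillationMin minimum state transitions (default 10).
#' @param nSim Monte-Carlo simulations for the clustering test.
#' @param seed integer seed.
#' @return `data.frame` with one row per chromosome carrying breakpoints:
#'   `chrom`, `x`, `enrichP`, `clusterP`, `transitions`, `flagged`.
#' @export
chromothripsisCandidates <- function(profile, callSet, genome,
                                     enrichAlpha = 1e-3,
                                     clusterAlpha = 0.05,
                                     oscillationMin = 10L,
                                     nSim = 2000L, seed = 1L) {
  bp <- breakpointsOf(callSet)
  chroms <- chromNames(genome)
  chroms <- chroms[chroms %in% unique(bp$chrom)]
  rows <- lapply(seq_along(chroms), function(i) {
    ch <- chroms[i]
    enr <- breakpointEnrichment(callSet, genome, ch, alpha = enrichAlpha)
    pos <- bp$pos[bp$chrom == ch]
    clus <- breakpointClusteringTest(
      pos, unname(chromLengths(genome)[ch]), nSim = nSim,
      seed = .substream(seed, i))
    tr <- suppressWarnings(oscillationTransitions(profile, ch))
    data.frame(chrom = ch, x = enr$x, enrichP = enr$pValue,
               clusterP = clus$pValue, transitions = tr,
               flagged = isTRUE(enr$significant) &&
                 isTRUE(clus$evaluable) &&
                 clus$pValue < clusterAlpha &&
                 tr >= oscillationMin,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(chrom = character(0), x = integer(0),
                      enrichP = numeric(0), clusterP = numeric(0),
                      transitions = integer(0), flagged = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write cohort SV-burden labels as TSV
#'
#' @param labels list of [SvBurdenLabel-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBurdenTsv <- function(labels, path) {
  tab <- do.call(rbind, lapply(labels, function(l) {
    ev <- burdenEvidence(l)
    data.frame(
      sample = sampleId(l), label = burdenLabel(l),
      qualifyingChrom = if (length(ev$qualifyingChroms))
        ev$qualifyingChroms[which.max(
          ev$transitionsPerChrom[ev$qualifyingChroms])] else NA_character_,
      transitions = if (length(ev$transitionsPerChrom))
        max(ev$transitionsPerChrom) else 0L,
      maxState = ev$maxState,
      ampThreshold = ev$ampThreshold,
      stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
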