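#' Amplified intervals of a segment profile
#'
#' Maximal runs of segments whose state reaches `minState`, merged when
#' adjacent. The default threshold `baseline + 2` (state >= 4 on a diploid
#' genome) separates focal amplification from single-copy gain.
#'
#' @param profile a [SegmentProfile-class] with called states.
#' @param minState minimum state to count as amplified.
#' @return `GRanges` of amplified intervals (1-based closed, as all
#'   in-memory ranges).
#' @export
amplifiedIntervals <- function(profile,
                               minState = profile@baselinePloidy + 2) {
  gr <- profile@segments
  st <- mcols(gr)$state
  if (length(gr) && any(is.na(st))) {
    stop("states not called for sample ", sampleId(profile))
  }
  amp <- gr[!is.na(st) & st >= minState]
  if (!length(amp)) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::reduce(amp, min.gapwidth = 1L)
}

## Normalize one sample's intervals on a chromosome to an IRanges
## (accepts GRanges, or a data.frame/matrix with 0-based half-open
## start/end columns).
.asChromIRanges <- function(x, chrom) {
  if (is(x, "GRanges")) {
    x <- x[as.character(seqnames(x)) == chrom]
    return(IRanges::reduce(IRanges(start(x), end(x))))
  }
  x <- as.data.frame(x)
  if (!is.null(x$chrom)) {
    x <- x[x$chrom == chrom, , drop = FALSE]
  }
  if (!nrow(x)) {
    return(IRanges())
  }
  IRanges::reduce(IRanges(start = x$start + 1, end = x$end))
}

#' Cohort recurrence map of amplified intervals on one chromosome
#'
#' Sweep-line over all interval endpoints: every atomic interval between
#' consecutive breakpoints is annotated with the number of samples whose
#' amplified intervals cover it (implemented as base-pair coverage of the
#' per-sample reduced interval sets).
#'
#' @param intervalSets list with one element per sample: a `GRanges` (e.g.
#'   from [amplifiedIntervals()]) or a `data.frame` with 0-based half-open
#'   `start`/`end` (and optionally `chrom`) columns.
#' @param chrom the chromosome to map.
#' @param nSamples cohort size (defaults to `length(intervalSets)`).
#' @return a [RecurrenceMap-class]; its interval table uses 0-based
#'   half-open coordinates.
#' @export
recurrenceMap <- function(intervalSets, chrom,
                          nSamples = length(intervalSets)) {
  irl <- unname(lapply(intervalSets, .asChromIRanges, chrom = chrom))
  all <- do.call(c, irl)
  if (!length(all)) {
    return(new("RecurrenceMap", chrom = chrom,
               intervals = data.frame(start = numeric(0), end = numeric(0),
                                      count = integer(0)),
               nSamples = as.integer(nSamples)))
  }
  cov <- IRanges::coverage(all)
  runs <- S4Vectors::runValue(cov)
  lens <- S4Vectors::runLength(cov)
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  keep <- runs > 0
  iv <- data.frame(start = starts[keep] - 1,   # back to 0-based half-open
                   end = ends[keep],
                   count = as.integer(runs[keep]))
  rownames(iv) <- NULL
  new("RecurrenceMap", chrom = chrom, intervals = iv,
      nSamples = as.integer(nSamples))
}

#' @rdname accessors
#' @export
setMethod("atomicIntervals", "RecurrenceMap", function(x) x@intervals)

#' @rdname accessors
#' @export
setMethod("cohortSize", "RecurrenceMap", function(x) x@nSamples)

setMethod("show", "RecurrenceMap", function(object) {
  iv <- object@intervals
  cat(sprintf(
    "RecurrenceMap on %s: %d atomic interval(s), max recurrence %s of %d samples\n",
    object@chrom, nrow(iv),
    if (nrow(iv)) max(iv$count) else 0L, object@nSamples))
})

#' Minimal recurrently amplified region
#'
#' Among atomic intervals at the maximal recurrence count, returns the
#' contiguous union; when several disjoint runs tie at the maximum, the one
#' with the smallest span wins, then the leftmost. The frequency is the
#' maximal count over the cohort size.
#'
#' @param map a [RecurrenceMap-class].
#' @return list with `chrom`, `start`, `end` (0-based half-open),
#'   `sampleCount`, `frequency`.
#' @export
minimalRecurrentRegion <- function(map) {
  iv <- atomicIntervals(map)
  if (!nrow(iv)) {
    stop("empty recurrence map on ", map@chrom)
  }
  maxc <- max(iv$count)
  top <- iv[iv$count == maxc, , drop = FALSE]
  ## group contiguous atomic intervals into runs
  runId <- cumsum(c(1, as.integer(top$start[-1L] != top$end[-nrow(top)])))
  runs <- do.call(rbind, lapply(split(top, runId), function(r) {
    data.frame(start = min(r$start), end = max(r$end))
  }))
  runs$span <- runs$end - runs$start
  best <- runs[order(runs$span, runs$start), ][1L, ]
  list(chrom = map@chrom, start = best$start, end = best$end,
       sampleCount = maxc, frequency = maxc / cohortSize(map))
}

#' Write recurrent regions as BED plus a JSON summary
#'
#' @param map a [RecurrenceMap-class].
#' @param region output of [minimalRecurrentRegion()].
#' @param bedPath,jsonPath output paths.
#' @param contributingSamples optional character vector of sample ids.
#' @return invisibly, the two paths.
#' @export
writeRecurrentRegion <- function(map, region, bedPath, jsonPath,
                                 contributingSamples = NULL) {
  iv <- atomicIntervals(map)
  bed <- data.frame(chrom = map@chrom,
                    start = sprintf("%.0f", iv$start),
                    end = sprintf("%.0f", iv$end),
                    name = sprintf("recurrence_%d", iv$count))
  utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  out <- list(schemaVersion = "1.0",
              chrom = region$chrom, start = region$start,
              end = region$end, sampleCount = region$sampleCount,
              nSamples = cohortSize(map),
              frequency = region$frequency)
  if (!is.null(contributingSamples)) {
    out$contributingSamples <- contributingSamples
  }
  jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(bedPath, jsonPath))
}
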