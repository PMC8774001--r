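#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom IRanges IRanges
NULL

#' GenomeBuild: ordered chromosome names and lengths
#'
#' Minimal description of a genome build: the ordered chromosome identifiers
#' and their lengths in base pairs. The total genome size (the population
#' size of the breakpoint-enrichment hypergeometric model) is the sum of the
#' chromosome lengths.
#'
#' @slot chromNames ordered, unique chromosome identifiers.
#' @slot chromLengths chromosome lengths in base pairs, parallel to
#'   `chromNames`.
#'
#' @seealso [makeGenome()]
#' @exportClass GenomeBuild
setClass("GenomeBuild",
  representation(chromNames = "character", chromLengths = "numeric")
)

setValidity("GenomeBuild", function(object) {
  msg <- character()
  if (length(object@chromNames) != length(object@chromLengths)) {
    msg <- c(msg, "chromNames and chromLengths must have equal length")
  }
  if (length(object@chromNames) < 1L) {
    msg <- c(msg, "at least one chromosome is required")
  }
  if (anyDuplicated(object@chromNames)) {
    msg <- c(msg, "chromosome names must be unique")
  }
  if (any(!is.finite(object@chromLengths)) || any(object@chromLengths <= 0)) {
    msg <- c(msg, "all chromosome lengths must be positive and finite")
  }
  if (length(msg)) msg else TRUE
})

#' BinnedCoverage: per-sample binned read counts
#'
#' Read counts on a fixed genome-wide bin grid (default 10 kb) for one
#' sample, the input of copy-number log2-ratio normalization. Bins are held
#' as a sorted, non-overlapping [GenomicRanges::GRanges] with a `count`
#' metadata column.
#'
#' @slot sampleId sample identifier.
#' @slot bins `GRanges` with integer-valued `count` metadata column.
#' @slot binSize bin width in base pairs (terminal bins may be shorter).
#' @slot totalReads total read count of the sample (sum of bin counts).
#'
#' @exportClass BinnedCoverage
setClass("BinnedCoverage",
  representation(sampleId = "character", bins = "GRanges",
                 binSize = "numeric", totalReads = "numeric")
)

setValidity("BinnedCoverage", function(object) {
  msg <- character()
  cnt <- mcols(object@bins)$count
  if (is.null(cnt)) {
    msg <- c(msg, "bins must carry a 'count' metadata column")
  } else {
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
    if (abs(sum(cnt) - object@totalReads) > 0.5) {
      msg <- c(msg, "totalReads must equal the sum of bin counts")
    }
  }
  if (length(object@bins) > 1L) {
    byChrom <- split(object@bins, as.character(seqnames(object@bins)))
    for (gr in byChrom) {
      if (is.unsorted(start(gr))) {
        msg <- c(msg, "bins must be sorted within chromosomes")
        break
      }
      if (length(gr) > 1L && any(start(gr)[-1L] <= end(gr)[-length(gr)])) {
        msg <- c(msg, "bins must not overlap")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' SegmentProfile: piecewise-constant copy-number segments for one sample
#'
#' Per-sample segmentation of the binned log2-ratio track: contiguous,
#' non-overlapping segments per chromosome with the number of contributing
#' (unmasked) bins, the mean log2 ratio, and -- after [callStates()] -- the
#' integer copy-number state.
#'
#' @slot sampleId sample identifier.
#' @slot segments `GRanges` with metadata columns `nBins`, `log2Ratio` and
#'   `state` (`NA` until states are called).
#' @slot baselinePloidy baseline copy number (2 for a diploid genome).
#'
#' @exportClass SegmentProfile
setClass("SegmentProfile",
  representation(sampleId = "character", segments = "GRanges",
                 baselinePloidy = "numeric")
)

setValidity("SegmentProfile", function(object) {
  msg <- character()
  mc <- mcols(object@segments)
  need <- c("nBins", "log2Ratio", "state")
  if (!all(need %in% colnames(mc))) {
    msg <- c(msg, "segments need nBins, log2Ratio and state metadata columns")
  } else {
    if (any(mc$nBins < 1L)) msg <- c(msg, "each segment needs >= 1 bin")
    st <- mc$state
    if (any(!is.na(st) & st < 0)) msg <- c(msg, "states must be >= 0")
  }
  if (object@baselinePloidy <= 0) {
    msg <- c(msg, "baselinePloidy must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' SvCallSet: typed somatic structural-variant calls for one sample
#'
#' Structural variant records (BND, DEL, DUP, INV, INS) with their
#' breakpoints, Delly-style PRECISE and FILTER flags and paired-end read
#' support, as read from a VCF by [readSvVcf()] or produced by the
#' synthetic generator. Positions are 1-based as in VCF.
#'
#' @slot sampleId sample identifier.
#' @slot records `data.frame` with columns `svType`, `chrom1`, `pos1`,
#'   `chrom2`, `pos2`, `precise`, `filterPass`, `readSupport`, `mateId`.
#'
#' @exportClass SvCallSet
setClass("SvCallSet",
  representation(sampleId = "character", records = "data.frame")
)

.svRecordCols <- c("svType", "chrom1", "pos1", "chrom2", "pos2",
                   "precise", "filterPass", "readSupport", "mateId")

setValidity("SvCallSet", function(object) {
  msg <- character()
  rec <- object@records
  if (!all(.svRecordCols %in% names(rec))) {
    msg <- c(msg, paste("records must have columns:",
                        paste(.svRecordCols, collapse = ", ")))
  } else if (nrow(rec)) {
    if (!all(rec$svType %in% c("BND", "DEL", "DUP", "INV", "INS"))) {
      msg <- c(msg, "svType must be one of BND, DEL, DUP, INV, INS")
    }
    if (any(rec$pos1 < 1, na.rm = TRUE)) {
      msg <- c(msg, "positions are 1-based and must be >= 1")
    }
    intra <- rec$svType %in% c("DEL", "DUP", "INV")
    if (any(intra & rec$chrom1 != rec$chrom2)) {
      msg <- c(msg, "DEL/DUP/INV records must be intra-chromosomal")
    }
    if (any(intra & rec$pos1 > rec$pos2)) {
      msg <- c(msg, "intra-chromosomal records need pos1 <= pos2")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SvBurdenLabel: high/low SV-burden classification with evidence
#'
#' Result of the rule-based SV-burden classification: the label plus the
#' evidence that supports it (per-chromosome state-transition counts,
#' maximum state, amplification threshold, qualifying chromosomes), kept
#' human-readable so the call can be audited or manually overridden.
#'
#' @slot sampleId sample identifier.
#' @slot label `"high"` or `"low"`.
#' @slot evidence named list of supporting statistics.
#'
#' @exportClass SvBurdenLabel
setClass("SvBurdenLabel",
  representation(sampleId = "character", label = "character",
                 evidence = "list")
)

setValidity("SvBurdenLabel", function(object) {
  if (!object@label %in% c("high", "low")) {
    "label must be 'high' or 'low'"
  } else {
    TRUE
  }
})

#' RecurrenceMap: per-base amplification recurrence on one chromosome
#'
#' Breakpoint-sorted atomic intervals annotated with the number of cohort
#' samples whose amplified intervals cover them. Interval coordinates in the
#' table are 0-based half-open (the BED convention used on disk).
#'
#' @slot chrom chromosome name.
#' @slot intervals `data.frame` with columns `start`, `end`, `count`.
#' @slot nSamples cohort size used for frequencies.
#'
#' @exportClass RecurrenceMap
setClass("RecurrenceMap",
  representation(chrom = "character", intervals = "data.frame",
                 nSamples = "integer")
)

setValidity("RecurrenceMap", function(object) {
  msg <- character()
  iv <- object@intervals
  if (!all(c("start", "end", "count") %in% names(iv))) {
    msg <- c(msg, "intervals must have start, end, count columns")
  } else if (nrow(iv)) {
    if (any(iv$end <= iv$start)) msg <- c(msg, "intervals must be non-empty")
    if (any(iv$count < 0) || any(iv$count > object@nSamples)) {
      msg <- c(msg, "counts must lie in [0, nSamples]")
    }
    if (is.unsorted(iv$start)) msg <- c(msg, "intervals must be sorted")
  }
  if (length(msg)) msg else TRUE
})

#' ConsensusResult: consensus-NMF subgrouping of a cohort
#'
#' Output of [consensusCluster()]: per-rank consensus matrices and mean
#' silhouette widths, the chosen rank, per-sample cluster labels, the
#' representative factorization used for signature extraction, and the
#' extracted cluster-specific gene signatures.
#'
#' @slot kRange ranks evaluated.
#' @slot consensus named list (by rank) of sample-by-sample consensus
#'   matrices with entries in `[0, 1]`.
#' @slot silhouettes named numeric vector of mean silhouette widths per rank
#'   (distance `1 - consensus`); `NA` for degenerate ranks.
#' @slot validK named logical vector; a rank is invalid when every run left
#'   at least one cluster empty.
#' @slot chosenK the selected rank.
#' @slot labels named integer cluster labels (1..chosenK) per sample.
#' @slot bestRun the factorization (list with `W`, `H`, `k`, `seed`,
#'   `objTrace`) whose partition best matches the consensus partition.
#' @slot signatures `data.frame` with columns `gene`, `cluster`, `score`.
#'
#' @exportClass ConsensusResult
setClass("ConsensusResult",
  representation(kRange = "integer", consensus = "list",
                 silhouettes = "numeric", validK = "logical",
                 chosenK = "integer", labels = "integer",
                 bestRun = "list", signatures = "data.frame")
)

setValidity("ConsensusResult", function(object) {
  msg <- character()
  for (k in names(object@consensus)) {
    C <- object@consensus[[k]]
    if (!isTRUE(all.equal(C, t(C), tolerance = 1e-12)) ||
        any(C < -1e-12) || any(C > 1 + 1e-12) ||
        any(abs(diag(C) - 1) > 1e-12)) {
      msg <- c(msg, sprintf(
        "consensus matrix for k=%s must be symmetric, unit-diagonal, in [0,1]",
        k))
    }
  }
  if (length(object@labels) &&
      !all(object@labels %in% seq_len(object@chosenK))) {
    msg <- c(msg, "labels must lie in 1..chosenK")
  }
  if (length(msg)) msg else TRUE
})
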