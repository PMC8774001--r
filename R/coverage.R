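#' Construct a BinnedCoverage object
#'
#' @param sampleId sample identifier.
#' @param chrom,start0,end,count parallel vectors describing the bins;
#'   `start0` is 0-based (BED convention), `end` exclusive.
#' @param binSize bin width in base pairs.
#' @param genome optional [GenomeBuild-class] supplying seqinfo.
#' @return a [BinnedCoverage-class] object.
#' @export
binnedCoverage <- function(sampleId, chrom, start0, end, count, binSize,
                           genome = NULL) {
  gr <- GRanges(chrom, IRanges(start = start0 + 1, end = end))
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- chromNames(genome)
    GenomeInfoDb::seqinfo(gr) <- .seqinfo(genome)
  }
  mcols(gr)$count <- as.numeric(count)
  new("BinnedCoverage", sampleId = sampleId, bins = gr,
      binSize = as.numeric(binSize), totalReads = sum(as.numeric(count)))
}

#' @rdname accessors
#' @export
setMethod("sampleId", "BinnedCoverage", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("bins", "BinnedCoverage", function(x) x@bins)

#' @rdname accessors
#' @export
setMethod("binSize", "BinnedCoverage", function(x) x@binSize)

#' @rdname accessors
#' @export
setMethod("totalReads", "BinnedCoverage", function(x) x@totalReads)

setMethod("show", "BinnedCoverage", function(object) {
  cat(sprintf(
    "BinnedCoverage '%s': %d bins of %.0f bp, %.0f reads total\n",
    object@sampleId, length(object@bins), object@binSize,
    object@totalReads))
})

## TRUE when two coverages share an identical bin grid.
.sameGrid <- function(a, b) {
  ga <- bins(a); gb <- bins(b)
  length(ga) == length(gb) &&
    identical(as.character(seqnames(ga)), as.character(seqnames(gb))) &&
    identical(start(ga), start(gb)) &&
    identical(end(ga), end(gb))
}

#' Read / write binned coverage as BED-like TSV
#'
#' On-disk format: four tab-separated columns `chrom`, `start`, `end`,
#' `count` with 0-based half-open coordinates and a header line.
#'
#' @param path file path.
#' @param sampleId sample identifier (defaults to the file base name).
#' @param binSize bin width in base pairs; inferred from the modal bin width
#'   when omitted.
#' @param genome optional [GenomeBuild-class].
#' @return `readBinnedCoverage` returns a [BinnedCoverage-class];
#'   `writeBinnedCoverage` returns `path` invisibly.
#' @export
readBinnedCoverage <- function(path, sampleId = NULL, binSize = NULL,
                               genome = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "count")
  if (!all(need %in% names(tab))) {
    stop("binned coverage file needs columns chrom/start/end/count: ", path)
  }
  if (is.null(binSize)) {
    w <- tab$end - tab$start
    binSize <- as.numeric(names(sort(table(w), decreasing = TRUE))[1L])
  }
  binnedCoverage(sampleId %||% sub("\\.[^.]*$", "", basename(path)),
                 tab$chrom, tab$start, tab$end, tab$count, binSize, genome)
}

#' @rdname readBinnedCoverage
#' @param x a [BinnedCoverage-class].
#' @export
writeBinnedCoverage <- function(x, path) {
  gr <- bins(x)
  tab <- data.frame(chrom = as.character(seqnames(gr)),
                    start = sprintf("%.0f", start(gr) - 1),
                    end = sprintf("%.0f", end(gr)),
                    count = sprintf("%.0f", mcols(gr)$count),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
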