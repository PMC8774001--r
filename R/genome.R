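#' Construct a GenomeBuild
#'
#' @param chromLengths numeric vector of chromosome lengths in base pairs;
#'   names, if present, are used as chromosome names.
#' @param chromNames optional character vector of chromosome names; defaults
#'   to the names of `chromLengths` or `chr1`, `chr2`, ...
#' @return a [GenomeBuild-class] object.
#' @examples
#' gb <- makeGenome(c(chr1 = 5e6, chr2 = 3e6, chr3 = 2e6))
#' genomeSize(gb)
#' @export
makeGenome <- function(chromLengths, chromNames = NULL) {
  if (length(chromLengths) < 1L) {
    stop("at least one chromosome length is required")
  }
  if (any(!is.finite(chromLengths)) || any(chromLengths <= 0)) {
    stop("all chromosome lengths must be positive")
  }
  if (is.null(chromNames)) {
    chromNames <- names(chromLengths) %||%
      paste0("chr", seq_along(chromLengths))
  }
  new("GenomeBuild", chromNames = as.character(chromNames),
      chromLengths = unname(as.numeric(chromLengths)))
}

#' @rdname accessors
#' @export
setMethod("chromNames", "GenomeBuild", function(x) x@chromNames)

#' @rdname accessors
#' @export
setMethod("chromLengths", "GenomeBuild", function(x) {
  stats::setNames(x@chromLengths, x@chromNames)
})

#' @rdname accessors
#' @export
setMethod("genomeSize", "GenomeBuild", function(x) sum(x@chromLengths))

setMethod("show", "GenomeBuild", function(object) {
  cat(sprintf("GenomeBuild with %d chromosome(s), %.0f bp total\n",
              length(object@chromNames), sum(object@chromLengths)))
  n <- min(length(object@chromNames), 6L)
  for (i in seq_len(n)) {
    cat(sprintf("  %s: %.0f bp\n", object@chromNames[i],
                object@chromLengths[i]))
  }
  if (length(object@chromNames) > n) cat("  ...\n")
})

## Seqinfo for GRanges containers built on this genome.
.seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = chromNames(genome),
                        seqlengths = as.integer(chromLengths(genome)))
}

#' Read / write a genome build table
#'
#' Plain two-column TSV (`chrom`, `length`) describing the genome build.
#'
#' @param path file path.
#' @return `readGenomeTable` returns a [GenomeBuild-class];
#'   `writeGenomeTable` returns `path` invisibly.
#' @export
readGenomeTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("chrom", "length") %in% names(tab))) {
    stop("genome table needs 'chrom' and 'length' columns: ", path)
  }
  makeGenome(stats::setNames(tab$length, tab$chrom))
}

#' @rdname readGenomeTable
#' @param genome a [GenomeBuild-class].
#' @export
writeGenomeTable <- function(genome, path) {
  tab <- data.frame(chrom = chromNames(genome),
                    length = sprintf("%.0f", unname(chromLengths(genome))),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
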