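#' Median-of-ratios size factors for a count matrix
#'
#' For each sample, the median over all-positive genes of the ratio of its
#' count to the gene's geometric mean across samples. When no gene is
#' positive in every sample the function falls back to total-count scaling
#' (factors proportional to library size, geometric-mean-centred) with a
#' warning. Size factors are defined up to a common scale.
#'
#' @param counts gene-by-sample matrix of non-negative counts.
#' @return named numeric vector of per-sample size factors.
#' @export
sizeFactorsForCounts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) {
    stop("counts must be non-negative")
  }
  if (any(colSums(counts) == 0)) {
    stop("every sample needs at least one nonzero count")
  }
  allPos <- rowSums(counts == 0) == 0L
  if (!any(allPos)) {
    warning("no gene is positive in all samples; ",
            "falling back to total-count scaling")
    tot <- colSums(counts)
    return(tot / exp(mean(log(tot))))
  }
  lc <- log(counts[allPos, , drop = FALSE])
  geo <- rowMeans(lc)
  apply(lc, 2L, function(x) exp(stats::median(x - geo)))
}

#' Variance-stabilizing transform of counts
#'
#' Shifted-log transform of size-factor-normalized counts:
#' `log2(count / factor + 1)`. This keeps the matrix non-negative (as the
#' downstream factorization requires) and is invariant to per-sample count
#' scaling once factors are recomputed.
#'
#' @param counts gene-by-sample count matrix.
#' @param factors per-sample size factors (default
#'   [sizeFactorsForCounts()]).
#' @return normalized gene-by-sample matrix.
#' @export
varianceStabilize <- function(counts, factors = sizeFactorsForCounts(counts)) {
  counts <- as.matrix(counts)
  if (any(factors <= 0)) {
    stop("size factors must be positive")
  }
  log2(sweep(counts, 2L, factors, "/") + 1)
}

#' Select the most variable genes by median absolute deviation
#'
#' Genes are ranked by the raw MAD of their normalized values across
#' samples (`median |x - median(x)|`, no consistency constant); the top `n`
#' are returned. Ties are broken by total expression, then by gene
#' identifier, so the selection is deterministic.
#'
#' @param normalized gene-by-sample matrix with gene-identifier rownames.
#' @param n number of genes to keep (default 6000). When `n` exceeds the
#'   number of genes, all genes are returned with a warning.
#' @return character vector of selected gene identifiers, highest MAD
#'   first.
#' @export
selectVariableGenes <- function(normalized, n = 6000L) {
  normalized <- as.matrix(normalized)
  ids <- rownames(normalized)
  if (is.null(ids)) {
    stop("normalized matrix needs gene-identifier rownames")
  }
  if (n > nrow(normalized)) {
    warning("n exceeds the number of genes; returning all ",
            nrow(normalized), " genes")
    n <- nrow(normalized)
  }
  med <- apply(normalized, 1L, stats::median)
  mads <- apply(abs(normalized - med), 1L, stats::median)
  tot <- rowSums(normalized)
  ord <- order(-mads, -tot, ids)
  ids[ord][seq_len(n)]
}

#' Read / write a gene-by-sample count matrix as TSV
#'
#' Gene identifiers in the first column (`gene`), one column per sample,
#' integer counts.
#'
#' @param path file path.
#' @return `readCountsTsv` returns a matrix with gene rownames;
#'   `writeCountsTsv` returns `path` invisibly.
#' @export
readCountsTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  m
}

#' @rdname readCountsTsv
#' @param counts gene-by-sample matrix with dimnames.
#' @export
writeCountsTsv <- function(counts, path) {
  tab <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
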