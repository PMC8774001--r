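#' Default pro- and anti-inflammatory cytokine gene lists
#'
#' Pro-inflammatory cytokines (IFNG, IL1A, IL1B, IL2) versus
#' immunosuppressive molecules (IL10, IL11, IL4, TGFB1). IL4's membership
#' of the immunosuppressive list is reported inconsistently in the
#' literature this ratio descends from; both lists are plain character
#' vectors and can be edited freely (or supplied via the pipeline YAML
#' config).
#'
#' @return named list with elements `pro` and `immuno`.
#' @export
defaultCytokineLists <- function() {
  list(pro = c("IFNG", "IL1A", "IL1B", "IL2"),
       immuno = c("IL10", "IL11", "IL4", "TGFB1"))
}

#' Per-sample pro/anti-inflammatory cytokine expression ratio
#'
#' For each sample, the sum of normalized expression over the
#' pro-inflammatory list divided by the sum over the immunosuppressive
#' list. Listed genes missing from the matrix are dropped with a warning;
#' samples with a zero denominator get `NA` (flagged, excluded from
#' downstream tests). Aggregation by mean instead of sum (a constant factor
#' on the ratio) is available via `aggregate = "mean"`.
#'
#' @param normalized gene-by-sample matrix of normalized expression with
#'   gene rownames.
#' @param proGenes,immunoGenes character vectors of gene identifiers
#'   (default [defaultCytokineLists()]).
#' @param aggregate `"sum"` (default) or `"mean"`.
#' @return named numeric vector of per-sample ratios.
#' @export
cytokineRatio <- function(normalized,
                          proGenes = defaultCytokineLists()$pro,
                          immunoGenes = defaultCytokineLists()$immuno,
                          aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  normalized <- as.matrix(normalized)
  if (length(intersect(proGenes, immunoGenes))) {
    stop("pro and immuno gene lists must be disjoint")
  }
  pick <- function(genes, what) {
    missing <- setdiff(genes, rownames(normalized))
    if (length(missing)) {
      warning("dropping ", what, " gene(s) absent from the matrix: ",
              paste(missing, collapse = ", "))
    }
    normalized[intersect(genes, rownames(normalized)), , drop = FALSE]
  }
  pro <- pick(proGenes, "pro-inflammatory")
  imm <- pick(immunoGenes, "immunosuppressive")
  if (!nrow(pro) || !nrow(imm)) {
    stop("both gene lists must have at least one gene present")
  }
  agg <- if (aggregate == "sum") colSums else colMeans
  num <- agg(pro)
  den <- agg(imm)
  ratio <- num / den
  if (any(den == 0)) {
    warning(sum(den == 0), " sample(s) with zero denominator flagged NA")
    ratio[den == 0] <- NA_real_
  }
  ratio
}

#' Student's t-test of cytokine ratios between two groups
#'
#' Two-sample pooled-variance Student's t-test, two-sided, on the
#' per-sample ratios. `NA` ratios (zero-denominator samples) are dropped.
#' The statistic is oriented as first group minus second (groups in label
#' sort order).
#'
#' @param ratios numeric vector (e.g. from [cytokineRatio()]).
#' @param labels two-level group labels, parallel to `ratios`.
#' @return list with `tStatistic`, `pValue`, `groupMeans`.
#' @export
groupRatioTest <- function(ratios, labels) {
  keep <- !is.na(ratios)
  ratios <- ratios[keep]
  labels <- as.character(labels)[keep]
  lv <- sort(unique(labels))
  if (length(lv) != 2L) {
    stop("labels must have exactly two levels")
  }
  x <- ratios[labels == lv[1L]]
  y <- ratios[labels == lv[2L]]
  if (length(x) < 2L || length(y) < 2L) {
    stop("both groups need at least two samples")
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(tStatistic = unname(tt$statistic), pValue = tt$p.value,
       groupMeans = stats::setNames(c(mean(x), mean(y)), lv))
}

#' Fisher exact association between cluster and SV-burden labels
#'
#' Builds the 2x2 table of transcriptomic cluster versus SV-burden label
#' and computes the two-sided Fisher exact p-value by summing, over all
#' tables with the observed margins, the hypergeometric point probabilities
#' not exceeding the observed one (relative tie tolerance 1e-12). The odds
#' ratio is taken from the observed table, with a 0.5 continuity correction
#' only when a zero cell is present (flagged in the result).
#'
#' @param clusterLabels,svLabels two binary labelings of the same samples.
#' @return list with `table`, `oddsRatio`, `pValue`,
#'   `continuityCorrected`.
#' @export
fisherAssociation <- function(clusterLabels, svLabels) {
  clusterLabels <- as.character(clusterLabels)
  svLabels <- as.character(svLabels)
  if (length(clusterLabels) != length(svLabels)) {
    stop("labelings must cover the same samples")
  }
  if (length(unique(clusterLabels)) != 2L ||
      length(unique(svLabels)) != 2L) {
    stop("both labelings must be binary")
  }
  tab <- table(cluster = clusterLabels, sv = svLabels)
  a <- tab[1L, 1L]
  b <- tab[1L, 2L]
  cc <- tab[2L, 1L]
  d <- tab[2L, 2L]
  p <- .fisherP2x2(a, b, cc, d)
  zero <- any(tab == 0L)
  or <- if (zero) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  list(table = tab, oddsRatio = unname(or), pValue = p,
       continuityCorrected = zero)
}

## Two-sided Fisher exact p for the 2x2 table [[a, b], [cc, d]] by
## point-probability summation with relative tie tolerance 1e-12.
.fisherP2x2 <- function(a, b, cc, d) {
  m <- a + cc
  n <- b + d
  k <- a + b
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pObs <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= pObs * (1 + 1e-12)]))
}

#' Per-gene group contrast of normalized expression
#'
#' For each queried gene: the log2 fold change of group means on the linear
#' normalized-count scale with a one-count pseudo-value
#' (`log2(mean1 + 1) - log2(mean2 + 1)`), and a two-sided Welch t-test on
#' the (log-scale) normalized values. P-values are Benjamini-Hochberg
#' corrected across the queried list. This is a deliberately simple
#' moderated-model-free contrast; its fold changes are not expected to
#' match shrinkage-based estimators.
#'
#' @param normalized gene-by-sample matrix (log2 scale, e.g. from
#'   [varianceStabilize()]).
#' @param labels two-level group labels; the contrast is first level minus
#'   second (sort order).
#' @param genes character vector of genes to test.
#' @return `data.frame` with columns `gene`, `log2FoldChange`, `pValue`,
#'   `padj`.
#' @export
markerGeneCompare <- function(normalized, labels, genes) {
  normalized <- as.matrix(normalized)
  absent <- setdiff(genes, rownames(normalized))
  if (length(absent)) {
    stop("gene(s) absent from the matrix: ", paste(absent, collapse = ", "))
  }
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) != 2L) {
    stop("labels must have exactly two levels")
  }
  g1 <- labels == lv[1L]
  g2 <- labels == lv[2L]
  if (sum(g1) < 2L || sum(g2) < 2L) {
    stop("both groups need at least two samples")
  }
  rows <- lapply(genes, function(g) {
    x <- normalized[g, g1]
    y <- normalized[g, g2]
    lin1 <- mean(2^x - 1)
    lin2 <- mean(2^y - 1)
    lfc <- log2(lin1 + 1) - log2(lin2 + 1)
    p <- stats::t.test(x, y)$p.value
    data.frame(gene = g, log2FoldChange = lfc, pValue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$pValue, method = "BH")
  rownames(out) <- NULL
  out
}
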