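## Rand index between two partitions (unadjusted; used only to pick the
## run most concordant with the consensus partition).
.randIndex <- function(a, b) {
  n <- length(a)
  if (n < 2L) return(1)
  sameA <- outer(a, a, "==")
  sameB <- outer(b, b, "==")
  up <- upper.tri(sameA)
  mean(sameA[up] == sameB[up])
}

#' Consensus clustering by repeated NMF
#'
#' For each rank `k` in `kRange`, runs `nRuns` seeded factorizations of the
#' selected-gene matrix; each run assigns every sample to its
#' largest-coefficient basis. The consensus matrix holds, for every sample
#' pair, the fraction of runs co-assigning the pair. Final labels come from
#' an average-linkage hierarchical cut of `1 - consensus` into `k` groups;
#' the quality of each rank is the mean silhouette width on the
#' `1 - consensus` distance, and the chosen rank maximizes it (ties go to
#' the smaller rank). Ranks whose every run leaves a cluster empty are
#' marked invalid and excluded. The factorization whose partition agrees
#' best (highest Rand index) with the consensus partition at the chosen
#' rank is retained for signature extraction, making signatures
#' deterministic given the seeds.
#'
#' @param X non-negative gene-by-sample matrix (normalized, gene-selected).
#' @param kRange ranks to evaluate (default `2:6`).
#' @param nRuns factorizations per rank (default 30).
#' @param seed integer seed; run seeds are derived substreams.
#' @param maxIter,tol passed to [nmfFactorize()].
#' @return a [ConsensusResult-class].
#' @export
consensusCluster <- function(X, kRange = 2:6, nRuns = 30L, seed = 1L,
                             maxIter = 500L, tol = 1e-5) {
  X <- as.matrix(X)
  s <- ncol(X)
  kRange <- as.integer(kRange)
  if (any(kRange < 2L) || any(kRange >= min(dim(X)))) {
    stop("kRange must lie within [2, min(dim(X)) - 1]")
  }
  sampleIds <- colnames(X) %||% paste0("S", seq_len(s))
  consensus <- list()
  sil <- stats::setNames(rep(NA_real_, length(kRange)), kRange)
  validK <- stats::setNames(rep(FALSE, length(kRange)), kRange)
  runsByK <- list()
  labelsByK <- list()
  for (ki in seq_along(kRange)) {
    k <- kRange[ki]
    C <- matrix(0, s, s)
    runs <- vector("list", nRuns)
    anyComplete <- FALSE
    for (r in seq_len(nRuns)) {
      run <- nmfFactorize(X, k, maxIter = maxIter, tol = tol,
                          seed = .substream(seed, ki, r))
      lab <- .nmfLabels(run)
      run$labels <- lab
      runs[[r]] <- run
      if (length(unique(lab)) == k) anyComplete <- TRUE
      C <- C + outer(lab, lab, "==")
    }
    C <- C / nRuns
    diag(C) <- 1
    dimnames(C) <- list(sampleIds, sampleIds)
    consensus[[as.character(k)]] <- C
    runsByK[[as.character(k)]] <- runs
    if (!anyComplete) {
      .mmLog("consensusCluster: k=%d degenerate (empty cluster in every run)",
             k)
      next
    }
    validK[ki] <- TRUE
    d <- stats::as.dist(1 - C)
    hc <- stats::hclust(d, method = "average")
    lab <- stats::cutree(hc, k = k)
    labelsByK[[as.character(k)]] <- lab
    sw <- cluster::silhouette(lab, d)
    sil[ki] <- if (is.matrix(sw)) mean(sw[, "sil_width"]) else NA_real_
  }
  if (!any(validK)) {
    stop("no valid rank: every k degenerated to empty clusters")
  }
  okIdx <- which(validK)
  chosen <- kRange[okIdx[which.max(sil[okIdx])]]   # leftmost max = smaller k
  labels <- labelsByK[[as.character(chosen)]]
  names(labels) <- sampleIds
  ## representative run: partition closest to the consensus partition
  runs <- runsByK[[as.character(chosen)]]
  ri <- vapply(runs, function(r) .randIndex(r$labels, labels), numeric(1))
  bestRun <- runs[[which.max(ri)]]
  sig <- extractSignatures(bestRun$W, geneIds = rownames(X),
                           runLabels = bestRun$labels,
                           consensusLabels = labels)
  new("ConsensusResult",
      kRange = kRange, consensus = consensus, silhouettes = sil,
      validK = validK, chosenK = as.integer(chosen), labels = labels,
      bestRun = bestRun, signatures = sig)
}

#' Extract cluster-specific gene signatures from an NMF basis matrix
#'
#' Scores every gene by the Kim-Park basis-specificity score
#' `s(g) = 1 + (1 / log2 k) * sum_i p_gi log2 p_gi` with
#' `p_gi = W_gi / sum_i W_gi`: 1 for a gene loading on exactly one basis, 0
#' for a gene loading uniformly on all. Genes with
#' `s > median(s) + 3 * MAD(s)` (raw MAD) are selected and assigned to their
#' largest-loading basis; all-zero rows are excluded. When run labels and
#' consensus labels are supplied, basis indices are mapped to the consensus
#' cluster most common among the samples of that basis.
#'
#' @param W non-negative gene-by-k basis matrix (`k >= 2`).
#' @param geneIds gene identifiers (default `rownames(W)`).
#' @param runLabels,consensusLabels optional per-sample basis assignments
#'   and consensus cluster labels used to report consensus cluster ids.
#' @return `data.frame` with columns `gene`, `cluster`, `score`, sorted by
#'   cluster then decreasing score.
#' @export
extractSignatures <- function(W, geneIds = rownames(W), runLabels = NULL,
                              consensusLabels = NULL) {
  W <- as.matrix(W)
  k <- ncol(W)
  if (k < 2L) {
    stop("signature extraction requires k >= 2")
  }
  geneIds <- geneIds %||% paste0("g", seq_len(nrow(W)))
  rs <- rowSums(W)
  ok <- rs > 0
  P <- W[ok, , drop = FALSE] / rs[ok]
  plog <- P * log2(P)
  plog[P == 0] <- 0
  score <- 1 + rowSums(plog) / log2(k)
  thr <- stats::median(score) + 3 * .madRaw(score)
  sel <- score > thr
  basis <- max.col(W[ok, , drop = FALSE], ties.method = "first")
  cluster <- basis
  if (!is.null(runLabels) && !is.null(consensusLabels)) {
    map <- vapply(seq_len(k), function(i) {
      memb <- consensusLabels[runLabels == i]
      if (!length(memb)) return(i)
      as.integer(names(sort(table(memb), decreasing = TRUE))[1L])
    }, integer(1))
    cluster <- map[basis]
  }
  out <- data.frame(gene = geneIds[ok][sel],
                    cluster = cluster[sel],
                    score = score[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(out$cluster, -out$score), ]
  rownames(out) <- NULL
  out
}

#' Kim-Park basis-specificity scores
#'
#' The per-gene score used by [extractSignatures()], exposed for testing
#' and diagnostics.
#'
#' @param W non-negative gene-by-k matrix, `k >= 2`; all-zero rows get
#'   `NA`.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
kimParkScore <- function(W) {
  W <- as.matrix(W)
  k <- ncol(W)
  if (k < 2L) {
    stop("score undefined for k < 2")
  }
  rs <- rowSums(W)
  out <- rep(NA_real_, nrow(W))
  ok <- rs > 0
  P <- W[ok, , drop = FALSE] / rs[ok]
  plog <- P * log2(P)
  plog[P == 0] <- 0
  out[ok] <- 1 + rowSums(plog) / log2(k)
  names(out) <- rownames(W)
  out
}

#' @rdname accessors
#' @export
setMethod("chosenK", "ConsensusResult", function(x) x@chosenK)

#' @rdname accessors
#' @export
setMethod("sampleLabels", "ConsensusResult", function(x) x@labels)

#' @rdname accessors
#' @param k rank whose consensus matrix to return (default the chosen one).
#' @export
setMethod("consensusMatrix", "ConsensusResult", function(x, k = NULL) {
  k <- k %||% x@chosenK
  x@consensus[[as.character(k)]]
})

#' @rdname accessors
#' @export
setMethod("silhouetteByK", "ConsensusResult", function(x) x@silhouettes)

#' @rdname accessors
#' @export
setMethod("signatures", "ConsensusResult", function(x) x@signatures)

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf(
    "ConsensusResult: chosen k = %d (ranks %s), %d samples, %d signature genes\n",
    object@chosenK, paste(object@kRange, collapse = ","),
    length(object@labels), nrow(object@signatures)))
  cat("  mean silhouette by k:\n")
  print(round(object@silhouettes, 3))
})
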