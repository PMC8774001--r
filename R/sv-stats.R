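#' Breakpoint positions of a structural-variant call set
#'
#' Breakpoint multiplicity per SV type: DEL, DUP and INV contribute both
#' ends on their chromosome; an INS contributes its insertion site; each BND
#' mate line contributes one breakpoint on its own chromosome (mates carry
#' `MATEID`s, so a junction is never double-counted on a side).
#'
#' @param callSet an [SvCallSet-class].
#' @param chrom optional chromosome; when given, only that chromosome's
#'   breakpoint positions (numeric, 1-based) are returned.
#' @return with `chrom`: a numeric vector of positions; otherwise a
#'   `data.frame` with columns `chrom` and `pos`.
#' @export
breakpointsOf <- function(callSet, chrom = NULL) {
  rec <- svRecords(callSet)
  ## statistics are defined on retained (PASS + PRECISE) calls only, so a
  ## call set still carrying filtered records gives identical results to
  ## one read back from a filtered VCF
  rec <- rec[rec$filterPass & rec$precise, , drop = FALSE]
  chroms <- character(0)
  pos <- numeric(0)
  if (nrow(rec)) {
    two <- rec$svType %in% c("DEL", "DUP", "INV")
    ## a BND row carrying a MATEID is one mate line (its partner holds the
    ## other side); an unpaired BND row is a whole junction and supplies
    ## both sides itself
    bndJunction <- rec$svType == "BND" & is.na(rec$mateId)
    bndMate <- rec$svType == "BND" & !is.na(rec$mateId)
    one <- rec$svType == "INS" | bndMate
    chroms <- c(rec$chrom1[two], rec$chrom1[two],
                rec$chrom1[bndJunction], rec$chrom2[bndJunction],
                rec$chrom1[one])
    pos <- c(rec$pos1[two], rec$pos2[two],
             rec$pos1[bndJunction], rec$pos2[bndJunction],
             rec$pos1[one])
  }
  if (!is.null(chrom)) {
    return(pos[chroms == chrom])
  }
  data.frame(chrom = chroms, pos = pos, stringsAsFactors = FALSE)
}

#' Hypergeometric breakpoint enrichment of one chromosome
#'
#' Models the number of breakpoints falling on a chromosome as a
#' hypergeometric draw over base-pair positions: with `x` breakpoints on the
#' chromosome out of `k` genome-wide, chromosome size `m` and genome size
#' `N`, the p-value is the point-mass probability
#' `C(m, x) * C(N - m, k - x) / C(N, k)` (computed with log-gamma binomials).
#' Significance is declared at `p < alpha` (default `1e-3`). An upper-tail
#' sum over `x' >= x` is available via `tail = TRUE`; the point-mass form is
#' the default.
#'
#' @param callSet an [SvCallSet-class].
#' @param genome a [GenomeBuild-class].
#' @param chrom the chromosome to test.
#' @param alpha significance threshold.
#' @param tail use the upper-tail sum instead of the point mass.
#' @return one-row `data.frame` with `chrom`, `x`, `k`, `m`, `N`, `pValue`,
#'   `significant`.
#' @export
breakpointEnrichment <- function(callSet, genome, chrom, alpha = 1e-3,
                                 tail = FALSE) {
  if (!chrom %in% chromNames(genome)) {
    stop("unknown chromosome: ", chrom)
  }
  bp <- breakpointsOf(callSet)
  k <- nrow(bp)
  x <- sum(bp$chrom == chrom)
  m <- unname(chromLengths(genome)[chrom])
  N <- genomeSize(genome)
  p <- hyperPointMass(x, m, N, k, tail = tail)
  data.frame(chrom = chrom, x = x, k = k, m = m, N = N, pValue = p,
             significant = is.finite(p) && p < alpha,
             stringsAsFactors = FALSE)
}

#' Hypergeometric point-mass (and tail) probability
#'
#' Probability of exactly `x` successes when drawing `k` from a population
#' of `N` containing `m` successes, evaluated via log-gamma binomial
#' coefficients so base-pair-scale populations are handled exactly enough
#' (relative error ~1e-10). With `tail = TRUE` the probabilities for
#' `x' >= x` are summed.
#'
#' @param x observed successes.
#' @param m success states in the population.
#' @param N population size.
#' @param k draws.
#' @param tail sum the upper tail instead of the point mass.
#' @return a probability.
#' @export
hyperPointMass <- function(x, m, N, k, tail = FALSE) {
  stopifnot(m < N || (m == N), k >= 0, x >= 0)
  if (x > min(k, m)) {
    stop("x cannot exceed min(k, m)")
  }
  if (k == 0) {
    return(1)
  }
  if (k - x > N - m) {
    stop("k - x cannot exceed N - m")
  }
  xs <- if (tail) x:min(k, m) else x
  xs <- xs[k - xs <= N - m]
  p <- sum(exp(lchoose(m, xs) + lchoose(N - m, k - xs) - lchoose(N, k)))
  min(p, 1)
}

#' Monte-Carlo breakpoint-clustering test on one chromosome
#'
#' One-sided test of whether breakpoint positions are more clustered than
#' uniformly placed points. The positions are reduced to their spacings
#' (gaps, including the two terminal gaps to the chromosome ends). The
#' default statistic is the negative log-likelihood of the gaps under the
#' uniform (Dirichlet) spacing law, `-sum(log(g_i / L))`: it is minimal for
#' perfectly regular spacings and grows as points cluster, so regularly
#' spaced breakpoints never masquerade as clustered. The null distribution
#' is simulated by placing the same number of points uniformly on
#' `[0, chromLength)`; `method = "ks"` instead uses the one-sided
#' Kolmogorov-Smirnov excess of small gaps over their theoretical
#' `1 - (1 - g/L)^n` law, against the same simulated null.
#'
#' @param positions breakpoint positions on one chromosome (any order).
#' @param chromLength chromosome length in base pairs.
#' @param nSim number of null simulations (default 10000).
#' @param seed integer seed.
#' @param method `"gaps"` (default) or `"ks"`.
#' @return list with `pValue` (add-one Monte-Carlo p-value), `statistic`,
#'   `evaluable` (`FALSE`, with `pValue = NA`, when fewer than 3 positions
#'   are supplied -- deliberately distinct from p = 1).
#' @export
breakpointClusteringTest <- function(positions, chromLength, nSim = 10000L,
                                     seed = 1L,
                                     method = c("gaps", "ks")) {
  method <- match.arg(method)
  n <- length(positions)
  if (n < 3L) {
    return(list(pValue = NA_real_, statistic = NA_real_, evaluable = FALSE))
  }
  stopifnot(chromLength > 0, all(positions >= 0),
            all(positions <= chromLength))
  stat <- .gapStatistic(sort(positions), chromLength, method)
  nullStats <- withr::with_seed(seed, {
    U <- matrix(stats::runif(nSim * n, 0, chromLength), nrow = nSim)
    apply(U, 1L, function(u) .gapStatistic(sort(u), chromLength, method))
  })
  p <- (1 + sum(nullStats >= stat)) / (nSim + 1)
  list(pValue = p, statistic = stat, evaluable = TRUE)
}

.gapStatistic <- function(sortedPos, L, method) {
  g <- diff(c(0, sortedPos, L)) / L
  if (method == "gaps") {
    -sum(log(g))
  } else {
    n <- length(sortedPos)
    gs <- sort(g)
    Fg <- 1 - (1 - gs)^n        # marginal CDF of a uniform spacing
    max(seq_along(gs) / length(gs) - Fg)
  }
}
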