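#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative matrix `V (genes x samples)` into `W (genes x
#' k)` and `H (k x samples)` with the classical multiplicative update rules.
#' The default objective is the generalized Kullback-Leibler divergence
#' `D(V || WH) = sum(V log(V / WH) - V + WH)` with the Brunet update rules
#' (the standard choice for expression subtyping); the Euclidean (Frobenius)
#' objective is available via `objective = "frobenius"`. `W` and `H` are
#' initialized from seeded uniform draws scaled to the magnitude of `V`; the
#' objective is recorded at every iteration and is non-increasing by
#' construction.
#'
#' @param V non-negative matrix (no all-zero matrix allowed).
#' @param k factorization rank, `1 <= k <= min(dim(V))`.
#' @param maxIter maximum number of update iterations (default 500).
#' @param tol relative objective-change convergence tolerance (default
#'   `1e-5`).
#' @param seed integer seed for the random initialization.
#' @param objective `"kl"` (default) or `"frobenius"`.
#' @return list with `W`, `H`, `k`, `objective` (final value), `objTrace`
#'   (per-iteration values), `iterations`, `seed`.
#' @export
nmfFactorize <- function(V, k, maxIter = 500L, tol = 1e-5, seed = 1L,
                         objective = c("kl", "frobenius")) {
  objective <- match.arg(objective)
  V <- as.matrix(V)
  if (any(V < 0)) {
    stop("V must be non-negative")
  }
  if (all(V == 0)) {
    stop("V must not be all zero")
  }
  g <- nrow(V)
  s <- ncol(V)
  if (k < 1L || k > min(g, s)) {
    stop("k must satisfy 1 <= k <= min(dim(V))")
  }
  eps <- .Machine$double.eps
  scale <- sqrt(mean(V) / k)
  init <- withr::with_seed(seed, {
    list(W = matrix(stats::runif(g * k, 0.1, 1), g, k) * scale,
         H = matrix(stats::runif(k * s, 0.1, 1), k, s) * scale)
  })
  W <- init$W
  H <- init$H
  klDiv <- function(WH) {
    pos <- V > 0
    sum(WH) - sum(V) + sum(V[pos] * log(V[pos] / WH[pos]))
  }
  objTrace <- numeric(0)
  prev <- Inf
  for (it in seq_len(maxIter)) {
    if (objective == "kl") {
      WH <- W %*% H + eps
      H <- H * (crossprod(W, V / WH)) / pmax(colSums(W), eps)
      WH <- W %*% H + eps
      W <- W * ((V / WH) %*% t(H)) /
        matrix(pmax(rowSums(H), eps), g, k, byrow = TRUE)
      obj <- klDiv(W %*% H + eps)
    } else {
      H <- H * crossprod(W, V) / (crossprod(W, W) %*% H + eps)
      W <- W * (V %*% t(H)) / (W %*% H %*% t(H) + eps)
      obj <- sum((V - W %*% H)^2) / 2
    }
    objTrace <- c(objTrace, obj)
    if (is.finite(prev) && prev > 0 &&
        abs(prev - obj) / max(prev, eps) < tol) {
      prev <- obj
      break
    }
    prev <- obj
  }
  list(W = W, H = H, k = as.integer(k), objective = prev,
       objTrace = objTrace, iterations = length(objTrace),
       seed = as.integer(seed))
}

## Hard sample assignment of an NMF run: sample j goes to the basis with
## the largest coefficient (ties -> lowest index).
.nmfLabels <- function(run) {
  apply(run$H, 2L, which.max)
}
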