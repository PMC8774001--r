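test_that("size factors follow median-of-ratios up to overall scale", {
  m <- matrix(c(10, 20, 30, 40), 4, 3)
  rownames(m) <- paste0("g", 1:4)
  expect_equal(unname(sizeFactorsForCounts(m)), c(1, 1, 1))

  ## doubling one column doubles its factor relative to the others
  m2 <- m
  m2[, 2] <- 2 * m2[, 2]
  f <- sizeFactorsForCounts(m2)
  expect_equal(unname(f[2] / f[1]), 2, tolerance = 1e-12)
  expect_equal(unname(f[3] / f[1]), 1, tolerance = 1e-12)

  ## gene order is irrelevant
  expect_equal(unname(sizeFactorsForCounts(m2[c(3, 1, 4, 2), ])),
               unname(f))

  ## no all-positive gene -> total-count fallback with warning
  m3 <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_warning(f3 <- sizeFactorsForCounts(m3), "total-count")
  expect_equal(unname(f3), c(1, 1))
})

test_that("variance stabilization is a shifted log2 on normalized counts", {
  expect_equal(varianceStabilize(matrix(0), factors = 1)[1, 1], 0)
  expect_equal(varianceStabilize(matrix(3), factors = 1)[1, 1], 2)
  ## doubling a column's counts and its factor cancels
  m <- matrix(rpois(20, 30), 5, 4)
  f <- rep(1, 4)
  v1 <- varianceStabilize(m, f)
  m2 <- m
  m2[, 3] <- 2 * m2[, 3]
  f2 <- f
  f2[3] <- 2
  expect_equal(varianceStabilize(m2, f2), v1)
})

test_that("MAD gene selection is deterministic with documented ties", {
  m <- rbind(
    constant = rep(5, 4),
    spiky = c(0, 0, 0, 10),     # median 0, deviations {0,0,0,10}: MAD 0
    varied = c(0, 4, 8, 12),
    mild = c(1, 2, 3, 4))
  sel <- selectVariableGenes(m, 2)
  expect_equal(sel, c("varied", "mild"))
  ## the spiky gene has MAD 0 despite its outlier
  expect_equal(mmscape:::.madRaw(m["spiky", ]), 0)
  ## MAD ties broken by total expression: spiky (10) beats constant? no --
  ## constant has higher total (20); then gene id orders equals
  sel3 <- selectVariableGenes(m, 3)
  expect_equal(sel3[3], "constant")
  expect_warning(all4 <- selectVariableGenes(m, 10), "all")
  expect_equal(length(all4), 4L)
})

test_that("counts round-trip through TSV", {
  m <- matrix(rpois(12, 20), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("S", 1:4)))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCountsTsv(m, path)
  expect_equal(readCountsTsv(path), m)
})

test_that("KL factorization represents rank-1 data and never backtracks", {
  ## exactly representable rank-1 matrix at k = 1
  w <- c(1, 2, 3)
  h <- c(4, 1, 2, 0.5)
  V <- outer(w, h)
  run <- nmfFactorize(V, k = 1, maxIter = 2000, tol = 1e-12, seed = 3)
  expect_lt(run$objective, 1e-6)

  ## KL objective is non-increasing on arbitrary data
  set.seed(8)
  V2 <- matrix(rexp(20 * 8), 20, 8)
  run2 <- nmfFactorize(V2, k = 3, maxIter = 150, tol = 0, seed = 5)
  expect_true(all(diff(run2$objTrace) <= 1e-10))

  expect_error(nmfFactorize(matrix(0, 3, 3), 2), "zero")
  expect_error(nmfFactorize(V2, 9), "k must")
})

test_that("Kim-Park scores hit the entropy anchors exactly", {
  W <- rbind(oneBasis = c(5, 0, 0),
             uniform = c(2, 2, 2),
             zero = c(0, 0, 0),
             mixed = c(3, 1, 0))
  s <- kimParkScore(W)
  expect_equal(s[["oneBasis"]], 1)
  expect_equal(s[["uniform"]], 0)
  expect_true(is.na(s[["zero"]]))
  expect_true(s[["mixed"]] > 0 && s[["mixed"]] < 1)
  expect_error(kimParkScore(matrix(1, 2, 1)), "undefined")
})

test_that("consensus clustering nails well-separated blocks", {
  ## two clean sample blocks: 20 block-specific genes over a majority of
  ## shared background genes (so the signature threshold has a baseline)
  set.seed(2)
  V <- matrix(2, 60, 12) + matrix(abs(rnorm(60 * 12, 0, 0.01)), 60, 12)
  V[1:10, 1:5] <- 8
  V[11:20, 6:12] <- 8
  rownames(V) <- paste0("g", 1:60)
  colnames(V) <- paste0("S", 1:12)
  cons <- consensusCluster(V, kRange = 2:4, nRuns = 8, seed = 7,
                           maxIter = 300)
  expect_equal(chosenK(cons), 2L)
  truth <- rep(1:2, c(5, 7))
  expect_equal(ari(sampleLabels(cons), truth), 1)
  C <- consensusMatrix(cons, 2)
  expect_true(all(C >= 0 & C <= 1))
  expect_equal(diag(C), rep(1, 12), ignore_attr = TRUE)
  expect_equal(C, t(C))
  ## signatures come from the block-specific genes, mapped to the right
  ## consensus cluster
  sig <- signatures(cons)
  expect_gt(nrow(sig), 0)
  expect_true(all(sig$gene %in% paste0("g", 1:20)))
  lab1 <- unique(sampleLabels(cons)[1:5])
  g1 <- sig$gene[sig$cluster == lab1]
  expect_true(all(g1 %in% paste0("g", 1:10)))
})

test_that("two seeds agree on well-separated data after label matching", {
  V <- matrix(0.05, 30, 10)
  V[1:15, 1:4] <- 4
  V[16:30, 5:10] <- 4
  r1 <- nmfFactorize(V, 2, seed = 1)
  r2 <- nmfFactorize(V, 2, seed = 99)
  expect_equal(ari(apply(r1$H, 2, which.max), apply(r2$H, 2, which.max)), 1)
})
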