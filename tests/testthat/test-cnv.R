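test_that("log2 ratio normalization is library-size aware and masks zeros", {
  t1 <- covFromCounts(c(30, 60, 30))
  r1 <- covFromCounts(c(30, 30, 30))
  ## equal relative depth everywhere -> 0
  same <- normalizeLog2Ratio(r1, r1)
  expect_equal(S4Vectors::mcols(same)$ratio, c(0, 0, 0))

  ## doubling tumor counts and tumor total cancels
  t2 <- covFromCounts(2 * c(30, 30, 30))
  expect_equal(S4Vectors::mcols(normalizeLog2Ratio(t2, r1))$ratio,
               c(0, 0, 0))

  ## hand-computed oracle: middle bin log2((60/120)/(30/90)) = log2(1.5)
  r <- S4Vectors::mcols(normalizeLog2Ratio(t1, r1))$ratio
  expect_equal(r[2], log2(1.5), tolerance = 1e-12)
  expect_equal(r[1], log2((30 / 120) / (30 / 90)), tolerance = 1e-12)

  ## zero bins masked, not zero-filled
  tz <- covFromCounts(c(0, 60, 30))
  rz <- S4Vectors::mcols(suppressMessages(normalizeLog2Ratio(tz, r1)))$ratio
  expect_true(is.na(rz[1]))
  expect_false(anyNA(rz[-1]))

  ## mismatched grids rejected
  expect_error(normalizeLog2Ratio(covFromCounts(c(1, 2)), r1), "grid")
})

test_that("reference pooling sums counts and is order-invariant", {
  a <- covFromCounts(c(10, 20, 30))
  b <- covFromCounts(c(1, 2, 3))
  c3 <- covFromCounts(c(5, 5, 5))

  expect_equal(S4Vectors::mcols(bins(poolReferences(list(a))))$count,
               c(10, 20, 30))
  pooled <- poolReferences(list(a, a, a))
  expect_equal(S4Vectors::mcols(bins(pooled))$count, 3 * c(10, 20, 30))
  ## tripling the reference leaves downstream ratios unchanged
  expect_equal(S4Vectors::mcols(normalizeLog2Ratio(b, pooled))$ratio,
               S4Vectors::mcols(normalizeLog2Ratio(b, a))$ratio)

  p1 <- poolReferences(list(a, b, c3))
  p2 <- poolReferences(list(c3, a, b))
  expect_equal(S4Vectors::mcols(bins(p1))$count,
               S4Vectors::mcols(bins(p2))$count)
  expect_error(poolReferences(list()), "at least one")
})

test_that("segmentation recovers forced changepoints and nulls", {
  ## noiseless piecewise-constant input with one jump -> exactly 2 segments
  vals <- c(rep(0, 20), rep(1, 20))
  prof <- segmentProfile(ratioTrack(vals), seed = 1)
  tab <- segmentTable(prof)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$end[1], 20 * 100)
  expect_equal(tab$log2Ratio, c(0, 1))

  ## constant input -> one segment per chromosome
  flat <- segmentProfile(ratioTrack(rep(0.3, 30)), seed = 1)
  expect_equal(nrow(segmentTable(flat)), 1L)

  ## segment means conserve the bin mean (weighted by nBins)
  set.seed(7)
  noisy <- c(rnorm(50, 0, 0.1), rnorm(50, 1, 0.1), rnorm(50, -1, 0.1))
  p <- segmentProfile(ratioTrack(noisy), seed = 3)
  st <- segmentTable(p)
  expect_equal(sum(st$log2Ratio * st$nBins) / sum(st$nBins), mean(noisy),
               tolerance = 1e-9)
})

test_that("decreasing alpha never increases the number of segments", {
  set.seed(11)
  vals <- c(rnorm(60, 0, 0.3), rnorm(60, 0.6, 0.3), rnorm(60, 0, 0.3))
  track <- ratioTrack(vals)
  nseg <- vapply(c(0.05, 0.01, 1e-3, 1e-4), function(a) {
    nrow(segmentTable(segmentProfile(track, alpha = a, seed = 5,
                                     nPermutations = 400)))
  }, numeric(1))
  expect_true(all(diff(nseg) <= 0))
})

test_that("best-split selection matches naive exhaustive scoring", {
  naiveBest <- function(x, minBins) {
    n <- length(x)
    cand <- minBins:(n - minBins)
    ts <- vapply(cand, function(i) {
      a <- x[1:i]; b <- x[(i + 1):n]
      sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n - 2)
      den <- sqrt(sp2 * (1 / length(a) + 1 / length(b)))
      d <- abs(mean(a) - mean(b))
      if (den > 0) d / den else if (d > 0) Inf else 0
    }, numeric(1))
    list(stat = max(ts), idx = cand[which.max(ts)])
  }
  set.seed(21)
  for (n in c(6, 8, 10, 12)) {
    for (rep in 1:20) {
      x <- rnorm(n)
      got <- mmscape:::.bestSplit(x, 3L)
      want <- naiveBest(x, 3L)
      expect_equal(got$idx, want$idx)
      expect_equal(got$stat, want$stat, tolerance = 1e-12)
    }
  }
})

test_that("masked bins are excluded from statistics without breaking tiling", {
  vals <- c(rep(0, 15), NA, NA, rep(1, 15))
  prof <- segmentProfile(ratioTrack(vals), seed = 1)
  tab <- segmentTable(prof)
  expect_equal(nrow(tab), 2L)
  ## segments tile the chromosome end to end
  expect_equal(tab$start[1], 0)
  expect_equal(tab$end[2], 32 * 100)
  expect_equal(tab$end[1], tab$start[2])
  expect_equal(sum(tab$nBins), 30)   # masked bins counted in no segment
})

test_that("state calling rounds baseline-scaled linear ratios", {
  prof <- profileFromStates(c(2L, 2L))
  gr <- prof@segments
  S4Vectors::mcols(gr)$log2Ratio <- c(0, 1)
  p <- callStates(new("SegmentProfile", sampleId = "s", segments = gr,
                      baselinePloidy = 2))
  expect_equal(S4Vectors::mcols(p@segments)$state, c(2L, 4L))

  ## focal amplification scale: log2(67/2) maps back to 67 copies
  S4Vectors::mcols(gr)$log2Ratio <- c(log2(67 / 2), 0)
  p2 <- callStates(new("SegmentProfile", sampleId = "s", segments = gr,
                       baselinePloidy = 2))
  expect_equal(S4Vectors::mcols(p2@segments)$state[1], 67L)

  ## deep loss floors at 0
  S4Vectors::mcols(gr)$log2Ratio <- c(-10, 0)
  p3 <- callStates(new("SegmentProfile", sampleId = "s", segments = gr,
                       baselinePloidy = 2))
  expect_equal(S4Vectors::mcols(p3@segments)$state[1], 0L)
})

test_that("segment profiles round-trip through the TSV dialect", {
  prof <- callStates(profileFromStates(c(2, 4, 2)))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSegmentsTsv(prof, path)
  back <- readSegmentsTsv(path)[[1]]
  expect_equal(segmentTable(back)$state, segmentTable(prof)$state)
  expect_equal(segmentTable(back)$start, segmentTable(prof)$start)
})
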