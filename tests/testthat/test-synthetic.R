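test_that("SV simulation is deterministic and respects its contracts", {
  gb <- tinyGenome()
  reg <- list(chrom = "chr1", start = 4e6, end = 4.6e6)

  a <- simulateSvSample(gb, "high", seed = 3, ampRegion = reg)
  b <- simulateSvSample(gb, "high", seed = 3, ampRegion = reg)
  expect_identical(a, b)
  c2 <- simulateSvSample(gb, "high", seed = 4, ampRegion = reg)
  expect_false(identical(a$svs, c2$svs))

  ## low samples: requested number of passing background records,
  ## near-diploid states
  lo <- simulateSvSample(gb, "low", seed = 5,
                         params = list(nBackgroundSvs = 10L))
  rec <- svRecords(lo$svs)
  expect_equal(sum(rec$filterPass & rec$precise), 10L)
  expect_true(all(lo$plantedSegments$copyNumber %in% 1:3))

  ## high samples: oscillation, focal amplification, clustered window
  hi <- simulateSvSample(gb, "high", seed = 6,
                         params = list(oscillationCycles = 6L,
                                       ampCopyNumber = 40L),
                         ampRegion = reg)
  segs <- hi$plantedSegments
  ct <- segs[segs$chrom == hi$truth$ctChrom, ]
  expect_gte(sum(diff(ct$copyNumber) != 0), 12L)
  expect_equal(max(ct$copyNumber), 40L)
  expect_true(all(segs$copyNumber >= 0))
  ## window no wider than a quarter of the chromosome
  win <- hi$truth$window
  expect_lte(win[2] - win[1],
             0.25 * chromLengths(gb)[["chr1"]] + 1e4)
  ## clustered breakpoints live inside the window
  bp <- breakpointsOf(hi$svs)
  inWin <- bp$chrom == hi$truth$ctChrom & bp$pos >= win[1] &
    bp$pos <= win[2]
  expect_gte(sum(inWin), 40L)

  ## more breakpoints than representable bins is rejected
  expect_error(
    simulateSvSample(gb, "high", seed = 1,
                     params = list(nChromothripsisBreakpoints = 10000L),
                     ampRegion = reg),
    "representable")
})

test_that("coverage means scale with planted copy number", {
  gb <- makeGenome(c(chr1 = 5e6))
  segsCn2 <- data.frame(chrom = "chr1", start = 0, end = 5e6,
                        copyNumber = 2)
  ## dispersion -> 0 limit: tumor/normal ratio exactly 1
  cov <- simulateCoverage(segsCn2, gb, dispersion = 0, seed = 1)
  tc <- S4Vectors::mcols(bins(cov$tumor))$count
  nc <- S4Vectors::mcols(bins(cov$normal))$count
  expect_equal(tc, nc)

  ## CN-4 segment at zero dispersion doubles the ratio
  segsCn4 <- data.frame(chrom = "chr1", start = c(0, 2e6, 3e6),
                        end = c(2e6, 3e6, 5e6), copyNumber = c(2, 4, 2))
  cov4 <- simulateCoverage(segsCn4, gb, dispersion = 0, seed = 1)
  t4 <- S4Vectors::mcols(bins(cov4$tumor))$count
  n4 <- S4Vectors::mcols(bins(cov4$normal))$count
  mid <- 201:300
  expect_equal(t4[mid] / n4[mid], rep(2, 100))

  ## Monte-Carlo: CN-6 segment of >= 100 bins, empirical mean ratio
  ## within 10% of 3.0 at dispersion 0.05
  segsCn6 <- data.frame(chrom = "chr1", start = c(0, 2e6, 3.5e6),
                        end = c(2e6, 3.5e6, 5e6), copyNumber = c(2, 6, 2))
  cov6 <- simulateCoverage(segsCn6, gb, dispersion = 0.05, seed = 7)
  t6 <- S4Vectors::mcols(bins(cov6$tumor))$count
  n6 <- S4Vectors::mcols(bins(cov6$normal))$count
  seg <- 201:350
  expect_equal(mean(t6[seg] / pmax(n6[seg], 1)), 3, tolerance = 0.1)

  ## determinism
  covA <- simulateCoverage(segsCn6, gb, seed = 9)
  covB <- simulateCoverage(segsCn6, gb, seed = 9)
  expect_identical(S4Vectors::mcols(bins(covA$tumor))$count,
                   S4Vectors::mcols(bins(covB$tumor))$count)
})

test_that("expression programs shift the planted groups as configured", {
  labels <- rep(c(1, 2), each = 6)

  ## null effect: program genes show no systematic group difference
  ex0 <- simulateExpression(nGenes = 400, sampleLabels = labels,
                            programSizes = c(immune = 50,
                                             pigmentation = 50),
                            log2Effect = 0, seed = 2)
  imm <- ex0$counts[ex0$truth$immuneGenes, ]
  d <- mean(imm[, labels == 1]) / mean(imm[, labels == 2])
  expect_equal(d, 1, tolerance = 0.15)

  ## dispersion -> 0, effect 2: program-gene group ratio -> 4
  ex4 <- simulateExpression(nGenes = 400, sampleLabels = labels,
                            programSizes = c(immune = 50,
                                             pigmentation = 50),
                            log2Effect = 2, dispersion = 0, seed = 2)
  imm4 <- ex4$counts[ex4$truth$immuneGenes, ]
  expect_equal(mean(imm4[, labels == 1]) / mean(imm4[, labels == 2]), 4,
               tolerance = 0.02)

  ## marker genes are present by name in the right programs
  expect_true(all(c("IFNG", "IL1A", "IL1B", "IL2") %in%
                    ex4$truth$immuneGenes))
  expect_true(all(c("IL10", "IL11", "IL4", "TGFB1", "MITF") %in%
                    ex4$truth$pigmentationGenes))
  expect_error(simulateExpression(100, c(1, 3)), "labels")
  expect_error(
    simulateExpression(90, labels,
                       programSizes = c(immune = 50, pigmentation = 50)),
    "less than")
})

test_that("cohort simulation matches the study design and is reproducible", {
  cfg <- cohortConfig()
  cfg$coverage$binSize <- 5e4       # coarse grid keeps the fixture light
  cfg$expression$nGenes <- 300L
  cfg$expression$programSizes <- c(immune = 40L, pigmentation = 40L)
  sim <- simulateCohort(cfg, seed = 21)

  expect_equal(length(sim$samples), 32L)
  expect_equal(sum(sim$truth$exprGroupTruth == 1), 12L)
  expect_equal(sum(sim$truth$svLabelTruth == "low"), 12L)
  expect_equal(sum(sim$truth$svLabelTruth == "high"), 20L)
  ## full concordance: expression group determines the SV label
  expect_true(all((sim$truth$exprGroupTruth == 1) ==
                    (sim$truth$svLabelTruth == "low")))
  ## every high sample carries a designated chromothripsis chromosome
  highs <- names(which(sim$truth$svLabelTruth == "high"))
  expect_true(all(!vapply(sim$truth$chromothripsisChroms[highs], is.null,
                          logical(1))))
  ## planted copy numbers are never negative
  expect_true(all(vapply(sim$truth$plantedSegments,
                         function(s) all(s$copyNumber >= 0), logical(1))))

  ## byte-identical on-disk output for the same seed
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeCohort(sim, d1)
  writeCohort(simulateCohort(cfg, seed = 21), d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 5e6),
                     readBin(file.path(d2, f), "raw", 5e6))
  }
})
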