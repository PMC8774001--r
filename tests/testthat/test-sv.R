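makeVcf <- function(lines, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1,length=10000000>",
           "##contig=<ID=chr2,length=6000000>",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"t\">",
           "##INFO=<ID=CHR2,Number=1,Type=String,Description=\"t\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"t\">",
           "##INFO=<ID=PE,Number=1,Type=Integer,Description=\"t\">",
           "##INFO=<ID=PRECISE,Number=0,Type=Flag,Description=\"t\">",
           "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"t\">",
           "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"t\">",
           "##FILTER=<ID=LowQual,Description=\"t\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(hdr, lines), path)
  path
}

test_that("VCF ingestion keeps only PASS and PRECISE records", {
  path <- withr::local_tempfile(fileext = ".vcf")
  keepers <- sprintf(
    "chr1\t%d\tDEL%05d\tN\t<DEL>\t.\tPASS\tPRECISE;SVTYPE=DEL;END=%d;PE=9",
    1:5 * 1e5, 1:5, 1:5 * 1e5 + 5e4)
  dropped <- c(
    "chr1\t700000\tD1\tN\t<DEL>\t.\tPASS\tIMPRECISE;SVTYPE=DEL;END=750000",
    "chr1\t800000\tD2\tN\t<DUP>\t.\tLowQual\tPRECISE;SVTYPE=DUP;END=850000",
    "chr2\t100000\tD3\tN\t<INV>\t.\tLowQual\tIMPRECISE;SVTYPE=INV;END=200000")
  makeVcf(c(keepers, dropped), path)
  cs <- suppressMessages(readSvVcf(path))
  expect_equal(nrow(svRecords(cs)), 5L)
  expect_true(all(svRecords(cs)$svType == "DEL"))
  expect_true(all(svRecords(cs)$precise & svRecords(cs)$filterPass))
})

test_that("BND ALT bracket coordinates are parsed", {
  path <- withr::local_tempfile(fileext = ".vcf")
  makeVcf(c("chr1\t1000\tB1\tA\tA[chr2:12345[\t.\tPASS\tPRECISE;SVTYPE=BND;PE=4"),
          path)
  rec <- svRecords(readSvVcf(path))
  expect_equal(rec$chrom2, "chr2")
  expect_equal(rec$pos2, 12345)
  expect_equal(rec$svType, "BND")
})

test_that("empty VCF body yields an empty call set without error", {
  path <- withr::local_tempfile(fileext = ".vcf")
  makeVcf(character(0), path)
  cs <- readSvVcf(path)
  expect_s4_class(cs, "SvCallSet")
  expect_equal(nrow(svRecords(cs)), 0L)
  expect_equal(nrow(breakpointsOf(cs)), 0L)
})

test_that("records without SVTYPE are skipped with a warning", {
  path <- withr::local_tempfile(fileext = ".vcf")
  makeVcf(c("chr1\t1000\tX\tA\tT\t.\tPASS\tPE=4",
            "chr1\t2000\tD\tN\t<DEL>\t.\tPASS\tPRECISE;SVTYPE=DEL;END=3000"),
          path)
  expect_warning(cs <- readSvVcf(path), "SVTYPE")
  expect_equal(nrow(svRecords(cs)), 1L)
})

test_that("a generated call set round-trips through VCF on disk", {
  gb <- tinyGenome()
  sv <- simulateSvSample(gb, "high", seed = 4, sampleId = "T",
                         ampRegion = list(chrom = "chr1", start = 4e6,
                                          end = 4.6e6))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeSvVcf(sv$svs, gb, path)
  back <- suppressMessages(readSvVcf(path, sampleId = "T"))
  ## the breakpoint multiset is preserved (records re-enter as mate pairs,
  ## so only order may differ)
  srt <- function(bp) {
    bp <- bp[order(bp$chrom, bp$pos), ]
    rownames(bp) <- NULL
    bp
  }
  expect_equal(srt(breakpointsOf(back)), srt(breakpointsOf(sv$svs)))
})

test_that("breakpoint multiplicity follows the SV type", {
  one <- svSet(data.frame(svType = "DEL", chrom1 = "chr1", pos1 = 100,
                          chrom2 = "chr1", pos2 = 500))
  expect_equal(nrow(breakpointsOf(one)), 2L)
  expect_equal(breakpointsOf(one, "chr1"), c(100, 500))

  ## interchromosomal BND mate pair: one breakpoint on each chromosome
  pair <- svSet(data.frame(
    svType = c("BND", "BND"), chrom1 = c("chr1", "chr2"),
    pos1 = c(100, 900), chrom2 = c("chr2", "chr1"), pos2 = c(900, 100),
    mateId = c("B2", "B1")))
  bp <- breakpointsOf(pair)
  expect_equal(nrow(bp), 2L)
  expect_equal(sort(bp$chrom), c("chr1", "chr2"))

  ## 2 DEL + 1 INV + 1 INS -> 7 breakpoints
  mixed <- svSet(data.frame(
    svType = c("DEL", "DEL", "INV", "INS"), chrom1 = "chr1",
    pos1 = c(1, 10, 100, 1000), chrom2 = "chr1",
    pos2 = c(5, 50, 500, 1000)))
  expect_equal(nrow(breakpointsOf(mixed)), 7L)
})

test_that("hypergeometric point mass matches exact binomial arithmetic", {
  ## worked example: N=20, m=5, k=4, x=2
  expect_equal(hyperPointMass(2, 5, 20, 4),
               choose(5, 2) * choose(15, 2) / choose(20, 4),
               tolerance = 1e-14)
  expect_equal(hyperPointMass(2, 5, 20, 4), 1050 / 4845, tolerance = 1e-12)
  ## degenerate draws
  expect_equal(hyperPointMass(0, 5, 20, 0), 1)
  expect_equal(hyperPointMass(1, 1, 2, 1), 0.5)
  expect_error(hyperPointMass(5, 3, 20, 4), "exceed")
})

test_that("enrichment flags a breakpoint-loaded chromosome", {
  gb <- tinyGenome()
  rec <- data.frame(svType = rep("DEL", 15), chrom1 = "chr1",
                    pos1 = seq(1e6, 2e6, length.out = 15),
                    chrom2 = "chr1",
                    pos2 = seq(1e6, 2e6, length.out = 15) + 1e4)
  enr <- breakpointEnrichment(svSet(rec), gb, "chr1")
  expect_equal(enr$x, 30)
  expect_equal(enr$k, 30)
  expect_equal(enr$N, 16e6)
  ## all 30 of 30 breakpoints on a 10/16 chromosome: point mass ~ (10/16)^30
  expect_equal(enr$pValue, (10 / 16)^30, tolerance = 1e-4)
  expect_true(enr$significant)
  ## upper tail equals the point mass at the top of the support here
  enrT <- breakpointEnrichment(svSet(rec), gb, "chr1", tail = TRUE)
  expect_equal(enrT$pValue, enr$pValue, tolerance = 1e-12)
})

test_that("clustering test separates clustered from regular positions", {
  L <- 1e6
  ## 20 points inside 1% of the chromosome
  clustered <- seq(5e5, 5e5 + 0.01 * L, length.out = 20)
  pc <- breakpointClusteringTest(clustered, L, nSim = 2000, seed = 9)
  expect_true(pc$evaluable)
  expect_lt(pc$pValue, 0.005)

  ## perfectly regular quantile positions are the least clustered input
  regular <- (1:20) / 21 * L
  pr <- breakpointClusteringTest(regular, L, nSim = 2000, seed = 9)
  expect_gt(pr$pValue, 0.5)

  ## order invariance for a fixed seed
  p1 <- breakpointClusteringTest(clustered, L, nSim = 500, seed = 3)
  p2 <- breakpointClusteringTest(rev(clustered), L, nSim = 500, seed = 3)
  expect_equal(p1$pValue, p2$pValue)

  ## fewer than 3 positions is not evaluable (distinct from p = 1)
  ne <- breakpointClusteringTest(c(1, 2), L, nSim = 100, seed = 1)
  expect_false(ne$evaluable)
  expect_true(is.na(ne$pValue))
})

test_that("oscillation transitions count adjacent state changes", {
  expect_equal(oscillationTransitions(profileFromStates(2L), "chr1"), 0L)
  expect_equal(
    oscillationTransitions(profileFromStates(c(2, 3, 2, 3, 2)), "chr1"), 4L)
  expect_equal(
    oscillationTransitions(profileFromStates(c(2, 2, 2)), "chr1"), 0L)
  expect_warning(
    z <- oscillationTransitions(profileFromStates(c(2, 3)), "chrX"),
    "no segments")
  expect_equal(z, 0L)
})

test_that("amplification threshold is the 90th percentile of gains", {
  expect_equal(
    amplificationThreshold(profileFromStates(c(3, 3, 3, 2))), 3)
  gains <- c(3, 4, 5, 6, 7, 8, 9, 10, 20, 67)
  expect_equal(
    amplificationThreshold(profileFromStates(c(gains, 2))), 24.7,
    tolerance = 1e-12)
  ## all-diploid profile -> no-amplification sentinel
  expect_true(is.na(amplificationThreshold(profileFromStates(c(2, 2)))))
})

test_that("the burden rule needs oscillation AND a major amplification", {
  ## 12 transitions plus a 40-copy segment -> high
  osc <- c(rep(c(3, 1), 6), 40, rep(2, 3))
  hi <- classifySvBurden(profileFromStateList(list(chr1 = osc,
                                                   chr2 = rep(2, 5))))
  expect_equal(burdenLabel(hi), "high")
  expect_equal(burdenEvidence(hi)$transitionsPerChrom[["chr1"]], 13L)

  ## flat diploid genome -> low
  lo <- classifySvBurden(profileFromStateList(list(chr1 = rep(2, 10))))
  expect_equal(burdenLabel(lo), "low")

  ## oscillation without any gain above threshold stays low
  oscOnly <- classifySvBurden(profileFromStates(rep(c(2, 1), 8)))
  expect_equal(burdenLabel(oscOnly), "low")

  emptyGr <- GenomicRanges::GRanges()
  S4Vectors::mcols(emptyGr) <- S4Vectors::DataFrame(
    nBins = integer(0), log2Ratio = numeric(0), state = integer(0))
  expect_error(classifySvBurden(
    new("SegmentProfile", sampleId = "e", segments = emptyGr,
        baselinePloidy = 2)),
    "empty")
})

test_that("burden classification is invariant to state-preserving splits", {
  states <- c(rep(c(3, 1), 6), 40, 2, 2)
  whole <- classifySvBurden(profileFromStates(states))
  split <- classifySvBurden(profileFromStates(rep(states, each = 2)))
  expect_equal(burdenLabel(split), burdenLabel(whole))
  expect_equal(burdenEvidence(split)$maxState,
               burdenEvidence(whole)$maxState)
  expect_equal(burdenEvidence(split)$transitionsPerChrom,
               burdenEvidence(whole)$transitionsPerChrom)
})

test_that("imprecise records never change downstream statistics", {
  gb <- tinyGenome()
  base <- data.frame(svType = c("DEL", "INV"), chrom1 = "chr1",
                     pos1 = c(1e5, 2e5), chrom2 = "chr1",
                     pos2 = c(1.5e5, 2.5e5))
  base$precise <- TRUE
  extra <- rbind(base, data.frame(
    svType = "DUP", chrom1 = "chr2", pos1 = 1e5, chrom2 = "chr2",
    pos2 = 9e5, precise = FALSE))
  a <- svSet(base)
  b <- svSet(extra)
  expect_equal(breakpointsOf(a), breakpointsOf(b))
  expect_equal(breakpointEnrichment(a, gb, "chr1")$pValue,
               breakpointEnrichment(b, gb, "chr1")$pValue)
})

test_that("candidate calling requires all three chromothripsis features", {
  gb <- tinyGenome()
  ## clustered breakpoints but flat copy number -> not flagged
  pos <- seq(4e6, 4.1e6, length.out = 20)
  rec <- data.frame(svType = "DEL", chrom1 = "chr1", pos1 = pos,
                    chrom2 = "chr1", pos2 = pos + 2e3)
  flat <- callStates(segmentProfile(ratioTrack(rep(0, 50), binSize = 2e5),
                                    seed = 1))
  cand <- chromothripsisCandidates(flat, svSet(rec), gb, nSim = 500,
                                   seed = 2)
  chr1 <- cand[cand$chrom == "chr1", ]
  expect_lt(chr1$clusterP, 0.05)        # clustering present
  expect_false(chr1$flagged)            # but no oscillation
})
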