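## Synthetic-cohort generator: seeded, deterministic emulation of the four
## inputs the pipeline consumes (binned tumor/normal coverage, Delly-style
## SV call sets, an expression count matrix, a genome table) plus the
## ground-truth labels needed for recovery tests. One global seed; every
## sample and stage draws from its own derived substream, so adding a
## sample never changes the draws of earlier ones.

#' Default structural-variant generator parameters
#'
#' @return named list: `nBackgroundSvs` (sparse genome-wide SVs every
#'   sample receives), `nChromothripsisBreakpoints` (breakpoints planted in
#'   the shattered window of a high-SV sample), `oscillationCycles` (pairs
#'   of alternating copy-number states in the window) and `ampCopyNumber`
#'   (state of the planted focal amplification).
#' @export
svSimParams <- function() {
  list(nBackgroundSvs = 10L, nChromothripsisBreakpoints = 40L,
       oscillationCycles = 6L, ampCopyNumber = 40L)
}

## Snap a coordinate to the bin grid.
.snap <- function(x, align) round(x / align) * align

#' Simulate one sample's SV call set and planted copy-number segments
#'
#' A `"low"` sample receives `nBackgroundSvs` uniformly placed background
#' SVs and a near-diploid genome (a couple of mild single-copy events,
#' states in 1..3). A `"high"` sample additionally gets one designated
#' chromosome with: `nChromothripsisBreakpoints` breakpoints clustered in a
#' window of at most 25% of the chromosome, alternating copy-number states
#' producing at least `2 * oscillationCycles` state transitions, and one
#' focal segment at `ampCopyNumber` covering `ampRegion` (plus random
#' bin-aligned flanks; `ampFlankZero = TRUE` pins the amplified interval to
#' the region exactly).
#'
#' @param genome a [GenomeBuild-class].
#' @param label `"high"` or `"low"`.
#' @param params see [svSimParams()].
#' @param seed integer seed.
#' @param sampleId sample identifier.
#' @param ampRegion list with `chrom`, `start`, `end` (0-based half-open)
#'   locating the recurrent focal amplification; defaults to a 0.6 Mb
#'   region at 16.2 Mb of the first chromosome.
#' @param ampFlankZero plant the amplified segment with zero flanks.
#' @param align bin-grid alignment of planted boundaries (default 10 kb).
#' @return list with `svs` ([SvCallSet-class]), `plantedSegments`
#'   (`data.frame` `chrom`, `start`, `end`, `copyNumber`, 0-based
#'   half-open, tiling the genome) and `truth` (label, designated
#'   chromosome, window).
#' @export
simulateSvSample <- function(genome, label = c("low", "high"),
                             params = svSimParams(), seed = 1L,
                             sampleId = "sample",
                             ampRegion = NULL, ampFlankZero = FALSE,
                             align = 1e4) {
  label <- match.arg(label)
  p <- utils::modifyList(svSimParams(), params)
  stopifnot(p$oscillationCycles >= 0, p$ampCopyNumber >= 0)
  lens <- chromLengths(genome)
  if (is.null(ampRegion)) {
    ampRegion <- list(chrom = names(lens)[1L], start = 16.2e6, end = 16.8e6)
  }
  withr::with_seed(seed, {
    ctChrom <- NULL
    window <- NULL
    events <- list()   # per-chrom (start, end, cn) overlays on CN-2 baseline
    rec <- list()

    ## mild near-diploid events on non-designated chromosomes
    mildChroms <- setdiff(names(lens), if (label == "high") ampRegion$chrom
                          else character(0))
    mildChroms <- utils::head(sample(mildChroms), 2L)
    for (ch in mildChroms) {
      w <- .snap(stats::runif(1, 1e6, 3e6), align)
      s <- .snap(stats::runif(1, 0, lens[ch] - w), align)
      events[[length(events) + 1L]] <- data.frame(
        chrom = ch, start = s, end = s + w,
        copyNumber = sample(c(1L, 3L), 1L), stringsAsFactors = FALSE)
    }

    ## background SVs, uniform over the genome
    nBg <- p$nBackgroundSvs
    if (nBg > 0) {
      types <- sample(c("DEL", "DUP", "INV", "BND", "INS"), nBg,
                      replace = TRUE, prob = c(.3, .25, .2, .15, .1))
      chr1 <- sample(names(lens), nBg, replace = TRUE,
                     prob = lens / sum(lens))
      for (i in seq_len(nBg)) {
        ln <- lens[chr1[i]]
        if (types[i] == "BND") {
          ch2 <- sample(names(lens), 1L)
          rec[[length(rec) + 1L]] <- data.frame(
            svType = "BND", chrom1 = chr1[i],
            pos1 = ceiling(stats::runif(1, 1, ln)),
            chrom2 = ch2, pos2 = ceiling(stats::runif(1, 1, lens[ch2])),
            precise = TRUE, filterPass = TRUE, readSupport = 6L,
            mateId = NA_character_, stringsAsFactors = FALSE)
        } else {
          sz <- if (types[i] == "INS") 0 else round(stats::runif(1, 5e4, 5e5))
          s <- ceiling(stats::runif(1, 1, ln - sz))
          rec[[length(rec) + 1L]] <- data.frame(
            svType = types[i], chrom1 = chr1[i], pos1 = s,
            chrom2 = chr1[i], pos2 = s + sz,
            precise = TRUE, filterPass = TRUE, readSupport = 6L,
            mateId = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }

    if (label == "high") {
      ctChrom <- ampRegion$chrom
      ln <- lens[ctChrom]
      w <- .snap(0.25 * ln, align)
      mid <- (ampRegion$start + ampRegion$end) / 2
      w0 <- .snap(min(max(0, mid - w / 2), ln - w), align)
      w1 <- w0 + w
      window <- c(w0, w1)

      ## clustered breakpoints inside the window, paired into SV records
      nBp <- 2L * (p$nChromothripsisBreakpoints %/% 2L)
      if (nBp > w / align) {
        stop("more chromothripsis breakpoints than representable bins")
      }
      if (nBp > 0) {
        bp <- sort(ceiling(stats::runif(nBp, w0 + 1, w1)))
        ctTypes <- sample(c("DEL", "DUP", "INV"), nBp / 2L, replace = TRUE)
        for (i in seq_len(nBp / 2L)) {
          rec[[length(rec) + 1L]] <- data.frame(
            svType = ctTypes[i], chrom1 = ctChrom, pos1 = bp[2L * i - 1L],
            chrom2 = ctChrom, pos2 = bp[2L * i],
            precise = TRUE, filterPass = TRUE, readSupport = 10L,
            mateId = NA_character_, stringsAsFactors = FALSE)
        }
      }

      ## oscillating states + focal amplification inside the window
      flankL <- if (ampFlankZero) 0 else align * sample(0:15, 1L)
      flankR <- if (ampFlankZero) 0 else align * sample(0:15, 1L)
      ampS <- max(w0, .snap(ampRegion$start, align) - flankL)
      ampE <- min(w1, .snap(ampRegion$end, align) + flankR)
      half <- p$oscillationCycles
      oscStates <- function(n, first) {
        if (n <= 0) return(integer(0))
        st <- rep(c(first, if (first == 3L) 1L else 3L), length.out = n)
        st
      }
      addOsc <- function(from, to, states) {
        n <- length(states)
        if (n == 0L || to - from < n * 3 * align) {
          ## window arm too small for the full oscillation: scale down
          n <- max(0L, as.integer((to - from) %/% (3 * align)))
          states <- states[seq_len(n)]
        }
        if (!n) return(invisible(NULL))
        cuts <- .snap(seq(from, to, length.out = n + 1L), align)
        for (i in seq_len(n)) {
          if (cuts[i + 1L] > cuts[i]) {
            events[[length(events) + 1L]] <<- data.frame(
              chrom = ctChrom, start = cuts[i], end = cuts[i + 1L],
              copyNumber = states[i], stringsAsFactors = FALSE)
          }
        }
      }
      addOsc(w0, ampS, oscStates(half, 3L))
      addOsc(ampE, w1, oscStates(half, 3L))
      events[[length(events) + 1L]] <- data.frame(
        chrom = ctChrom, start = ampS, end = ampE,
        copyNumber = p$ampCopyNumber, stringsAsFactors = FALSE)
    }

    ## a few decoy records that PASS/PRECISE filtering must drop
    for (i in 1:2) {
      ch <- sample(names(lens), 1L)
      s <- ceiling(stats::runif(1, 1, lens[ch] - 1e5))
      rec[[length(rec) + 1L]] <- data.frame(
        svType = "DEL", chrom1 = ch, pos1 = s, chrom2 = ch, pos2 = s + 1e5,
        precise = (i == 1L), filterPass = (i != 1L), readSupport = 2L,
        mateId = NA_character_, stringsAsFactors = FALSE)
    }

    planted <- .tileSegments(genome, events)
    list(svs = svCallSet(sampleId, do.call(rbind, rec)),
         plantedSegments = planted,
         truth = list(label = label, ctChrom = ctChrom, window = window))
  })
}

## Turn overlay events on a CN-2 baseline into a genome tiling
## (0-based half-open, sorted; later events win on overlap).
.tileSegments <- function(genome, events) {
  lens <- chromLengths(genome)
  out <- list()
  ev <- if (length(events)) do.call(rbind, events) else NULL
  for (ch in names(lens)) {
    cuts <- c(0, lens[ch])
    e <- if (!is.null(ev)) ev[ev$chrom == ch, , drop = FALSE] else NULL
    if (!is.null(e) && nrow(e)) {
      cuts <- sort(unique(c(cuts, e$start, e$end)))
    }
    for (i in seq_len(length(cuts) - 1L)) {
      s <- cuts[i]
      en <- cuts[i + 1L]
      cn <- 2L
      if (!is.null(e) && nrow(e)) {
        hit <- which(e$start <= s & e$end >= en)
        if (length(hit)) cn <- e$copyNumber[hit[length(hit)]]
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s, end = en, copyNumber = cn,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  ## merge adjacent equal-state tiles
  keep <- c(TRUE, !(tab$chrom[-1L] == tab$chrom[-nrow(tab)] &
                      tab$copyNumber[-1L] == tab$copyNumber[-nrow(tab)]))
  grp <- cumsum(keep)
  merged <- do.call(rbind, lapply(split(tab, grp), function(g) {
    data.frame(chrom = g$chrom[1L], start = min(g$start), end = max(g$end),
               copyNumber = g$copyNumber[1L], stringsAsFactors = FALSE)
  }))
  merged <- merged[order(match(merged$chrom, names(lens)), merged$start), ]
  rownames(merged) <- NULL
  merged
}

#' Simulate binned tumor and normal coverage from planted segments
#'
#' Normal bin counts are negative binomial with mean `meanDepthPerBin`
#' (scaled for short terminal bins); tumor bin means are additionally
#' scaled by `copyNumber / 2` of the planted segment covering the bin
#' midpoint. `dispersion = 0` returns the deterministic rounded means (the
#' point-mass limit of the NB), which makes limit behaviour exactly
#' testable.
#'
#' @param plantedSegments `data.frame` with `chrom`, `start`, `end`
#'   (0-based half-open), `copyNumber`.
#' @param genome a [GenomeBuild-class].
#' @param binSize bin width in bp (default 10 kb).
#' @param meanDepthPerBin expected reads per full bin in the normal.
#' @param dispersion NB dispersion (variance `mu + dispersion * mu^2`).
#' @param seed integer seed.
#' @param sampleId sample identifier prefix.
#' @return list with `tumor` and `normal` [BinnedCoverage-class] objects on
#'   the same grid.
#' @export
simulateCoverage <- function(plantedSegments, genome, binSize = 1e4,
                             meanDepthPerBin = 100, dispersion = 0.02,
                             seed = 1L, sampleId = "sample") {
  lens <- chromLengths(genome)
  if (any(lens < binSize)) {
    stop("binSize must fit at least one bin per chromosome")
  }
  chrom <- character(0); s0 <- numeric(0); e0 <- numeric(0)
  for (ch in names(lens)) {
    st <- seq(0, lens[ch] - 1, by = binSize)
    chrom <- c(chrom, rep(ch, length(st)))
    s0 <- c(s0, st)
    e0 <- c(e0, pmin(st + binSize, lens[ch]))
  }
  frac <- (e0 - s0) / binSize
  cn <- rep(2, length(s0))
  mids <- (s0 + e0) / 2
  for (i in seq_len(nrow(plantedSegments))) {
    seg <- plantedSegments[i, ]
    hit <- chrom == seg$chrom & mids >= seg$start & mids < seg$end
    cn[hit] <- seg$copyNumber
  }
  muN <- meanDepthPerBin * frac
  muT <- muN * cn / 2
  draw <- function(mu) {
    if (dispersion <= 0) {
      round(mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
  }
  withr::with_seed(seed, {
    nc <- draw(muN)
    tc <- draw(muT)
  })
  list(
    tumor = binnedCoverage(paste0(sampleId, "_tumor"), chrom, s0, e0, tc,
                           binSize, genome),
    normal = binnedCoverage(paste0(sampleId, "_normal"), chrom, s0, e0, nc,
                            binSize, genome))
}

## Marker genes carried by name in the expression matrix so downstream
## scoring is name-driven. TIM3 is carried under its gene symbol HAVCR2.
.immuneMarkers <- c("IFNG", "IL1A", "IL1B", "IL2", "CTLA4", "LAG3",
                    "HAVCR2", "IL2RG")
.pigmentationMarkers <- c("IL10", "IL11", "IL4", "TGFB1", "MITF", "TERT",
                          "KIT", "POM121")

#' Simulate a gene-by-sample expression count matrix with two programs
#'
#' Negative-binomial counts around lognormal per-gene baselines, with two
#' latent gene programs: immune-program genes have their mean multiplied by
#' `2^log2Effect` in group-1 samples, pigmentation/oncogene-program genes
#' likewise in group-2 samples; all other genes are exchangeable across
#' groups. The named cytokine and checkpoint markers (IFNG, IL1A, IL1B,
#' IL2, CTLA4, LAG3, HAVCR2, IL2RG) head the immune program and the
#' immunosuppressive/pigmentation markers (IL10, IL11, IL4, TGFB1, MITF,
#' TERT, KIT, POM121) head the pigmentation program, so name-driven
#' association scoring is exercisable. `dispersion = 0` gives deterministic
#' rounded means.
#'
#' @param nGenes total number of genes.
#' @param sampleLabels vector of group labels, values 1 or 2.
#' @param programSizes named vector `c(immune = , pigmentation = )`; must
#'   sum to less than `nGenes`.
#' @param log2Effect log2 fold effect of a program in its group (>= 0).
#' @param baselineMean median baseline expression.
#' @param dispersion NB dispersion.
#' @param seed integer seed.
#' @return list with `counts` (matrix, gene rownames, sample colnames) and
#'   `truth` (`immuneGenes`, `pigmentationGenes`, `labels`).
#' @export
simulateExpression <- function(nGenes = 2000L, sampleLabels,
                               programSizes = c(immune = 300L,
                                                pigmentation = 300L),
                               log2Effect = 2, baselineMean = 50,
                               dispersion = 0.3, seed = 1L) {
  sampleLabels <- as.integer(sampleLabels)
  if (!all(sampleLabels %in% c(1L, 2L))) {
    stop("sample labels must be 1 or 2")
  }
  if (sum(programSizes) >= nGenes) {
    stop("program sizes must sum to less than nGenes")
  }
  if (log2Effect < 0) {
    stop("log2Effect must be >= 0")
  }
  nImm <- programSizes[["immune"]]
  nPig <- programSizes[["pigmentation"]]
  pad <- function(markers, n, prefix) {
    c(markers[seq_len(min(length(markers), n))],
      if (n > length(markers))
        sprintf("%s_%04d", prefix, seq_len(n - length(markers))))
  }
  immGenes <- pad(.immuneMarkers, nImm, "IMM")
  pigGenes <- pad(.pigmentationMarkers, nPig, "PIG")
  bgGenes <- sprintf("BG_%05d", seq_len(nGenes - nImm - nPig))
  geneIds <- c(immGenes, pigGenes, bgGenes)
  ns <- length(sampleLabels)
  withr::with_seed(seed, {
    base <- stats::rlnorm(nGenes, meanlog = log(baselineMean), sdlog = 0.5)
    mu <- matrix(base, nGenes, ns)
    eff <- 2^log2Effect
    mu[seq_len(nImm), sampleLabels == 1L] <-
      mu[seq_len(nImm), sampleLabels == 1L] * eff
    mu[nImm + seq_len(nPig), sampleLabels == 2L] <-
      mu[nImm + seq_len(nPig), sampleLabels == 2L] * eff
    counts <- if (dispersion <= 0) {
      round(mu)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
             nGenes, ns)
    }
  })
  dimnames(counts) <- list(geneIds,
                           sprintf("S%02d", seq_len(ns)))
  list(counts = counts,
       truth = list(immuneGenes = immGenes, pigmentationGenes = pigGenes,
                    labels = sampleLabels))
}

#' Default cohort configuration
#'
#' The generator's study conditions: 32 samples split 12 (expression group
#' 1, low-SV) versus 20 (group 2, high-SV) with fully concordant labels by
#' default, a scaled-down four-chromosome 100 Mb genome with the recurrent
#' focal amplification planted at chr1:16.2-16.8 Mb, 10 kb coverage bins at
#' 100 reads mean depth, and 2000 genes with two 300-gene programs at a
#' 4-fold (log2 effect 2) program effect.
#'
#' @return nested configuration list (see [simulateCohort()]).
#' @export
cohortConfig <- function() {
  list(
    nSamples = 32L,
    nGroup1 = 12L,
    concordance = 1.0,
    genomeLengths = c(chr1 = 40e6, chr2 = 25e6, chr3 = 20e6, chr4 = 15e6),
    ampRegion = list(chrom = "chr1", start = 16.2e6, end = 16.8e6),
    sv = svSimParams(),
    coverage = list(binSize = 1e4, meanDepthPerBin = 100, dispersion = 0.02),
    expression = list(nGenes = 2000L,
                      programSizes = c(immune = 300L, pigmentation = 300L),
                      log2Effect = 2, baselineMean = 50, dispersion = 0.3))
}

#' Simulate a full synthetic cohort
#'
#' Generates, for every sample, an SV call set, planted copy-number
#' segments and tumor/normal binned coverage, plus one cohort-wide
#' expression matrix and the complete ground truth. Expression group 1 maps
#' to low SV and group 2 to high SV; `concordance < 1` flips the SV label
#' of the trailing fraction of each group. The first high-SV sample carries
#' the focal amplification with zero flanks, so the planted region is
#' exactly the cohort's maximal-recurrence interval.
#'
#' @param config configuration list (see [cohortConfig()]); partial lists
#'   are completed with defaults.
#' @param seed integer seed; all per-sample streams derive from it.
#' @return list with `genome`, `samples` (per sample: `svs`,
#'   `plantedSegments`, `coverage`), `counts`, `truth`, `config`, `seed`.
#' @export
simulateCohort <- function(config = cohortConfig(), seed = 1L) {
  cfg <- utils::modifyList(cohortConfig(), config)
  n <- cfg$nSamples
  n1 <- cfg$nGroup1
  stopifnot(n1 >= 1L, n1 < n)
  genome <- makeGenome(cfg$genomeLengths)
  group <- c(rep(1L, n1), rep(2L, n - n1))
  svLabel <- ifelse(group == 1L, "low", "high")
  nFlip <- round((1 - cfg$concordance) * n)
  if (nFlip > 0) {
    flip1 <- utils::tail(which(group == 1L), ceiling(nFlip / 2))
    flip2 <- utils::tail(which(group == 2L), floor(nFlip / 2))
    svLabel[c(flip1, flip2)] <- ifelse(
      svLabel[c(flip1, flip2)] == "low", "high", "low")
  }
  ids <- sprintf("S%02d", seq_len(n))
  firstHigh <- which(svLabel == "high")[1L]
  samples <- vector("list", n)
  names(samples) <- ids
  for (i in seq_len(n)) {
    sv <- simulateSvSample(genome, svLabel[i], cfg$sv,
                           seed = .substream(seed, i, 1L),
                           sampleId = ids[i], ampRegion = cfg$ampRegion,
                           ampFlankZero = identical(i, firstHigh),
                           align = cfg$coverage$binSize)
    cov <- simulateCoverage(sv$plantedSegments, genome,
                            binSize = cfg$coverage$binSize,
                            meanDepthPerBin = cfg$coverage$meanDepthPerBin,
                            dispersion = cfg$coverage$dispersion,
                            seed = .substream(seed, i, 2L),
                            sampleId = ids[i])
    samples[[i]] <- list(svs = sv$svs,
                         plantedSegments = sv$plantedSegments,
                         ctChrom = sv$truth$ctChrom,
                         coverage = cov)
  }
  expr <- simulateExpression(
    nGenes = cfg$expression$nGenes, sampleLabels = group,
    programSizes = cfg$expression$programSizes,
    log2Effect = cfg$expression$log2Effect,
    baselineMean = cfg$expression$baselineMean,
    dispersion = cfg$expression$dispersion,
    seed = .substream(seed, n + 1L, 3L))
  colnames(expr$counts) <- ids
  truth <- list(
    sampleIds = ids,
    svLabelTruth = stats::setNames(svLabel, ids),
    exprGroupTruth = stats::setNames(group, ids),
    chromothripsisChroms = lapply(samples, function(s) s$ctChrom),
    plantedSegments = lapply(samples, function(s) s$plantedSegments),
    plantedRegion = cfg$ampRegion,
    immuneGenes = expr$truth$immuneGenes,
    pigmentationGenes = expr$truth$pigmentationGenes,
    seed = as.integer(seed))
  list(genome = genome, samples = samples, counts = expr$counts,
       truth = truth, config = cfg, seed = as.integer(seed))
}

#' Write a simulated cohort to disk
#'
#' Emits the on-disk forms of every input: `genome.tsv`, per-sample
#' coverage BED-like TSVs under `coverage/`, Delly-dialect VCFs under
#' `svs/`, the count matrix `counts.tsv` and the ground truth
#' `truth.json`. Output is byte-deterministic for a fixed cohort.
#'
#' @param sim output of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(sim, dir) {
  dir.create(file.path(dir, "coverage"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "svs"), showWarnings = FALSE)
  writeGenomeTable(sim$genome, file.path(dir, "genome.tsv"))
  for (id in names(sim$samples)) {
    s <- sim$samples[[id]]
    writeBinnedCoverage(s$coverage$tumor,
                        file.path(dir, "coverage",
                                  paste0(id, "_tumor.tsv")))
    writeBinnedCoverage(s$coverage$normal,
                        file.path(dir, "coverage",
                                  paste0(id, "_normal.tsv")))
    writeSvVcf(s$svs, sim$genome, file.path(dir, "svs", paste0(id, ".vcf")))
  }
  writeCountsTsv(sim$counts, file.path(dir, "counts.tsv"))
  jsonlite::write_json(
    list(schemaVersion = "1.0", truth = sim$truth, seed = sim$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
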