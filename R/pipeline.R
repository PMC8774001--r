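#' Pipeline configuration
#'
#' Builds the full nested parameter list driving [runPipeline()], merging
#' user overrides into the documented defaults. Unknown keys are rejected.
#' The configuration round-trips through YAML via [readPipelineConfig()]
#' and [writePipelineConfig()].
#'
#' @param ... named overrides of the default entries (nested lists are
#'   merged recursively).
#' @return nested configuration list.
#' @export
pipelineConfig <- function(...) {
  defaults <- list(
    seed = 1L,
    cohort = cohortConfig(),
    segmentation = list(alpha = 1e-4, minBins = 3L, nPermutations = 1000L),
    svBurden = list(oscillationMin = 10L, ampPercentile = 90),
    chromothripsis = list(enrichAlpha = 1e-3, clusterAlpha = 0.05,
                          nSim = 2000L),
    recurrent = list(minStateAboveBaseline = 2L),
    expression = list(nMadGenes = 6000L, kRange = c(2L, 6L),
                      nRuns = 30L, maxIter = 500L, tol = 1e-5),
    cytokines = defaultCytokineLists())
  over <- list(...)
  .checkKeys <- function(over, def, path = "") {
    bad <- setdiff(names(over), names(def))
    if (length(bad)) {
      stop("unknown config key(s): ",
           paste0(path, bad, collapse = ", "))
    }
    for (nm in names(over)) {
      if (is.list(over[[nm]]) && is.list(def[[nm]])) {
        .checkKeys(over[[nm]], def[[nm]], paste0(path, nm, "$"))
      }
    }
  }
  .checkKeys(over, defaults)
  utils::modifyList(defaults, over)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return `readPipelineConfig` returns the validated configuration list;
#'   `writePipelineConfig` returns `path` invisibly.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  ## yaml turns named numeric vectors into lists; restore the two of them
  for (nm in c("genomeLengths")) {
    if (!is.null(raw$cohort[[nm]])) {
      raw$cohort[[nm]] <- unlist(raw$cohort[[nm]])
    }
  }
  if (!is.null(raw$cohort$expression$programSizes)) {
    raw$cohort$expression$programSizes <-
      unlist(raw$cohort$expression$programSizes)
  }
  if (!is.null(raw$expression$kRange)) {
    raw$expression$kRange <- as.integer(unlist(raw$expression$kRange))
  }
  do.call(pipelineConfig, raw)
}

#' @rdname readPipelineConfig
#' @param config configuration list from [pipelineConfig()].
#' @export
writePipelineConfig <- function(config, path) {
  ## yaml drops the names of named atomic vectors; store them as maps
  if (!is.null(config$cohort$genomeLengths)) {
    config$cohort$genomeLengths <- as.list(config$cohort$genomeLengths)
  }
  if (!is.null(config$cohort$expression$programSizes)) {
    config$cohort$expression$programSizes <-
      as.list(config$cohort$expression$programSizes)
  }
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full cohort analysis pipeline
#'
#' Executes every stage in dependency order on a seeded synthetic cohort
#' (or on one previously written to disk): coverage normalization against
#' the matched normal, segmentation and state calling, SV-burden
#' classification and chromothripsis candidate detection, cohort
#' recurrent-amplification mapping, expression normalization, consensus-NMF
#' subgrouping with signature extraction, cytokine-ratio scoring and the
#' Fisher exact cluster-vs-SV association. All applied thresholds are
#' logged, and every output is written deterministically, so a rerun on the
#' same configuration and seed reproduces the report byte for byte.
#'
#' @param config configuration from [pipelineConfig()].
#' @param outDir output directory; created if needed.
#' @param cohortDir optional directory of a cohort written by
#'   [writeCohort()]; when `NULL` the cohort is simulated from
#'   `config$cohort` with `config$seed`.
#' @return invisibly, the report list (also written as
#'   `report.json` under `outDir` together with all stage tables).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir,
                        cohortDir = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  if (is.null(cohortDir)) {
    .mmLog("run: simulating cohort (seed %d)", seed)
    sim <- simulateCohort(config$cohort, seed = seed)
  } else {
    sim <- .readCohort(cohortDir)
  }
  genome <- sim$genome
  ids <- names(sim$samples)

  ## per-sample copy-number profiles and SV statistics
  segCfg <- config$segmentation
  .mmLog("segmentation: alpha=%g, minBins=%d, nPermutations=%d",
         segCfg$alpha, segCfg$minBins, segCfg$nPermutations)
  profiles <- list()
  burden <- list()
  candidates <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    s <- sim$samples[[id]]
    ratios <- normalizeLog2Ratio(s$coverage$tumor, s$coverage$normal)
    prof <- segmentProfile(ratios, alpha = segCfg$alpha,
                           minBins = segCfg$minBins,
                           nPermutations = segCfg$nPermutations,
                           seed = .substream(seed, i, 10L), sampleId = id)
    prof <- callStates(prof)
    profiles[[id]] <- prof
    burden[[id]] <- classifySvBurden(
      prof, oscillationMin = config$svBurden$oscillationMin,
      ampPercentile = config$svBurden$ampPercentile)
    candidates[[id]] <- chromothripsisCandidates(
      prof, s$svs, genome,
      enrichAlpha = config$chromothripsis$enrichAlpha,
      clusterAlpha = config$chromothripsis$clusterAlpha,
      oscillationMin = config$svBurden$oscillationMin,
      nSim = config$chromothripsis$nSim,
      seed = .substream(seed, i, 11L))
  }
  writeSegmentsTsv(profiles, file.path(outDir, "segments.tsv"))
  writeBurdenTsv(burden, file.path(outDir, "sv_burden.tsv"))
  candTab <- do.call(rbind, Map(function(id, tab) {
    if (nrow(tab)) cbind(sample = id, tab) else NULL
  }, ids, candidates))
  utils::write.table(candTab, file.path(outDir, "chromothripsis.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## cohort recurrent amplification
  minState <- 2 + config$recurrent$minStateAboveBaseline
  .mmLog("recurrent regions: minState=%d", minState)
  ampSets <- lapply(profiles, amplifiedIntervals, minState = minState)
  ampChroms <- unique(unlist(lapply(ampSets, function(gr) {
    as.character(seqnames(gr))
  })))
  region <- NULL
  regionMap <- NULL
  for (ch in intersect(chromNames(genome), ampChroms)) {
    m <- recurrenceMap(ampSets, ch, nSamples = length(ids))
    r <- minimalRecurrentRegion(m)
    if (is.null(region) || r$sampleCount > region$sampleCount ||
        (r$sampleCount == region$sampleCount &&
         (r$end - r$start) < (region$end - region$start))) {
      region <- r
      regionMap <- m
    }
  }
  if (!is.null(region)) {
    contrib <- ids[vapply(ampSets, function(gr) {
      any(as.character(seqnames(gr)) == region$chrom &
            start(gr) - 1 < region$end & end(gr) > region$start)
    }, logical(1))]
    writeRecurrentRegion(regionMap, region,
                         file.path(outDir, "recurrent_regions.bed"),
                         file.path(outDir, "recurrent_region.json"),
                         contributingSamples = contrib)
  }

  ## expression subgrouping
  exCfg <- config$expression
  factors <- sizeFactorsForCounts(sim$counts)
  normalized <- varianceStabilize(sim$counts, factors)
  nSel <- min(exCfg$nMadGenes, nrow(normalized))
  genesSel <- selectVariableGenes(normalized, nSel)
  kRange <- seq(exCfg$kRange[1L], exCfg$kRange[2L])
  .mmLog("expression: %d MAD genes, k in [%d,%d], %d runs",
         nSel, min(kRange), max(kRange), exCfg$nRuns)
  cons <- consensusCluster(normalized[genesSel, , drop = FALSE],
                           kRange = kRange, nRuns = exCfg$nRuns,
                           seed = .substream(seed, 0L, 20L),
                           maxIter = exCfg$maxIter, tol = exCfg$tol)
  labTab <- data.frame(sample = names(sampleLabels(cons)),
                       cluster = unname(sampleLabels(cons)))
  utils::write.table(labTab, file.path(outDir, "expression_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  silTab <- data.frame(k = names(silhouetteByK(cons)),
                       meanSilhouette = sprintf("%.6f",
                                                silhouetteByK(cons)))
  utils::write.table(silTab, file.path(outDir, "silhouette_by_k.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- signatures(cons)
  sig$score <- sprintf("%.6f", sig$score)
  utils::write.table(sig, file.path(outDir, "signatures.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  C <- consensusMatrix(cons)
  utils::write.table(
    data.frame(sample = rownames(C), round(C, 6), check.names = FALSE),
    file.path(outDir, "consensus_chosen_k.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  ## association scoring
  ratios <- suppressWarnings(
    cytokineRatio(normalized, config$cytokines$pro,
                  config$cytokines$immuno))
  clusterLab <- sampleLabels(cons)[ids]
  svLab <- vapply(burden, burdenLabel, character(1))[ids]
  ratioTest <- groupRatioTest(ratios[ids], clusterLab)
  assoc <- fisherAssociation(clusterLab, svLab)
  utils::write.table(
    data.frame(sample = ids, ratio = sprintf("%.6f", ratios[ids]),
               cluster = unname(clusterLab), svLabel = unname(svLab)),
    file.path(outDir, "cytokine_ratios.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  report <- list(
    schemaVersion = "1.0",
    seed = seed,
    nSamples = length(ids),
    chosenK = chosenK(cons),
    clusterSizes = as.list(table(clusterLab)),
    svLabelCounts = as.list(table(svLab)),
    associationTable = lapply(seq_len(nrow(assoc$table)),
                              function(i) as.list(assoc$table[i, ])),
    fisherP = assoc$pValue,
    oddsRatio = assoc$oddsRatio,
    cytokineRatioT = ratioTest$tStatistic,
    cytokineRatioP = ratioTest$pValue,
    recurrentRegion = region,
    nSignatureGenes = nrow(signatures(cons)))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

## Read back a cohort written by writeCohort().
.readCohort <- function(dir) {
  for (f in c("genome.tsv", "counts.tsv", "truth.json")) {
    if (!file.exists(file.path(dir, f))) {
      stop("missing cohort input: ", file.path(dir, f))
    }
  }
  genome <- readGenomeTable(file.path(dir, "genome.tsv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  covFiles <- list.files(file.path(dir, "coverage"),
                         pattern = "_tumor\\.tsv$")
  ids <- sort(sub("_tumor\\.tsv$", "", covFiles))
  samples <- lapply(ids, function(id) {
    list(
      svs = readSvVcf(file.path(dir, "svs", paste0(id, ".vcf")),
                      sampleId = id),
      coverage = list(
        tumor = readBinnedCoverage(
          file.path(dir, "coverage", paste0(id, "_tumor.tsv")),
          sampleId = paste0(id, "_tumor"), genome = genome),
        normal = readBinnedCoverage(
          file.path(dir, "coverage", paste0(id, "_normal.tsv")),
          sampleId = paste0(id, "_normal"), genome = genome)))
  })
  names(samples) <- ids
  counts <- readCountsTsv(file.path(dir, "counts.tsv"))
  if (is.null(counts) || !ncol(counts)) {
    stop("missing or empty counts matrix under ", dir)
  }
  list(genome = genome, samples = samples, counts = counts,
       truth = truth$truth, seed = truth$seed)
}
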