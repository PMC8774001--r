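# mmscape

Integrative structural-variant (SV) and expression landscape analysis for
mucosal melanoma cohorts.

Mucosal melanoma carries few point mutations but a heavy burden of
structural variants and copy-number alterations, and cohorts tend to split
into two molecular subgroups: an immune-infiltrated, SV-poor group and a
pigmentation/oncogene-driven, SV-rich group marked by chromothripsis-like
rearrangements and recurrent focal amplifications. `mmscape` implements
the computational backbone of that analysis for anyone working with binned
coverage, Delly-style SV calls and RNA-seq counts from such cohorts
(canine or human):

* **Copy-number profiles** — per-bin log2 tumor/normal ratios
  (`normalizeLog2Ratio`, `poolReferences`), permutation-tested recursive
  segmentation in the circular-binary-segmentation family
  (`segmentProfile`) and integer state calling
  `state = round(2 * 2^lr)` (`callStates`).
* **SV landscape** — Delly-dialect VCF ingestion with PASS/PRECISE
  filtering (`readSvVcf`), breakpoint accounting (`breakpointsOf`),
  hypergeometric breakpoint enrichment
  `p = C(m,x) C(N-m,k-x) / C(N,k)` over base-pair populations
  (`breakpointEnrichment`), a Monte-Carlo spacing test for breakpoint
  clustering (`breakpointClusteringTest`), copy-number oscillation
  counting and the high/low SV-burden rule — at least 10 state
  transitions on one chromosome plus one amplification reaching the 90th
  percentile of the sample's gains (`classifySvBurden`,
  `chromothripsisCandidates`).
* **Recurrent amplifications** — cohort sweep-line recurrence maps and
  the minimal recurrently amplified region with its frequency
  (`amplifiedIntervals`, `recurrenceMap`, `minimalRecurrentRegion`).
* **Expression subgroups** — median-of-ratios size factors, shifted-log
  normalization, top-MAD gene selection, consensus NMF (KL multiplicative
  updates) over ranks 2–6 with silhouette-based rank choice, and
  Kim–Park signature extraction (`consensusCluster`,
  `extractSignatures`).
* **Microenvironment association** — the pro-/anti-inflammatory cytokine
  expression ratio with Student's t-test, exact two-sided Fisher
  association between expression clusters and SV-burden labels, and
  simple marker-gene contrasts (`cytokineRatio`, `fisherAssociation`,
  `markerGeneCompare`).
* **A seeded synthetic-cohort generator** (`simulateCohort`,
  `writeCohort`) that emulates every input — NB coverage over planted
  segments, clustered-breakpoint/oscillating chromothripsis chromosomes,
  two-program expression — with full ground truth, so the entire pipeline
  is testable without sequencing data.

See `vignettes/mmscape-methods.Rmd` for the models, defaults and design
decisions.

## Worked example

```r
library(mmscape)
options(mmscape.quiet = TRUE)

cfg <- pipelineConfig(
  seed = 42L,
  segmentation = list(nPermutations = 200L),
  expression = list(nMadGenes = 600L, kRange = c(2L, 4L), nRuns = 12L,
                    maxIter = 200L, tol = 1e-4))
report <- runPipeline(cfg, outDir = "mm_run")

report$chosenK
#> [1] 2
unlist(report$clusterSizes)
#>  1  2
#> 12 20
report$fisherP
#> [1] 4.428838e-09
report$cytokineRatioT
#> [1] 13.95325
str(report$recurrentRegion)
#> List of 5
#>  $ chrom      : chr "chr1"
#>  $ start      : num 16200000
#>  $ end        : int 16800000
#>  $ sampleCount: int 20
#>  $ frequency  : num 0.625
```

Reading the numbers: the default synthetic cohort plants 32 samples, 12
with an immune expression program and low SV burden and 20 with a
pigmentation/oncogene program and high SV burden. Consensus NMF picks
`k = 2` and recovers the 12/20 split; with fully concordant planted
labels the cluster-versus-SV Fisher test is extreme (p ≈ 4.4e-9), the
cytokine ratio is strongly higher in the immune cluster (t ≈ 14), and the
minimal recurrently amplified region is exactly the planted
chr1:16.2–16.8 Mb interval, amplified in the 20 high-SV samples (0.625 of
the cohort). `mm_run/` additionally holds the per-stage tables (segments,
burden labels with evidence, chromothripsis candidates, consensus
matrices, signatures, cytokine ratios) and `report.json`; rerunning with
the same config and seed reproduces every file byte for byte.

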