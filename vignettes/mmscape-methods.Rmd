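---
title: "Models and methods behind mmscape"
author: "mmscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mmscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmscape)
options(mmscape.quiet = TRUE)
```

# Scope

Mucosal melanoma carries few point mutations but a heavy load of structural
variants (SVs) and copy-number alterations, and cohorts split into an
immune-infiltrated, SV-poor subgroup and a pigmentation/oncogene-driven,
SV-rich subgroup. `mmscape` implements the computational core of that kind
of integrative analysis as reusable, seeded, testable components:

1. copy-number profiling from binned tumor/normal coverage,
2. SV ingestion plus chromothripsis feature statistics,
3. rule-based high/low SV-burden classification,
4. cohort mapping of minimal recurrently amplified regions,
5. consensus non-negative matrix factorization (NMF) subgrouping of
   expression with signature extraction, and
6. immune-microenvironment association scoring.

A synthetic-cohort generator emulates every input, so the full pipeline is
exercised end to end without any sequencing data.

# Copy-number profiling

Coverage is summarised in fixed genomic bins (10 kb by default). For bin
$b$ with tumor count $t_b$ (total $T$) and reference count $r_b$ (total
$R$, a matched normal or a pool of normals), the profile is

$$\mathrm{lr}_b = \log_2 \frac{t_b / T}{r_b / R}.$$

Bins with a zero tumor or reference count are masked rather than
zero-filled: they contribute to no statistic but do not interrupt
segments. No GC or mappability correction is applied (synthetic inputs
have none; real low-pass data would want one upstream).

Note one consequence of total-count normalization that users of the
synthetic generator will see: a large focal amplification inflates $T$,
shifting all other bins' log ratios slightly negative. States are still
recovered correctly at the default generator settings because the shift is
far below half a copy.

**Segmentation** is recursive binary splitting in the circular-binary-
segmentation family: within an interval, every candidate changepoint is
scored by the pooled-variance two-sample t statistic between its flanks,
and the best split (leftmost on ties) is accepted when its permutation
p-value falls below `alpha` (default $10^{-4}$, with `minBins = 3` bins
minimum per flank and 1000 permutations by default). Accepted splits
recurse into both flanks; merging is implicit because an interval with no
accepted split stays one segment.

A single changepoint statistic is structurally blind to one configuration:
a short segment whose two flanks share a mean (an isolated bump), because
no single split then separates different means. This is precisely why the
classical method in this family is *circular*. When the single-split test
fails on an interval, a second stage therefore tests the best
two-changepoint (inside-versus-outside) t statistic over candidate inner
segments of at most `bumpMax` bins (default 50), against its own
permutation null; an accepted bump contributes both cuts and recursion
continues. Wider equal-flank segments are already caught by the
single-split stage. Two numerical choices matter:

* The permutation p-value is $\#\{\text{perm} \ge \text{obs}\}/n_{perm}$
  with a deterministic generator seeded per tested interval (a hash of the
  global seed, chromosome and interval bounds). Because the decision for a
  given interval never depends on the recursion path, lowering `alpha` can
  only remove splits — the monotonicity the test suite asserts. Scanning
  stops early once the exceedance count reaches
  $\alpha \cdot n_{perm}$; the decision is identical to the full scan. The
  permutation scan is compiled code with its own portable generator, so
  results do not depend on R's RNG state.
* Integer states come from
  $\mathrm{state} = \max(0, \mathrm{round}(\rho \cdot 2^{\mathrm{lr}}))$
  with baseline ploidy $\rho = 2$, so a log ratio of about 5.06 maps to a
  67-copy focal amplification — the magnitude seen in heavily amplified
  melanoma cell lines.

# SV landscape and chromothripsis features

SV call sets enter as Delly-dialect VCF 4.2 (`SVTYPE`, `CHR2`/`END`, `PE`,
`SR`, `PRECISE`/`IMPRECISE`, `MATEID`); only records flagged both `PASS`
and `PRECISE` are used, and all statistics are defined on the retained
records. Breakpoint multiplicity: DEL/DUP/INV contribute both ends, INS
its insertion site, and a BND junction one breakpoint per side (mate lines
are recognized by `MATEID` so a side is never counted twice).

**Breakpoint enrichment.** The number of breakpoints $x$ on a chromosome
of size $m$ bp, out of $k$ genome-wide breakpoints in a genome of $N$ bp,
is scored by the hypergeometric point-mass probability

$$p = \frac{\binom{m}{x}\binom{N-m}{k-x}}{\binom{N}{k}},$$

evaluated with log-gamma binomials (relative error far below $10^{-10}$;
the test suite compares against exact binomial-coefficient arithmetic on
small populations). Significance is $p < 10^{-3}$. The point mass — not a
tail sum — is deliberate: it is the form the burden analysis defines, and
an upper-tail variant is available behind the `tail` flag for users who
prefer a conventional tail test. Note the point mass is small for any
atypical $x$, including depletion; the candidate caller therefore never
uses enrichment alone.

**Breakpoint clustering.** Clustering on a chromosome of length $L$ is
tested by Monte Carlo against $n$ points placed uniformly. The statistic
is the negative log-likelihood of the $n + 1$ spacings $g_i$ (terminal
gaps included) under the uniform (Dirichlet) spacing law,
$-\sum_i \log(g_i/L)$. By the AM–GM inequality this is minimal for
perfectly regular spacings and grows without bound as points coalesce, so
it orders inputs regular < uniform < clustered — exactly the one-sided
behaviour wanted: evenly spread breakpoints can never look "clustered". A
one-sided Kolmogorov–Smirnov alternative on the spacing distribution is
available behind `method = "ks"`, but any KS distance also flags regular
spacings as non-uniform, which is the wrong direction for this question;
that is why the spacing log-likelihood is the default. The p-value is the
add-one Monte-Carlo estimate, and fewer than three breakpoints yields a
"not evaluable" result, deliberately distinct from $p = 1$.

**SV-burden rule.** A sample is "high" when some chromosome shows at least
10 copy-number state transitions and the maximum state reaches the 90th
percentile (linear interpolation) of the sample's gained-segment states;
otherwise "low". Two readings of "at least 10 oscillating states" exist —
10 transitions or 10 distinct values; the transition reading is used
(oscillation implies alternation) and both counts are reported in the
evidence block, which is kept human-readable to support manual curation.
The percentile is per sample over gained segments; a sample with no gain
cannot be "high" (an explicit sentinel, not a silent 0). The per-segment
(unweighted) percentile follows the worked definition of the rule; note it
is not invariant to subdividing segments, whereas the label in practice
is, and the classification invariance test asserts exactly that.

**Chromothripsis candidates** are chromosomes satisfying all three
criteria at once: enrichment $p < 10^{-3}$, clustering $p < 0.05$, and
$\ge 10$ state transitions.

# Recurrently amplified regions

Per sample, amplified intervals are maximal runs of segments with state
$\ge$ baseline + 2 (i.e. $\ge 4$ copies on a diploid genome — above
single-copy gain; the threshold is a parameter since published analyses
rarely print theirs). Across the cohort, interval endpoints induce atomic
intervals, each annotated with the number of covering samples (computed as
base-pair coverage, equivalent to a sweep-line and verified against a
per-base brute force). The minimal recurrent region is the contiguous
union of atomic intervals at the maximal count; disjoint ties resolve to
the smallest span, then leftmost. Frequency is maximal count over cohort
size.

# Expression subgrouping by consensus NMF

Counts are normalized by median-of-ratios size factors and transformed as
$\log_2(\mathrm{count}/\mathrm{factor} + 1)$. This shifted log is a stated
stand-in for a variance-stabilizing transform: it preserves the relative
structure the clustering operates on while keeping the matrix
non-negative, which NMF requires. The 6000 most variable genes by raw
median absolute deviation (no 1.4826 constant — ranking is scale
invariant) are kept, with ties broken by total expression then gene
identifier so selection is deterministic.

Factorization minimizes the generalized Kullback–Leibler divergence
$D(V\,\|\,WH)$ with the classical multiplicative updates from seeded
uniform initializations; the objective is recorded every iteration and is
non-increasing by construction (asserted to $10^{-10}$ slack in tests). A
Frobenius variant sits behind a flag. For each rank $k \in 2..6$, 30 runs
assign each sample to its largest coefficient; the consensus matrix holds
pairwise co-assignment fractions. Final labels cut an average-linkage
dendrogram of $1 - \mathrm{consensus}$; rank quality is the mean
silhouette width on that same distance, and the chosen rank maximizes it
(ties to the smaller rank; ranks whose every run leaves an empty cluster
are excluded). The run count, seeding scheme, linkage and silhouette
distance are declared defaults — the upstream literature names the
consensus-silhouette method without pinning these details.

Signatures come from the factorization whose partition agrees best (Rand
index) with the consensus partition — making them deterministic given
seeds — scored per gene by the Kim–Park basis-specificity score

$$s(g) = 1 + \frac{1}{\log_2 k}\sum_i p_{gi}\log_2 p_{gi},
\qquad p_{gi} = W_{gi}/\textstyle\sum_i W_{gi},$$

which is exactly 1 for a one-basis gene and 0 for a uniform gene. Genes
with $s > \mathrm{median}(s) + 3\,\mathrm{MAD}(s)$ are assigned to their
largest-loading basis. When nearly all scored genes are perfectly
basis-specific (degenerate toy data) the threshold can select none; with
a realistic background gene majority it behaves as intended.

# Association scoring

The **cytokine ratio** per sample is the summed normalized expression of
pro-inflammatory cytokines (IFNG, IL1A, IL1B, IL2) over immunosuppressive
molecules (IL10, IL11, IL4, TGFB1) — sum rather than mean is a
convention; the two differ by a constant and a mean option exists. IL4's
membership of the immunosuppressive list is reported inconsistently in
the source literature; the lists are plain configuration. Group
comparison uses the two-sided pooled-variance Student's t-test; genes
missing from the matrix are dropped with a warning and zero-denominator
samples are excluded as flagged `NA`s.

The **cluster–SV association** is the two-sided Fisher exact test computed
by point-probability summation over fixed-margin tables (tie tolerance
$10^{-12}$), cross-checked in the test suite against full enumeration and
against `stats::fisher.test`. The odds ratio uses a 0.5 continuity
correction only when a zero cell is present, and says so.

**Marker contrasts** (`markerGeneCompare`) are a deliberately simple
stand-in for shrinkage-based differential expression: log2 fold change of
group means on the linear normalized scale with a one-count pseudo-value,
Welch t-test on the log scale, Benjamini–Hochberg correction across the
queried genes. Their fold changes are not expected to match moderated
estimators on real data; in this package they order and orient planted
effects, which is what the tests assert.

# The synthetic cohort: what it emulates and what it does not

The generator plants exactly the features the analysis assumes, under one
global seed with per-sample, per-stage substreams (so adding a sample
never changes another sample's draws; `dispersion = 0` switches both
count models to their deterministic point-mass limit, which makes limit
behaviour exactly testable):

* **Design.** 32 samples, 12 in expression group 1 (immune program up,
  low SV) and 20 in group 2 (pigmentation/oncogene program up, high SV),
  mirroring the subgroup proportions the analysis targets; label
  concordance is configurable and defaults to full.
* **Genome.** A four-chromosome, 100 Mb build with the recurrent focal
  amplification planted at chr1:16.2–16.8 Mb — a deliberately scaled-down
  stand-in for a 2.4 Gb genome chosen so the whole pipeline runs in
  minutes on one CPU; all statistics are size-aware, nothing assumes this
  scale.
* **Coverage.** Negative-binomial bin counts, 10 kb bins, mean 100 reads
  per bin, dispersion 0.02 — WES-grade profile quality, matching the data
  class burden classification is defined on (low-pass depth would need
  longer oscillation segments to keep the same power; the "low SV"
  background rates are not quantified anywhere, so these defaults are
  chosen for test power, not biological fidelity).
* **High-SV samples.** One designated chromosome receives clustered
  breakpoints in a window of at most 25% of the chromosome (extent chosen
  so the clustering test has power at default sizes), alternating
  1-vs-3-copy states producing $\ge 2\times$`oscillationCycles`
  transitions, and one focal segment at `ampCopyNumber` (default 40)
  covering the planted region plus random bin-aligned flanks; the first
  high sample gets zero flanks so the planted region is exactly the
  cohort's maximal-recurrence intersection. Low-SV samples get sparse
  uniform background SVs and near-diploid genomes (states 1–3).
* **Expression.** Negative-binomial counts around lognormal baselines
  with two planted 300-gene programs at $2^{2}$-fold effect; the named
  cytokine/checkpoint markers head the immune program and the
  immunosuppressive/pigmentation markers (including MITF, TERT, KIT,
  POM121) head the pigmentation program, so name-driven scoring works.
* **Deliberate decoys.** Every call set carries a couple of
  non-PASS/imprecise records so the filtering path is always exercised.

What it does **not** emulate: read-level data, GC/mappability bias,
subclonality and purity, allele-specific copy number, genuinely complex
rearrangement topologies, or survival. Tests passing on this cohort
demonstrate that the statistics recover what they are defined to recover
at realistic noise — not that the pipeline is robust to every artefact of
FFPE low-pass sequencing.

# Degenerate inputs and tie-breaking, collected

* Best split ties → leftmost candidate; constant intervals → no split.
* All-masked chromosome → no segments, with a warning.
* Empty VCF body → empty call set; missing `SVTYPE` → record skipped with
  a warning.
* `< 3` breakpoints → clustering "not evaluable", never $p = 1$.
* No gained segment → amplification sentinel; sample cannot be "high".
* Ranks where every NMF run leaves an empty cluster are invalid and never
  chosen; silhouette ties prefer the smaller rank.
* Gene-selection ties → total expression, then lexicographic gene id.
* Disjoint recurrence maxima → smallest span, then leftmost.

# Problem sizes used by the shipped checks

The test-suite and acceptance-script runs use the generator defaults above
with desk-scale analysis settings: 200 segmentation permutations (the
planted jumps are far above the null either way), 10 NMF runs over ranks
2–6 on the top 600 MAD genes, 1000 clustering simulations, and 2–20
seeded replicates per property. These are the package's declared
evaluation conditions; every threshold the pipeline applies is logged at
run time.

# Known limitations

* The two-changepoint rescue stage only searches bumps up to `bumpMax`
  bins; an equal-flank segment wider than that but still too small for
  the single-split statistic can be missed. The alpha-monotonicity
  guarantee is exact for the single-stage procedure and holds empirically
  for the two-stage one.
* The hypergeometric population is base pairs, treating breakpoints as
  independent single-base draws; fragment-size effects are ignored.
* Consensus NMF is stochastic; rank choice is only as stable as the run
  count, and 30 runs is a declared default, not an inferred one.
* The VST stand-in is not DESeq2's variance-stabilizing transform;
  absolute expression contrasts should not be compared against
  shrinkage-based published values.
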