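---
title: "Comparing drug-response signatures within and across molecular modalities"
author: "SigConcord maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing drug-response signatures within and across molecular modalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SigConcord)
```

## The problem

Rapid-acting antidepressants such as ketamine, its metabolite
(2R,6R)-hydroxynorketamine (HNK), and serotonergic psychedelics produce
transcriptomic responses in human iPSC-derived neurons that are strongly
time-dependent: different agents look alike at the same timepoint, while the
same agent's profile can reverse between an early (6 h) and a late (24 h)
snapshot. A complementary question is whether those in vitro signatures
resemble what happens in living humans — for example, whether a neuronal
gene signature for HNK tracks serial cerebrospinal-fluid (CSF) proteomic
changes after a ketamine infusion.

SigConcord implements the statistics that make those comparisons
quantitative and testable:

* **signature calling** from per-analyte differential statistics with
  strict p and |log2FC| cutoffs;
* **overlap enrichment** of two signatures over an explicit background
  universe (exact hypergeometric tail, permutation test, odds ratio,
  Jaccard);
* **directional concordance**: do overlapping analytes move in the same
  direction more often than a background-derived null predicts?
* **rank-correlation profiles** of signed log2 fold changes across
  conditions and timepoints, with Benjamini–Hochberg control;
* a **cross-modal universe** construction for gene-vs-protein comparisons,
  and a **temporal concordance profile** of one fixed transcriptomic
  signature against serial proteomic tables;
* **MAD-based QC filtering** of per-cell metrics for the single-cell arm;
* a **synthetic-data generator** that plants all of the above structure
  with known ground truth, so every stage can be validated end to end
  without access to any raw study data.

## Statistical model

### Overlap enrichment

Given signatures $A$ and $B$ inside a universe of $N$ analytes, the 2×2
table $(a, b, c, d)$ counts the overlap, the private members of each set,
and the remainder. Under the null that $A$ is an arbitrary size-$|A|$
subset of the universe, the overlap is hypergeometric, and
`hypergeometricP()` returns the exact upper tail $P(X \ge a)$.
`permutationOverlapP()` estimates the same tail by redrawing $A$ uniformly
(`nPerm` times, compiled resampling on R's RNG) and reporting
$(1 + \#\{X^\ast \ge a\})/(n_{\mathrm{perm}} + 1)$ — the +1 convention
avoids reporting zero. Resampling only the smaller set, holding the other
fixed, is equivalent in distribution to resampling both and is cheaper.
One-sided enrichment tails are the default throughout; depletion is a
flag. The odds ratio uses the Haldane–Anscombe +0.5 correction on all four
cells whenever any cell is zero; the Jaccard index $a/(a+b+c)$ is defined
as 0 for an empty union. Because "percent overlap" has two natural
denominators, `percentOverlap()` reports both (of the union, and of the
smaller set).

A worked example at the sizes that motivate the package — a universe of
1235 gene↔protein analytes, 72 differential genes, 364 differential
proteins, 28 shared:

```{r overlap-example}
universe <- sprintf("A%04d", 1:1235)
A <- universe[1:72]
B <- universe[c(1:28, 73:408)]
overlapTest(A, B, universe, nPerm = 10000, seed = 1)
```

The exact tail here is 0.0496; any 10,000-draw permutation estimate of it
carries a Monte-Carlo standard error of about 0.002.

### Directional concordance

Counting overlap ignores sign. `directionalConcordance()` counts the
overlapping analytes whose fold-change directions agree and compares the
count against $\mathrm{Binomial}(n_{\mathrm{overlap}}, p_0)$ with an exact
upper tail. The null agreement probability
$p_0 = u_A u_B + (1-u_A)(1-u_B)$ comes from
`backgroundAgreementProb()`, where $u_X$ is the proportion of *all tested*
universe analytes (not just significant ones) with a positive log2FC —
with 60% of analytes up-regulated on both sides, $p_0 = 0.52$. Using the
full background rather than the significant subset is deliberate: the
significant subsets are exactly what is being tested, and conditioning on
them would bias the null. Analytes with zero or missing fold change are
excluded from both numerator and denominator. Degenerate nulls
($p_0 \in \{0, 1\}$) are handled by the exact tail without special cases.

### Rank correlations

`spearmanRhoP()` computes Spearman's $\rho$ from midranks (ties are
expected in rounded fold-change tables) with a two-sided p-value from the
$t$ approximation on $n-2$ degrees of freedom; for $n \le 8$ without ties
it enumerates the exact permutation distribution instead, and the method
used is recorded in the result. Constant input is a flagged result, not a
silent `NaN`. The choice of the $t$ approximation as default matches the
sample sizes these analyses see in practice (tens to thousands of shared
analytes); the recorded method makes any residual discrepancy with other
software diagnosable. `signatureCorrelationMatrix()` restricts to the
union of analytes passing a selection threshold in *any* condition before
correlating pairs — mirroring how cross-condition fold-change similarity
is normally summarized — and flags pairs with fewer than 3 shared analytes
as undefined rather than failing.

### Cross-modal temporal profiles

`buildUniverse()` intersects the tested gene space with the mappable
protein panel: a gene enters the universe iff it was tested and maps to at
least one protein actually measured. Many-to-many mappings are collapsed
when a protein table is translated to gene space (`mapProteinTable()`);
the default keeps the protein with the smallest p-value per gene, which
preserves the strongest evidence (alternatives: first pair, mean log2FC).

`temporalConcordance()` then runs, per CSF timepoint: signature calling
with deliberately *asymmetric* thresholds — FDR-corrected on the protein
side, uncorrected p on the gene side, reflecting the limited assay
coverage of protein panels relative to transcriptome-wide testing —
followed by overlap counts, the permutation enrichment p, directional
concordance, and the Spearman correlation over overlapping analytes;
correlation p-values are BH-corrected across the series. By default the
signatures are re-called *within* the cross-modal universe (including
re-computing the protein-side BH adjustment on the restricted table);
calling globally and intersecting afterwards is available
(`restrictToUniverse = FALSE`) since published analyses are often
ambiguous on this point.

### QC filtering

`madOutlierFilter()` applies median-absolute-deviation rules to per-cell
metrics: upper-only for mitochondrial percentage (only high values signal
damage), two-sided for gene and UMI counts, 3 MADs by default. The MAD is
scaled by 1.4826 (normal consistency) by default, with the raw MAD
selectable, since published filtering rules rarely state the constant.
Thresholds are computed once on all input cells jointly — no iterative
re-filtering — so results are order-independent and removing an unflagged
cell cannot change any other cell's fate. Per-sample grouping, when
wanted, is a matter of splitting the table before filtering. A metric with
MAD = 0 makes its rule a no-op, logged as degenerate rather than removing
everything or nothing silently.

## The synthetic-data generator

`simConditionTables()` and `simCrossModalPair()` generate inputs with the
statistical structure the analysis assumes, plus the ground truth needed
for recovery tests. They are stand-ins for real data, not simulators of
the measurement process: effects are Gaussian on the log2 scale and
p-values derive from z-scores of the noisy effects (so null p-values are
exactly uniform).

Key design points, fixed at design time:

* **Correlation targets refer to what the pipeline measures.** The
  generator's `withinTimeCorr` (default 0.8) and `acrossTimeCorr`
  (default −0.3) are targets for the realized *Spearman* correlation of
  *observed* log2FC. Internally the latent effect correlation is the
  target passed through the Greiner identity
  $\rho_P = 2\sin(\pi\rho_S/6)$ and divided by the attenuation
  $\sigma_e^2/(\sigma_e^2+\sigma_n^2)$; infeasible targets (a
  non-positive-definite latent matrix) error before any sampling.
* **Default effect structure** — 5% signal genes, effect SD 2, noise SD
  0.5 — yields per-condition signatures of a few hundred genes at the
  conventional cutoffs (uncorrected p < 0.01, |log2FC| > 1.5) on a 20k
  gene universe, the order of magnitude such experiments report.
* **The cross-modal pair plants called signatures directly.** Membership
  of the neuronal signature A (expected size 72) and each serial protein
  signature B_t (expected size 364) within the 1235-analyte universe is
  Bernoulli per analyte, and p-values are constructed so that calling at
  the default thresholds recovers the planted sets exactly. The planted
  enrichment ramps cubically to `concordancePeakTimepoint` (default index
  5 of 6, the 12 h draw) and decays after it; at the peak the expected
  overlap is `crossmodalEnrichment` (default 2) times the null
  expectation $|A||B|/N$. Overlapping analytes couple their |log2FC|
  magnitudes (peak coupling 0.95) and agree in direction with probability
  ramping from the background null 0.52 up to 25/28; direction-discordant
  analytes get weak magnitudes, since a strong effect reversed across
  modalities is not the planted biology. With
  `crossmodalEnrichment <= 1` every coupling is zero and the pair is an
  exact null.
* **QC metrics** are lognormal (UMI, genes; correlated) and scaled-beta
  (mitochondrial %), with planted high-mito, low-quality and oversized
  subpopulations. Inlier spread is calibrated so that with no planted
  outliers the default rules remove at most ~2% of cells, while planted
  outliers are recovered essentially completely.

What the generator does *not* emulate: count-level noise, normalization
artifacts, antibody-panel (NPX) distributions, batch structure, or real
pharmacokinetics. Passing recovery tests therefore demonstrates that the
statistics do what they claim on data with the assumed structure — not
that any particular biological dataset satisfies those assumptions.

```{r crossmodal-demo}
sim <- simCrossModalPair(syntheticSpec(nGenes = 2000L), seed = 1)
prof <- temporalConcordance(sim$neuronal, sim$csfSeries, sim$map,
                            universe = sim$universe,
                            nPerm = 2000, seed = 1)
prof
```

## Numerical and testing choices

* **Strict inequalities** at both calling cutoffs (p strictly below,
  |log2FC| strictly above); boundary records are excluded, and a zero
  fold change can never be a member. Records with missing statistics are
  dropped and tallied (`nDropped`), never silently imputed.
* **Identifier matching is exact and case-sensitive**; an uppercase
  normalization hook exists at table reading.
* **Conservative permutation p.** For a discrete overlap count the
  one-sided permutation p is super-uniform under the null — its mean
  exceeds 0.5 by half the modal tie probability, for the exact tail just
  as for any correct estimator of it. Calibration diagnostics therefore
  use the mid-p variant (`midP = TRUE`, ties count half), which is
  near-uniform, while reported p-values keep the conservative +1
  estimator. The test suite checks both: mid-p uniformity by
  Kolmogorov–Smirnov, and conservativeness of the reported estimator at
  the 0.05 level, over 500 null replicates.
* **Every stochastic result carries its `(nPerm, seed)`**, and all
  generators and pipeline runs are deterministic given a seed (seeds are
  applied locally; the caller's RNG state is restored).
* **Validation problem sizes.** The replicated statistical checks in the
  test suite run at reduced sizes chosen to keep the whole suite fast
  while leaving the statistics meaningful: gene universes of 1300–2000
  (the cross-modal universe stays at its full 1235), 500 null replicates
  at 2000 permutations, 100 recovery seeds at 500 permutations, and an
  exhaustive sweep of all small-universe ($N \le 20$) overlap
  configurations at $10^5$ permutations against the exact tail (with a
  bounded retry to absorb the expected handful of chance 3-SE
  exceedances among ~5800 simultaneous checks).

## Known limitations

* The package consumes *pre-computed* differential statistics; it does not
  fit differential-expression models, integrate single-cell data, or
  process proteomic assays.
* The exact binomial concordance tail needs the null $p_0$ as an input;
  when up/down proportions differ strongly between arbitrary analyte
  subsets, a single background-derived $p_0$ is an approximation (the
  permutation analogue over signature redraws is the natural extension).
* The directional and quantitative concordance measures treat the
  gene→protein map as fixed truth; mapping errors propagate silently.
* Percent-overlap conventions, FDR scope (within-universe vs global), and
  the selection rule for correlation matrices all change numbers; the
  package exposes each as an explicit option precisely because published
  descriptions are often ambiguous on them.
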