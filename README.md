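# SigConcord

Overlap and cross-modal concordance statistics for drug-response
signatures.

## What this is for

Studies of rapid-acting antidepressants (ketamine and its metabolite
(2R,6R)-HNK, psilocybin, LSD, DOI) in human iPSC-derived neurons produce
one differential-expression table per agent × timepoint, and sometimes a
parallel series of CSF proteomic tables from dosed human volunteers. The
recurring analytical questions are set comparisons, not model fits:

* Do two signatures share more analytes than chance, given the background
  universe both were tested on? (exact hypergeometric tail, permutation
  test, odds ratio with Haldane–Anscombe correction, Jaccard)
* Do the overlapping analytes move in the **same direction** more often
  than the background up/down proportions predict? (exact binomial tail
  against p₀ = u_A·u_B + (1−u_A)(1−u_B))
* How similar are signed log2 fold-change profiles across agents and
  timepoints? (tie-aware Spearman matrices over union-selected analytes,
  BH-corrected)
* Does a fixed neuronal gene signature align progressively with serial
  CSF protein draws, and at which timepoint does the alignment peak?
  (cross-modal universe from a gene↔protein map, per-timepoint overlap +
  permutation p + Spearman ρ with FDR across the series)
* Which cells survive MAD-based QC? (3-MAD rules, upper-only for
  mitochondrial %, two-sided for genes/UMIs)

All inputs are plain TSV differential tables (analyte, log2fc, pvalue,
optional padj); a synthetic-data generator with planted ground truth makes
the whole pipeline testable without any external data.

## Worked example

The canonical cross-modal configuration: a background universe of 1235
analytes (genes tested for differential expression that map onto a
measured CSF protein panel), a 72-gene neuronal signature, a 364-protein
CSF signature, 28 analytes in common.

```r
library(SigConcord)
universe <- sprintf("A%04d", 1:1235)
A <- universe[1:72]
B <- universe[c(1:28, 73:408)]
overlapTest(A, B, universe, nPerm = 10000, seed = 1)
#> OverlapResult: a=28 b=44 c=336 d=827 (N=1235)
#>   expected overlap 21.22 | hypergeometric p 0.0496 | OR 1.57 | Jaccard 0.0686
#>   permutation p 0.049 (nPerm=10000, seed=1)
```

Read: ~21 shared analytes were expected by chance, 28 were observed; the
exact tail probability is 0.0496 and the 10,000-draw permutation estimate
agrees to within its Monte-Carlo error (SE ≈ 0.002) — a nominally
significant enrichment, with a modest odds ratio.

An end-to-end temporal profile on synthetic data with a planted
concordance peak at the fifth of six CSF timepoints:

```r
sim  <- simCrossModalPair(syntheticSpec(nGenes = 2000L), seed = 1)
temporalConcordance(sim$neuronal, sim$csfSeries, sim$map,
                    universe = sim$universe, nPerm = 2000, seed = 1)
#> TemporalProfile over 6 timepoints (universe 1235, nPerm 2000)
#>  hours nGeneSig nProteinSig overlap expected overlapP kAgree    p0   pBinom
#>      1       86         361      25     25.1   0.5720     19 0.516 1.12e-02
#>      2       86         355      20     24.7   0.9050     15 0.518 2.99e-02
#>      4       86         368      25     25.6   0.5970     15 0.516 2.63e-01
#>      8       86         353      36     24.6   0.0030     24 0.513 4.56e-02
#>     12       86         372      52     25.9   0.0005     48 0.518 3.08e-10
#>     24       86         369      36     25.7   0.0135     24 0.515 4.80e-02
#>    rho        p        q
#>  0.543 5.03e-03 7.54e-03
#>  0.564 9.61e-03 1.15e-02
#>  0.192 3.59e-01 3.59e-01
#>  0.624 4.83e-05 1.45e-04
#>  0.974 4.94e-34 2.97e-33
#>  0.493 2.26e-03 4.51e-03
```

The planted peak (12 h) shows the maximal overlap (52 observed vs ~26
expected; permutation p at the estimator's floor), near-total directional
agreement (48/52 against a 0.52 null), and the strongest rank correlation.

A one-config pipeline driver (`runConcordance("config.yaml")`) and a thin
CLI (`inst/scripts/concord.R` with subcommands `run`, `simulate`,
`qc-mad`, `overlap`) wrap the same functions; see the methods vignette
(`vignettes/signature-concordance.Rmd`) for the statistical details and
design rationale.

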