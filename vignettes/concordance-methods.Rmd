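---
title: "Methods: scoring transcriptomic convergence of a disease model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring transcriptomic convergence of a disease model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txconcord)
```

## The question the package answers

An in vitro model of a disease — here the motivating design is a neuronal
culture system probed against an autism-spectrum-disorder (ASD) cortex
cohort — is only useful to the extent that its transcriptional response
moves the same genes in the same direction as the disease itself.
`txconcord` operationalizes that comparison: it computes a reference
disease-vs-control contrast and one or more model contrasts from raw count
matrices, classifies every reference DEG as **convergent** (model effect
significant, same direction), **divergent** (significant, opposite
direction), **unresolved** (tested but not passing the gates) or **absent**
(not tested in the model), intersects those labels across model contrasts
to form the "all convergent" / "all divergent" exclusion sets, removes
them to obtain contrast-specific residual sets, and asks which annotated
gene sets the convergent and divergent genes over-represent.

The expected study shape is a 12 vs 12 bulk RNA-seq reference cohort and a
three-condition model with 3–4 replicates per condition (a co-culture
condition `NM`, treated neurons `NTr`, untreated neurons `NUntr`), and the
synthetic generator defaults mirror exactly that shape; every component,
however, accepts arbitrary group labels and sizes.

## The differential expression model

Counts are modeled as negative binomial, `Var(K) = mu + alpha * mu^2`.
The engine is deliberately compact and fully in-package:

* **Normalization** is median-of-ratios: per-sample factors are the median
  across all-positive genes of the count over the gene's geometric mean
  (`estimate_size_factors()`). Factors are *not* rescaled afterwards, so
  only factor ratios are meaningful — a property the tests assert. A
  `pseudo_reference` flag handles matrices without any all-positive gene.
* **Dispersion** (`estimate_dispersions()`) uses a per-gene
  method-of-moments estimate on normalized counts, `alpha_hat = max(0,
  (s2 - mu)/mu^2)` with `s2` the pooled within-condition variance, then
  fits a parametric trend `a0 + a1/mu` across genes (least squares with
  one trimming pass against gross outliers) and shrinks `log(alpha_hat)`
  halfway toward the trend (`shrink_weight = 0.5`). Genes with a raw
  estimate of zero take the trend value; everything is floored at
  `dispersion_floor = 1e-8`. This is intentionally simpler than
  Cox–Reid adjusted profile likelihood with outlier replacement: the
  target property is parameter recovery and test calibration, both of
  which are measured directly by the test suite (null rejection at 5%
  measured at ~5–6%, planted log2 fold changes of 1.0 recovered with mean
  error < 0.01).
* **Testing** (`fit_contrast()`) fits, per gene, the saturated two-group
  NB log-linear model with `log(size factor)` offsets. Because the design
  is saturated, each group's log mean solves a one-dimensional score
  equation, which we iterate in vectorized form across all genes at once;
  the Wald statistic `log2FC / SE` is referred to the standard normal,
  two-sided. Genes with zero counts in all used samples are dropped
  before testing and excluded from the multiple-testing family; genes
  whose iteration does not converge (e.g. a group with all zeros) are
  flagged and get missing p-values. BH adjustment (`bh_adjust()`) runs
  over the tested genes only.

Not implemented, by design: independent filtering, fold-change shrinkage,
Cook's-distance outlier replacement, multi-factor designs. Where a
comparison with a full-featured NB engine matters, the test suite includes
a cross-check of fold-change estimates against DESeq2 on a simulated
dataset; agreement is at the hundredths level for well-expressed genes.

## Thresholds and orientation

DEG selection uses `padj < 0.05` and `|log2FC| >= 0.2` by default — a
deliberately permissive fold-change gate suited to detecting fine-grained
shifts between closely related culture conditions, with significance still
required. The same gates are reused on the model side of the concordance
classification; both are arguments everywhere they apply.

Every contrast result carries an orientation stamp (`semantic`, e.g.
`"case_vs_control"`). `classify_genes()` refuses to compare contrasts
whose stamps differ or are missing unless the caller passes `flip`
explicitly; flipping swaps convergent and divergent exactly and leaves
unresolved/absent untouched. This makes the one genuinely dangerous
silent error in this analysis — comparing a treated-vs-untreated contrast
against a control-vs-disease contrast — impossible to commit by accident.

Two open choices are resolved as follows. First, convergence requires the
model effect to *pass the significance and fold-change gates*, not merely
to have a sign: a sign from a near-zero, noisy estimate carries no
directional evidence at n = 3–4. Genes failing the gates are reported as
`unresolved` rather than silently folded into either side, so the
sign-only reading remains recoverable from the table. Second, "all
contrasts" in the exclusion sets means the intersection over whichever
contrasts the caller supplies; the pipeline config exposes this as an
explicit `exclusion` list defaulting to all model contrasts.

## Enrichment statistics

**ORA** is the upper hypergeometric tail `P(X >= k)` of the query/set
overlap within a universe (`ora()`, `hyper_tail_p()`). The universe is
the set of mapped, *tested* genes of the originating contrast, not the
genome: testing against the genome inflates enrichment for any expressed
set. BH runs across sets overlapping the universe with `k >= min_overlap`;
a set is "retained" at `p_adjust < 0.05`. The statistic is checked against
an explicit combinatorial sum for every parameter combination with
`N <= 60`.

**GSEA** uses the weighted Kolmogorov–Smirnov-like running sum
(`gsea_es()`): hits add `|metric|^w / sum_hits |metric|^w` (default
`w = 1`), misses subtract `1/(N - |S|)`; the enrichment score is the
signed extremum. Two numerical details are fixed by definition rather
than left to floating-point accident: when the positive and negative
extrema tie in magnitude (within 1e-12) the positive one is reported, and
the score is clamped to its exact `[-1, 1]` range, which long-double
accumulation can overshoot by one ulp.

The permutation null (`gsea()`) is gene-set permutation by default —
random same-size subsets of the ranked genes — because phenotype
relabeling is not meaningful at the 3–4 replicates this design carries;
phenotype permutation is available for count input and falls back, with a
warning, when any group has fewer than 3 samples. The nominal p-value is
computed relative to the same-sign portion of the null,
`(1 + #[|ES_perm| >= |ES_obs|]) / (n_same_sign + 1)`, the standard
construction; it is never zero and its granularity floor is `1/(B + 1)`.
`NES` divides ES by the mean same-sign null magnitude. When the full
subset space is no larger than `B`, it is enumerated exactly instead of
sampled, which is what makes the tiny-instance tests exact. Ranking
metrics (`rank_genes()`) are the Wald statistic (default), the log2 fold
change, or `sign(log2FC) * -log10(p)`, with deterministic lexicographic
tie-breaking.

## The synthetic generator

`sim_config()` defaults *are* the emulated study: a 12 vs 12 reference
(`CTL`/`ASD`), model conditions `NUntr = 3`, `NM = 3`, `NTr = 4`, gene
baseline means log-normal with `meanlog = 4`, `sdlog = 1.3` (median ~55
counts, heavy-tailed as empirical RNA-seq means are), library-size factors
log-uniform on 0.5–2x to exercise normalization, a shared dispersion of
0.1 (typical bulk tissue), 10% DE genes with |log2FC| = 1 split evenly by
sign, and reference DEGs planted 40% convergent / 30% divergent / 30%
null in the model. Planted model effects are applied to both non-baseline
conditions relative to the untreated condition, so the two
treated-vs-untreated contrasts carry the planted direction while the
treated-vs-treated contrast is null — and the per-contrast truth tables
record exactly that. A `dispersion_trend = c(a0, a1)` option replaces the
shared dispersion with `a0 + a1/mean`, exercising the estimator's trend
fit; the pipeline exposes it as the `trended` preset alongside `default`,
`null` (no DE) and `strong` (|log2FC| = 2, dispersion 0.05).

What the generator does *not* emulate: batch effects, gene length and GC
bias, correlated genes, outlier samples, and read-level artifacts.
Passing tests therefore demonstrate the statistical machinery is correct
and calibrated under the stated model — not that any particular real
dataset satisfies that model.

## Pipeline, determinism, and problem sizes

`run_pipeline()` chains the stages behind a YAML config with an explicit
seed, writes every table as TSV, and emits a JSON manifest whose config
hash covers the analytic configuration (not the output path), so the same
analysis is recognizable wherever it is written. Manifest bookkeeping is
enforced, not advisory: label counts must sum to the reference DEG count
and residual sets cannot exceed it, or the run aborts. Plots (lollipop,
z-score heatmap) are rebuilt from the serialized tables, never from
in-memory state. Identical config and seed reproduce every numeric table
byte-for-byte; the manifest differs only in its timestamp.

The shipped tests and the acceptance script run the chain at reduced but
structure-preserving sizes chosen as the package's own verification
budget: 200 random matrices for the normalization oracle, 2000 genes for
calibration and recovery checks, 800 genes x 100 seeded studies for the
end-to-end planted-recovery measurement, exhaustive sweeps at `N <= 60`
(ORA) and `N <= 12` (GSEA running sum). Operating characteristics at
these sizes (null rejection ~5%, empirical FDR <= 8%, convergent
sensitivity ~94%, divergent mislabeling 0%) are computed fresh on every
run of `scripts/acceptance.R`.

## Known limitations

* Two-group contrasts only; no covariates, no batch terms.
* The Wald test with plug-in dispersion is mildly liberal at very small
  n; at the 12 vs 12 reference it measures within [0.035, 0.065] null
  rejection at the 5% level, but 2 vs 2 designs should not be trusted.
* Identifier mapping is a static table lookup with explicit ambiguity and
  collision policies; no alias or ortholog resolution.
* GSEA leading-edge reporting follows the running-sum peak; no
  leading-edge clustering across sets.
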