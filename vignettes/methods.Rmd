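---
title: "Methods: downstream single-cell statistics in scdownstream"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream single-cell statistics in scdownstream}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scdownstream)
```

This vignette is the package's account of its statistical methods: what
each stage computes, the assumptions behind it, the parameters that
matter, and the choices made where more than one reasonable convention
exists. The running example throughout is a cardiac immune-cell style
experiment — clusters of macrophages/monocytes, two genotypes, a
treatment, chemokine signalling between clusters — but nothing in the
code is tissue-specific.

## Data model

All functions operate on a sparse gene-by-cell matrix (`Matrix::dgCMatrix`
with unique gene rownames and cell colnames) plus a plain `data.frame` of
per-cell metadata keyed by `cell_id`. Gene identifiers are symbols and are
matched case-sensitively everywhere; the single sanctioned renaming
mechanism is an explicit two-column ortholog map
(`apply_ortholog_map()`), because cross-species symbol conversion is a
scientific decision that should be visible in the analysis, not an
implicit side effect.

## Quality control

The QC stages run in a fixed order — gene filter, cell filter, doublet
removal, mitochondrial removal, normalization — and the `preprocess()`
wrapper computes every filter on the **raw** matrix before applying them
jointly. The alternative (re-estimating each filter on the output of the
previous one) is not idempotent for the percentile filter: percentiles
re-estimated on an already-trimmed distribution always move inward, so a
second pass would keep shrinking the dataset. Single-pass estimation
avoids that and matches how these filters are normally described.

* **Gene filter**: a gene is kept iff detected (count > 0) in at least
  `min_cells` cells (default 10). The boundary case is inclusive.
* **Cell filter**: a cell is kept iff its total count *and* its number of
  detected features both lie inside the `[P10, P90]` interval of the
  pre-filter distribution. Percentiles use linear interpolation between
  order statistics (the common "type 7" convention) and the interval is
  inclusive, reading "outside the percentiles" as the strict exterior.
  A `mode` flag switches the removal rule from either-metric to
  both-metrics, since descriptions of this filter are often ambiguous
  between union and intersection.
* **Doublets**: cells with a *supplied* doublet score strictly greater
  than 0.5 are removed; a score of exactly 0.5 is kept. The package never
  computes doublet scores — they are an upstream input — and the
  synthetic generator therefore simulates them rather than deriving them.
* **Mitochondrial genes**: removed by case-insensitive symbol prefix
  (`mt-` by default, which also catches human `MT-`).
* **Normalization**: `log(1 + c_gi / C_i * scale_factor)` with natural
  log and scale factor 10,000. Zeros map to zeros, so sparsity and the
  detection pattern are preserved, and the transform is invariant to
  rescaling a cell's library.
* **Scaling**: per-gene z-scores with the sample (n−1) standard
  deviation, zero-variance genes set to all-zero, values clipped to
  ±10. Clipping bounds the influence of single outlier cells on
  downstream percentile gates.

**Variable genes** are ranked by the residual of `log10(variance)` about
a degree-2 polynomial fit on `log10(mean)` over genes with positive mean
and variance. This is a deliberately deterministic, dependency-light
surrogate for local-regression trend fitting; it is an approximation, and
it needs baseline expression to spread over a reasonable range for the
trend to be identifiable (a point the synthetic generator reflects — see
below).

## Differential expression

The core test is a two-sided Wilcoxon rank-sum with midranks. When both
groups have at most 8 observations the p-value is computed by exhaustive
enumeration of the permutation distribution of the rank sum
(`P(|W − EW| ≥ |w − EW|)`); otherwise a normal approximation with the
standard tie correction and a continuity correction is used. The exact
path matters because tied, zero-inflated expression values make small-n
normal approximations unreliable; the tests verify the approximation
stays within 0.02 of the exact answer for continuous data at group sizes
5–8.

`wilcoxon_de()` applies two gates **before** testing: a gene is tested
only if expressed in at least `min_pct` of one group (default marker
setting 0.25; subcluster setting 0.1 with `logfc 0.5`) and
`|log2FC| ≥ logfc_threshold` (default 0.25). Benjamini–Hochberg
adjustment then runs over the tested genes only, so the multiplicity
equals the number of genes actually tested — this noticeably changes
adjusted values relative to adjusting over the whole transcriptome, and
matches the convention of the popular marker-finding implementations.
The fold change is computed on de-logged means with pseudocount 1,
`log2((mean(expm1 x_A) + 1) / (mean(expm1 x_B) + 1))`, again the
convention of the toolkits this workflow interoperates with.

`gate_positive_cells()` implements percentile gating of marker-positive
cells (e.g. Ccr2+ macrophages above the 70th percentile of scaled Ccr2):
the threshold is the type-7 percentile over the chosen cell subset and
the gate is strictly greater-than, so a constant gene yields an empty
gate rather than "all cells".

`hypergeom_enrichment()` is the one-sided upper-tail hypergeometric test
`P(X ≥ k)` for overlap between a hit list and an annotation inside a
finite universe; both sets must be subsets of the universe or the call
errors, because silently intersecting away stray genes fabricates
enrichment.

## Cluster specificity and cross-dataset correspondence

The specificity index of gene *g* in cluster *c* is the ratio of the
gene's mean expression over the cells of *c* to its mean over **all**
cells. A uniformly expressed gene scores 1 in every cluster; the
cell-fraction-weighted mean of every gene's row is exactly 1 by
construction (this is tested to machine precision). For balanced clusters
the index is bounded by the number of clusters *N*; for unbalanced
clusters the bound is `1/min(cluster fraction)`, which is why the
package's own calibration datasets use balanced clusters. The index is
computed on log-normalized expression by default (raw counts can be
passed instead): z-scored input would break the ratio interpretation and
the [0, N] range.

Two datasets are compared by Spearman correlation of their specificity
columns over a shared gene set — the intersection of each dataset's top
variable genes (default 5000), or, when the partner is a bulk table such
as a microarray with no meaningful per-gene variance ranking, one top set
intersected with the partner's full detected universe
(`universe_b = TRUE`). Genes missing from either dataset are dropped,
never zero-filled, since imputed zeros would fabricate specificity.
Spearman (midrank ties) makes the correspondence invariant to any
monotone per-gene transformation. Constant columns have undefined
correlation and are reported as `NA` with a warning.

## Regulon activity

`regulon_auc()` scores a regulon per cell by ranking all genes by
decreasing expression and accumulating the step recovery curve of the
regulon's targets over the top `k = ceiling(top_fraction × n_genes)`
positions; the score is the curve's area divided by the maximal area the
set could achieve (all targets packed at the top), giving a value in
[0, 1]. The window fraction defaults to 0.05, the convention of rank-AUC
regulon scoring tools. Ties (the many zeros of droplet data) are broken
by a fixed seeded permutation of gene order so results are reproducible;
for a random gene set of size *m* the expected score has the closed form
`(m/n)·k(k+1)/2 / maxarea` (from the hypergeometric mean of the curve),
which the tests use to verify calibration.

`module_score()` is the matched-control signature score: genes are
binned into 24 equal-frequency bins by average expression, each set gene
draws 100 control genes from its bin (with replacement, seeded), and the
score is mean(set) − mean(controls) per cell. The score is invariant to
adding a constant to all genes of a cell. Cell-cycle phase scoring is
this same operation applied to phase gene sets; no dedicated function is
needed.

`differential_regulons()` compares per-cell module scores between two
conditions (Wilcoxon + BH over regulons) and applies three pass criteria:
the regulon must be expressed, must contain at least one differential
gene of the same contrast, and its differential genes must be at least 5%
of the regulon size. The *expressed* criterion defaults to mean
normalized target expression > 0 rather than mean module score > 0:
module scores are centered against matched controls and hover around
zero even for strongly expressed programs, so the module-score reading
rejects genuinely active regulons essentially at random. The
module-score variant remains available via
`expression_criterion = "module_score"`. Differential testing operates
on module scores (not AUC scores); AUC remains available for per-cell
activity maps.

## Ligand–receptor statistics

Pair tables are standardized to ligand→receptor orientation
(`standardize_orientation()`, which requires explicit per-row orientation
metadata and collapses duplicates created by flipping) and can be
restricted to the chemokine families by case-insensitive symbol prefix
(CCL-/CCR-/CX-).

For each (sender, receiver, pair), the interaction score is the
arithmetic mean of the ligand's mean expression in the sender and the
receptor's mean in the receiver; a pair is flagged non-expressed if
either gene is detected in less than 10% of its cluster's cells.
Significance comes from shuffling cluster labels (default 1000 times)
with the add-one estimate `p = (1 + #{perm ≥ obs}) / (B + 1)`, so p lies
on the grid `1/(B+1) … 1` and is never zero; non-expressed pairs carry a
missing p rather than a misleading one.

The genotype-differential pair test treats the per-cell pair expression
(ligand + receptor)/2 as the observation unit and runs a two-sided
Wilcoxon + BH across pairs, with the same de-logged pseudocount-1 fold
change as the DE module. Whether cells or cluster-level summaries are the
right observation unit is genuinely ambiguous in workflows of this kind;
cells are the default here because a rank test needs replicated
observations, and a cluster-level variant can be obtained by passing
cluster-mean profiles.

## Pseudotime profiles

Pseudotime is consumed, never inferred. `bin_profile()` averages a gene's
normalized expression in equal-width bins over the observed pseudotime
range (default 20; empty bins are `NA` and removed pairwise downstream).
Equal-width rather than equal-count bins keep the time axis linear, at
the cost of noisier sparse bins — `bin_counts` is returned so users can
see them. `cosine_perm_test()` permutes the bin order of one profile and
reports the add-one two-sided p for `|cos|`; with fewer than 4 usable
bins the permutation space is too small and the function refuses to
answer. Identical constant profiles give cosine 1 with p = 1 (every
permutation ties), a deliberate degenerate-case answer: a flat profile
carries no evidence of shape similarity.

## The synthetic generator

`simulate_dataset()` draws counts from a negative binomial with a shared
dispersion (default 0.3) and gene-by-cell mean
`baseline × cluster fold × genotype fold × regulon fold ×
exp(amplitude · direction · t)`, times a log-normal library-size factor
(sdlog 0.2). Doublets are sums of two random cells' counts with scores
planted above 0.5; pseudotime is uniform on [0, 1] within designated
clusters; mitochondrial decoys use the `mt-` prefix. Baseline means may
be a single value or a per-gene vector; realistic log-normally spread
baselines (roughly `exp(N(log 1.5, 1))`) matter for two stages that
assume real-data structure: the mean–variance trend of variable-gene
selection is unidentifiable when every gene shares one baseline, and
matched-control module scores assume regulon targets are a small
fraction of each expression bin — in a small uniform universe the
controls end up being other planted targets and the signal cancels.

What the generator does **not** emulate: batch effects, ambient RNA,
gene–gene correlation beyond the planted programs, realistic
transcriptome-wide parameter fits, or doublet score computation. Passing
tests on this generator therefore demonstrate the statistics are
implemented correctly and calibrated under their stated assumptions, not
that any particular biological dataset satisfies those assumptions.

One consequence the tests surface deliberately: planting a large
up-regulated program shifts library sizes, and after library-size
normalization every other gene drifts down — composition effects create
genuine (small) systematic differences that a rank test will detect at
large n. The `logfc_threshold` gate is what keeps these out of DEG lists,
which is one reason the gates run before testing.

## Problem sizes and determinism

The bundled test-and-acceptance runs use deliberately small problems —
hundreds to a few thousands of cells, hundreds to 4000 genes, 200–1000
permutations, 10–20 simulation replicates — chosen so the whole suite
completes in a few minutes on one CPU while leaving the statistical
margins (recovery ≥ 95%, KS calibration p > 0.01, ≤ 2 false ledger
passes) comfortably wide. Every stochastic operation takes an explicit
seed, seeds are recorded in outputs (`run_pipeline()` writes a manifest
with seed, parameters and per-stage dimensions), and reruns with the same
configuration are byte-identical.

## Known limitations

* The Wilcoxon exact path enumerates subsets, so it is restricted to
  groups of ≤ 8 (beyond that the tie-corrected normal approximation is
  accurate and is used automatically).
* The specificity index's [0, N] range is exact only for balanced
  clusters; for skewed cluster sizes the index remains well-defined but
  its maximum depends on the smallest cluster fraction.
* Variable-gene selection uses a global polynomial trend, which can
  misrank genes at the extremes of the mean range compared to local
  regression.
* The ligand–receptor permutation test shares one set of label shuffles
  across all pairs of a run, so p-values of overlapping pairs are
  dependent; calibration holds marginally per pair.
* `run_pipeline()` orchestrates one dataset end to end; cross-dataset
  comparison (`simulate_paired_datasets()` + `cross_dataset_correlation()`)
  is run separately, as in the examples.
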