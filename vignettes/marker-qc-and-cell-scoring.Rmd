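---
title: "Marker-gene QC and immune cell scoring: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-gene QC and immune cell scoring: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TILscore)
```

## The measurement model

TILscore measures the abundance of immune cell populations in bulk tumor
expression data from small sets of marker genes.  The model behind every
operation in the package is deliberately minimal: a marker gene is a gene
expressed by exactly one cell population at a fixed (unknown) number of
copies per cell.  Under that assumption, on the log2 scale,

$$x_{g,s} = \log_2(c_g) + a_{t(g),s} + \varepsilon_{g,s},$$

where $c_g$ is the gene's per-cell expression constant, $a_{t,s}$ is the
log2 abundance of cell type $t$ in sample $s$, and $\varepsilon$ is
measurement noise.  Two consequences drive the package:

1. **Two ideal markers of the same cell type are perfectly correlated
   with slope 1** — their log2 values differ by the constant
   $\log_2(c_{g_1}/c_{g_2})$ only.  This is a testable property in bulk
   data, and most published candidate markers fail it.
2. **The mean log2 expression of a cell type's markers equals its log2
   abundance plus a constant**, so one score unit is one doubling of
   abundance.  Scores support comparisons across samples, not across
   cell types (the constant differs per cell type) unless calibrated
   against a sample with known counts.

## The pairwise similarity statistic

Plain correlation cannot test property 1: a gene tracking the right cell
type with slope 2 (co-regulated, but not abundance-stable) correlates
near 1.  The package therefore scores gene pairs with

$$\mathrm{similarity}(x, y) =
  \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
       {\tfrac{n-1}{2}\left(\mathrm{var}(x) + \mathrm{var}(y)\right)}
  = \frac{2\,\mathrm{cov}(x, y)}{\mathrm{var}(x) + \mathrm{var}(y)},$$

with unbiased (divisor $n-1$) variances — the $(n-1)/2$ in the
denominator is what makes the two forms identical.  The statistic equals
Pearson's $r$ shrunk by $2 s_x s_y / (s_x^2 + s_y^2) \le 1$, so
$|\mathrm{similarity}| \le |r|$ with equality iff the variances match.
For an exact linear relation $y = a + bx$ it equals $2b/(1+b^2)$:
1 at slope 1, 0.8 at slope 2 or 0.5, $-1$ at slope $-1$.  It is
invariant to shifting either gene and to scaling both by a common
factor; scaling only one gene strictly lowers a positive similarity.

Degenerate input is handled at two levels: `pairwiseSimilarity()` on a
zero-variance vector is an error (the statistic is undefined), while
`similarityMatrix()` drops zero-variance genes with a warning so one
flat probe cannot sink a whole candidate list.  Genes absent from a
dataset are recorded as absent, never imputed.

When several cohorts are available, `averageSimilarity()` averages each
pair over the datasets in which both genes were measured, with equal
weight per dataset regardless of its sample size — a deliberate choice:
dataset-level biology (one tumor type with aberrant expression) should
not be up- or down-weighted by cohort size.  Per-pair contribution
counts are kept so users can filter thinly-supported pairs.

## Selecting markers: a deterministic reconstruction

Published descriptions of this kind of marker triage involve judgment:
one clusters the similarity matrix, spots the "obvious" coherent block,
and applies thresholds (moderate > 0.4, high > 0.6 when better genes
exist) plus biological overrides.  `selectMarkers()` turns this into a
deterministic rule, which we state precisely because it is a design
choice, not an inevitability:

1. **Cluster**: average-linkage hierarchical clustering on
   $1 - \mathrm{similarity}$; every cluster induced at any dendrogram
   cut is scored by its mean off-diagonal similarity.
2. **Seed selection**: the largest cluster with mean above the high
   threshold (0.6), else the largest above the moderate threshold
   (0.4), else the empty set.  Ties break by cluster mean, then by
   lexicographic gene order.
3. **Slope-outlier pruning**: within the selected cluster, a pair with
   $|r|$ above the high threshold but similarity below $0.9\,|r|$
   betrays a non-unit slope (the 0.9 ratio tolerates exact slopes in
   roughly $[0.63, 1.6]$).  The gene in the most such pairs is removed,
   iteratively, and recorded as `non_unit_slope_cluster`.  Without this
   step a slope-2 gene rides into the selection on its high correlation:
   at slope 2 its similarity to true markers is about 0.8, and a cluster
   containing it still averages well above 0.6.
4. **Core-coherence pruning**: a gene whose mean similarity to the rest
   of the selection falls below 0.75 of the remaining core's own mean is
   peeled off.  This is what "the obvious subset" means operationally: a
   tight core at 0.95 sheds a hanger-on at 0.65 — for example a
   contaminant gene fed by two cell populations — even though 0.65 would
   clear the absolute threshold.
5. **Domain exclusions** are applied last and recorded as
   `domain_exclusion`, mirroring the practice of overruling promising
   co-expression when a gene is known to be expressed elsewhere.

A single candidate is returned as `single_gene_unvalidated`: its quality
simply cannot be assessed from co-expression, yet canonical single genes
(FOXP3, TBX21, PTPRC) remain worth scoring.  `cellTypeQuality()`
applies the panel-level verdict, discarding cell types whose selected
markers average *strictly below* 0.4 — strictly, so a 0.40 cell type
(the weakest retained population in the bundled panel) survives — and
attaches mean log2 expression as a diagnostic, since weakly expressed
marker sets look worse purely through measurement noise.

Both pruning ratios (`slopeRatio = 0.9`, `coreRatio = 0.75`) are
exposed as arguments; the defaults were fixed once from the geometry of
the gene archetypes above, and the package's tests exercise them only
through the generator's standard conditions.

## Scoring, Total TILs, enrichment

`cellScores()` averages each cell type's available marker genes per
sample.  Scoring from the *available* subset (rather than erroring) is
the practical rule for targeted panels that carry only part of the
marker list; the provenance slot always records which genes were used.
Derived scores are contrasts computed after scoring — the bundled set
defines CD4 cells as T-cells minus CD8 T cells, reported only when both
parents were scored.

Because most immune populations rise and fall together with the overall
infiltrate, `totalTILs()` forms a composite: the mean of all cell
scores whose correlation with CD45 (PTPRC) expression exceeds 0.6
(Pearson by default; Spearman available).  The inclusion set is
recomputed on the data at hand because it legitimately differs between
cohorts; a frozen list can be supplied for reproduction.  No score
passing the rule is an error, not an empty composite.
`enrichmentScores()` then regresses each cell score on Total TILs
(ordinary least squares, pooled over all supplied samples) and keeps
the residuals: an enrichment of 1 means twice the cell abundance
expected at that infiltrate level.  Residuals of each cell type average
zero over the fitting samples by construction.

Three reporting transforms share one caveat — they change the meaning
of a score, so the object's `scoreType` label changes and slots that no
longer make sense (enrichment after re-anchoring, for instance) are
dropped rather than silently carried: `calibrateAbsolute()` (counts via
a reference sample: score 5 against a 500-cell reference scoring 4
gives 1000 cells), `relativeToBaseline()` (log2 fold change from a
baseline group's mean), and `normalizeToCellType()` (per-sample
contrasts to an anchor population, immune to any additive per-sample
normalization — the appropriate view in PBMC-like material where
reference genes are themselves confounded by composition).

## Normalization

For count platforms, `selectReferenceGenes()` ranks candidate reference
genes by the geNorm stability measure: $M_j$ is the mean over other
candidates $k$ of the SD across samples of $\log_2(x_j/x_k)$, and genes
are peeled off worst-first down to `minGenes` (default 3).  Since the
"best subset" size is a judgment call, the full exclusion trajectory is
reported so any cut can be taken.  `referenceNormalize()` divides each
sample by its reference geometric mean and rescales by the grand
geometric mean; the operation is idempotent and equalizes reference
geometric means across samples to within floating tolerance.
Candidates with zero counts are excluded from ranking (their log ratios
are undefined), and a zero reference count at normalization time is an
error naming the sample and gene.

For sequencing data the package follows the convention of scoring
log2-transformed normalized values directly; `log2Transform()` uses a
pseudocount of 1 by default (zero counts map to zero) and records the
choice in the object metadata, since upstream pipelines are often
silent about zero handling.

## Concordance and reproducibility

`platformConcordance()` reports Pearson $r$, the least-squares slope,
and `centeredRMSE()` — RMSE after mean-centering each platform
separately, since every platform reports on its own scale.  The slope
is reported alongside $r$ because near-unit slope on log2 data is the
stronger claim: a 2-fold change on one platform predicting a 2-fold
change on the other.

`noiseVariance()` decomposes replicate scores with a one-way
random-effects model (sample identity as random effect) fit by REML via
`lme4`, and reports residual/(residual + between) as the proportion of
variance due to noise, plus the residual SD in log2 units.  On balanced
designs REML coincides with the classical ANOVA method-of-moments
estimates whenever those are non-negative, which the test suite uses as
an independent oracle.  Two degenerate cases are resolved by convention
before any fitting (the mixed-model machinery cannot estimate a zero
residual): replicates identical within every sample give residual 0,
and fully constant data give 0/0 defined as noise proportion 0.
Between-sample components at the zero boundary are flagged as
truncated.

## The synthetic-data generator

`simulateDataset()` exists so that every statistic above can be tested
against known truth without external downloads.  It draws latent log2
abundances per cell type, each loading 0.7 by default on a shared
"total infiltrate" factor — emulating the strong mutual correlation of
immune populations in real tumors — and generates genes in four
archetypes: `pure` markers (the measurement model above),
`contaminant` genes whose *linear-scale* contributions from two or more
cell types are summed before logging (the physically correct mixing
model; note that equal mixing roughly halves the gene's log2 variance,
which is exactly why such genes fall visibly below the pure-marker
similarity band, at about 0.65 rather than 0.99 under the standard test
conditions), `slope` genes tracking one cell type with $\gamma \ne 1$,
and `noise` genes.  `simulateArchetypes()` is the canned four-gene
walkthrough — two ideal markers, an independent gene, a slope-2 gene —
used as the standard QC demonstration; at its defaults ($n = 500$,
abundance SD 1, noise SD 0.1, $\gamma = 2$) selection recovers exactly
the two ideal markers on every seed, with the slope-2 gene discarded as
`non_unit_slope_cluster` and the independent gene as `low_similarity`.

What the generator does **not** emulate: count-level sequencing noise
(negative binomial reads, depth variation), expression-dependent
measurement error (a hook exists but is off by default), batch effects,
tumor-intrinsic expression of immune genes, and spatial sampling
variability.  Tests passing on this generator therefore establish that
the statistics behave as designed under their own model, not that the
bundled marker genes are valid in any particular new cohort — that
validation must come from the QC workflow run on real data.

## Problem sizes and numerical conventions

The test and acceptance suites run at deliberately modest sizes chosen
to make Monte-Carlo bands tight enough to be meaningful: $n = 500$
samples for similarity/selection checks (SE of a similarity near 0.99
is well under 0.01 there), 100 seeds for the archetype-recovery sweep,
12 samples x 3 replicates x 200 seeds for variance-component recovery
(matching the triplicate design such assays use in practice, true noise
proportion $0.01/1.01 \approx 0.0099$), and 50 seeds per point for the
noise-monotonicity grid (SD in $\{0, 0.2, 0.5, 1\}$).  Gene symbols are
matched case-insensitively with a small alias table (the CD45 gene
appears in print both as PTPRC and the transposed PTRPC; both are
accepted and stored as PTPRC).  All ties anywhere in selection break
lexicographically; all randomness flows from a single explicit seed.

## Known limitations

Scores conflate abundance with per-cell activity where marker
expression is activity-dependent; cell types without coherent markers
(CD4 subpopulations beyond the derived contrast) are out of reach of
the marker approach entirely; the selection rule's pruning constants,
while fixed and documented, encode one reading of an inherently
judgment-laden procedure; and Total TILs inherits the arbitrariness of
its 0.6 inclusion threshold — the package surfaces the full correlation
vector so the sensitivity of the composite to that choice is always
inspectable.
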