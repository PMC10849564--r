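---
title: "Quantifying cell-type maturation from developmental single-nucleus data"
author: "devtraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-type maturation from developmental single-nucleus data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Developmental single-nucleus RNA-seq atlases profile the same brain region
at an ordered ladder of ages — here eight ages from embryonic day 16 (E16)
to postnatal day 65 (P65), with P65 the adult reference — with a small
number of biological replicates per sex per age. The questions this package
answers are statistical, not curatorial: *how far* is each cell type from
its adult transcriptomic state at each age, *how* does it close that gap
(gradually or in steps), *when* do sexes or sensory-mutant genotypes
diverge, which genes drive the change, how does sub-regional identity
sharpen, how reliably do young cells map onto adult types, and whether a
mutant genotype is developmentally *delayed* along a reference maturation
axis. Every statistic is implemented against a seeded synthetic-data
generator whose ground truth makes each stage testable without the original
sequencing data.

## The maturation trajectory statistic

For one cell type, cells of all ages are pooled and embedded: library-size
log-normalization (`log1p(count / libsize * 1e4)`), the 2000 most variable
genes, per-gene scaling (n−1 standard deviation, values clipped to ±10) and
PCA. The number of PCs used is the smallest k whose cumulative variance
fraction reaches 20%, capped at 100 — a rule that adapts dimensionality to
how concentrated the biological signal is. The trajectory value at age *a*
is the Manhattan distance between the age-*a* centroid and the adult
centroid in that PC space; by construction the adult value is 0.

Distances occasionally rise transiently (e.g. transient expression of
axon-guidance programs); a left-to-right **monotone clamp** replaces any
value exceeding the previous clamped value with that previous value, so the
curve reads as cumulative approach to the adult state. **Stage deltas** are
differences of the clamped curve across consecutive age pairs of the stage
set; the default stage set is the five postnatal stages P0–P4, P4–P10,
P10–P18, P18–P28, P28–P65. Embryonic distances are computed and reported
but excluded from staging: the stage accounting that defines the classes is
named over postnatal stages, and including the embryonic intervals would
change the class semantics (this is configurable via `age_ladder()`).

**Classification.** Let k\* be the minimum number of stages, taken
largest-first, whose deltas sum to ≥90% of the total change. With five
stages, k\* ≤ 2 is stepwise (class 3), k\* = 3 intermediate (class 2), and
k\* ≥ 4 gradual (class 1). For S ≠ 5 stages the fractional cutpoints
k\*/S ≤ 0.4 (class 3) and ≤ 0.6 (class 2) are used; they reduce to the
2 / 3 / 4–5 split at S = 5. Classes are computed on the *clamped* curve —
the clamped curves are what is plotted and reasoned about, and stage deltas
of the raw curve could be negative.

A k-nearest-neighbor maturity measure complements the distances: per cell,
the fraction of its 50 Euclidean nearest neighbors (ties broken by cell
index, for determinism) that are adult cells, averaged per age.

## Group contrasts (sex, genotype)

Per cell type, the same embedding pipeline is run on both groups jointly;
each sample's centroid is computed, and the effect size is the mean
Manhattan distance between group centroids divided by the pooled mean
within-group distance. The p-value is a two-sided t-test between the
between-group and within-group distance lists, BH-adjusted across cell
types. The distance lists share samples and are therefore dependent; the
t-test deliberately ignores this, replicating the source procedure.
`group_distance_statistic(n_perm = ...)` offers a label-permutation
p-value as a safer alternative; the default reproduces the published
procedure.

## Pseudobulk differential expression

All gene-level tests run on **pseudobulk**: raw counts summed over each
sample's cells, so inference is at the biological-replicate level. The
engine is deliberately plain: log2-CPM with a +1 pseudocount, then a
per-gene one-way F-test across groups (ages for devDEGs, sexes for
sexDEGs), BH adjustment, significance at adjusted p < 0.05 (FDR < 5%).
This replaces moderated pipelines (DESeq2, limma-voom): the estimand —
group-mean differences of sample-level aggregates — is the same, and the
plain F-test is exactly specifiable and dependency-free. It gives up
empirical-Bayes shrinkage, which mostly matters at very small n; the
calibration and power checks in the test suite measure what the plain
engine actually delivers at the design's n = 4 samples/age. Note that CPM
normalization couples genes: when many genes ramp up with age, constant
genes lose relative abundance and can be genuinely differential in CPM
space. This compositional effect is a property of the method (also of the
published pipelines), not a bug, and the null-calibration test therefore
uses a fully null dataset.

Zero-residual-variance genes are flagged: constant genes get p = 1,
perfectly separated genes p = 0.

**Sharing.** A devDEG found in >70% of cell types is `shared`, in <20%
`specific`, otherwise `intermediate`; both boundaries strict, so exactly
70% is intermediate.

**Trends.** Per-gene expression trends over the age index are fitted with
a cubic smoothing spline at fixed df = 4 (a generalized additive model
with one predictor is a penalized spline; fixing df makes it exactly
specifiable). Constant input returns a constant; at least df + 1 distinct
ages are required. Z-scored trends are clustered agglomeratively (Ward
linkage, Euclidean), cut at a user-chosen number of clusters — the source
does not state its cluster count, so it is exposed as a parameter.

**Module scores.** Score = mean expression of the set genes minus the mean
over control genes drawn per set gene (100 controls, seeded, with
replacement) from the same average-expression bin of 24 bins. Controls
exclude the set genes themselves; without that exclusion a coherently
shifted set would be compared against itself whenever it dominates the top
bins. Scores are averaged within ages and z-scored across ages.

**Refinement score.** For a gene set: the number of (gene, cell type)
combinations significant in a *dedicated* P10-vs-adult two-group contrast,
divided by the number of combinations with nonzero pseudobulk at ≥1 age.
The dedicated contrast (rather than reading significance off the omnibus
across-age test) matches the definition of change *between* P10 and adult.

## Regionalization

Cell-type profiles are mean *scaled* log-normalized values per type,
computed **within each age** — scaling across ages would let age effects
masquerade as regional correlation. Within-region cohesion at an age is the
mean off-diagonal Pearson correlation among the region's member types,
normalized by the adult value; regions need ≥2 member types to be scorable.
Region markers are one-vs-rest Wilcoxon rank-sum tests (normal
approximation with tie and continuity correction, matching
`wilcox.test(exact = FALSE)`), BH within region, adjusted p < 0.05 and
higher in-region mean.

## Identity mapping

The canonical-correlation label-transfer algorithm is out of scope; its
*decision rules* are the contribution here. A correlation soft classifier
stands in: each query cell's scaled expression is Pearson-correlated with
each adult type's scaled profile, negatives truncated to zero, normalized
to sum 1 (uniform fallback for all-zero rows). Scaled values matter: on raw
log-normalized data the shared baseline expression profile dominates every
correlation and scores collapse toward uniform. Because the module's
contract is the score matrix, scores from an external transfer tool can be
imported and pushed through identical rules.

Assignment rules mirror the published wording exactly: reference mapping
assigns when the top score *exceeds* 0.6 (strict, no second-best condition
— the source states none); across-age mapping assigns when the top score
exceeds 0.8, or exceeds 0.5 *and* is at least (inclusive) twice the
second-best. The identity ratio of a type is (diagonal − top off-diagonal)
/ diagonal of the type-averaged score matrix: 1 is a perfect one-to-one
mapping, 0 a tie, negative values mean another type wins.

## Pseudotime and developmental delay

The reference (wild-type) cells of a cell type define a 20-PC space from
2000 variable genes; the gene selection, scaling statistics and rotation
are retained. The maturation axis is the piecewise-linear **principal
path** through the age centroids in ladder order — with a single lineage
over ordered ages this is the deterministic skeleton of a principal curve.
A cell's pseudotime is the arc-length position of its nearest point on the
path (per-segment orthogonal projection, clamped to the segment; global
nearest; ties to the earlier segment). Projections are clamped to
[0, total length]: the delay statistic compares means, and unbounded
extrapolation would let outliers dominate. Mutant and control cells are
projected with the *reference* parameters, pseudotimes averaged per
sample, and genotypes compared with a two-sided t-test, typically within
one age. A per-cell-type aggregation (means per type, t-test across types)
is available for across-type summaries.

## The synthetic world

Counts are negative binomial with a shared dispersion; each gene's log-mean
composes a log-normal baseline, a cell-type marker effect, a region effect
that sharpens linearly from 0.25 to 1 across ages, a maturation effect
scaled by the cell type's schedule m(a) ∈ [0, 1], and a sex effect active
in configured stage windows. A genotype's developmental delay shifts the
schedule look-back by whole stages (clamped at the first age). One global
seed drives everything; identical configurations are bit-identical.

Schedules: `gradual` is linear in age index; `stepwise` jumps 0→1 at its
dominant stage — defaults draw from the middle and last stages, where
stepwise cell types show their dominant steps; `intermediate` is a logistic
rescaled to the endpoints with scale span/15 age-index units. That scale is
the max-margin choice for the class definition itself: the noiseless
schedule puts ~81% of its change in its two largest stages (safely below
the 90% stepwise boundary) and ~98% in three (safely above the 90%
intermediate requirement), so the ground-truth class is 2 with balanced
margin on both sides, as the truth-consistency invariant requires.

Default noise scales are chosen for realism against deeply sequenced
single-nucleus data (thousands of UMIs per cell): baseline log-mean log 2
over a 400-gene panel (≈1700 UMIs/cell), dispersion 10
(var = μ + μ²/10), log-normal library factors (sd 0.3 on the log scale),
effect sizes log 4, and a maturation-dominated panel (200 of 400 genes) —
variable-gene panels in developing tissue are dominated by age-varying
genes. A deliberately shallow world (hundreds of UMIs per cell, dispersion
2) makes the 20%-variance rule admit ~30 pure-noise PCs and degrades class
recovery; that regime is unrealistic for the data type and is not the
default.

**What the generator does not emulate:** batch and dissection effects,
doublets, ambient RNA, varying cell-type abundances, gene-gene correlation
beyond the planted factors, and realistic compositional structure. A green
recovery test therefore establishes that the statistics recover the planted
signal under NB sampling noise at the stated design — not robustness to
artifacts the generator never produces.

## Numerical conventions

* Standard deviations use the n−1 denominator; scaling clips at ±10.
* PCA fixes each component's sign so its largest-magnitude loading is
  positive; scores match a dense SVD to 1e-8 up to that convention.
* BH adjustment is the step-up rule with monotonicity enforcement, capped
  at 1; `NA` p-values pass through.
* Degenerate cases are flagged, not dropped silently: zero-variance
  t-tests report p = 1 with a `degenerate` flag, zero trajectories an
  undefined class, zero diagonals an `NA` identity ratio.
* All neighbor and tie decisions (kNN ties, equal projection distances)
  resolve by index / earlier segment, for exact reproducibility.

## Open design points resolved here

* Embryonic ages are excluded from the default stage set (overridable).
* Classes are computed on clamped curves.
* The residual covariate adjustment the source applies inside its
  variance-stabilizing transform is not replicated; the log-CPM + scaling
  stand-in carries no covariate regression.
* The reference-mapping 0.6 rule carries no second-best condition.
* Within-age (not cross-age) scaling for regional profiles.

## Limitations

The distance trajectory has a noise floor: at ages where a cell type is
already adult-like, centroid distances sit at a sampling-noise level rather
than 0 while the adult's own distance is exactly 0, which inflates the
last stage's delta when many noisy PCs are retained. The t-test on distance
lists ignores their dependence (by design, to replicate the procedure); the
permutation option is the statistically safer variant. The pseudobulk
F-test inherits CPM compositional coupling. None of these are corrected
silently, because the package's purpose is to implement the published
procedures exactly and make their behavior measurable.
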