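---
title: "Tissue-of-origin classification with weighted expression-profile alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-of-origin classification with weighted expression-profile alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wagep)
```

## The problem

A cancer of unknown primary origin (CUP) is a metastasis whose primary tumor
cannot be located clinically. Because treatment regimes are organized around
the anatomical origin and histology of the primary tumor, inferring the
tissue of origin from the metastasis's expression profile is clinically
valuable. `wagep` implements a density-alignment classifier for this task:
instead of training on a fixed signature gene set, it compares every gene of
a query profile against class-conditional reference distributions, so the
classifier improves as annotated reference data accumulate and is not tied
to any *a priori* gene list.

## The model

**Reference model.** For every gene $g$ and reference class $c$ (a cancer
type or tissue), the expression values of the class's samples are summarized
by a Gaussian kernel density estimate $f_{g,c}$. All classes of a gene share
one evaluation grid so the curves are pointwise comparable, and each curve
is renormalized to trapezoidal area 1 on that grid.

**tm-score (tissue match).** For a query value $x_g$,
$\mathrm{tm}(g,c) = f_{g,c}(x_g) / \max_u f_{g,c}(u) \in [0,1]$:
the class density at the query value, normalized by the class's modal
density. 1 means the value sits at the most typical expression level for the
class; 0 means it is outside the class's observed range.

**ts-score (tissue specificity).**
$\mathrm{ts}(g,c) = \mathrm{tm}(g,c) - \max_{c' \ne c} \mathrm{tm}(g,c')
\in [-1,1]$: +1 is a perfect fit to this class to the exclusion of all
others, $-1$ means the gene fits anything but this class, 0 is
indeterminate. At most one class per gene can be positive.

**Gene-uniqueness weight.** With $f_c$ the class density and $g$ the
pointwise maximum of all competing densities,
$$w(g,c) = \int_{\{f_c > g\}} \big(f_c(x) - g(x)\big)\,dx \in [0,1],$$
the area by which the class's expression distribution exceeds its best
competitor where it is strictly the highest. Identically distributed classes
get exactly 0 (ties contribute nothing); a class whose expression range is
entirely its own approaches 1. The weight is a property of the reference
alone — it never sees the query.

**Similarity and classification.** The similarity of a query to class $c$ is
the weight-weighted mean of its ts-scores,
$\sum_g \mathrm{ts}(g,c)\,w(g,c) \big/ \sum_g w(g,c)$, equivalently
"multiply each ts-score by the gene's weight, then divide by the class's
mean weight, then average" — the division compensates classes for having
different numbers of specific genes. The predicted class is the similarity
argmax (lexicographic tie-break, flagged). With all weights equal the
statistic reduces to the plain mean of ts-scores (the unweighted variant,
kept available for comparison).

**Reliability.** The best-hit similarity score itself calibrates confidence:
calls at or above 0.10 are tier `high`, at or above 0.05 `medium`, below
that `low` (both boundaries inclusive; thresholds configurable). The
sliding-window accuracy curve (`accuracy_curve()`, width 0.1 similarity
units, step 0.005, starting at the observed minimum score) makes the
score-accuracy relationship visible on any validated cohort.

**Accuracy categories.** Against a truth label a call is `exact` (same
class), `similar` (same organ group, e.g. one lung carcinoma subtype called
as another), `same_site` (the top class is the representative class of the
metastasis site and the runner-up is exact/similar), or `incorrect`. Organ
groups and site maps are user-supplied (`taxonomy()`), since sensible
groupings depend on the reference class roster; defaults ship only for the
synthetic classes, where each class is its own group.

## Numerical choices

- **Kernel and bandwidth.** Gaussian kernel with Silverman's rule-of-thumb
  bandwidth ($0.9\,\min(\hat\sigma, \mathrm{IQR}/1.34)\,n^{-1/5}$) per
  (gene, class), floored at one grid spacing so an all-tied value set still
  yields a proper density. The KDE is evaluated exactly (no FFT binning) in
  a small C++ kernel; estimates are deterministic and bitwise reproducible.
- **Grid.** 512 points per gene spanning the pooled value range padded by 3
  pooled standard deviations per side. The padding leaves Gaussian tails
  negligible at the grid edge, which is what lets disjoint-support genes
  reach weights near 1; values outside the grid score 0 by convention.
- **Eligibility.** A (gene, class) density requires at least `min_class_n`
  (default 6) non-missing values; genes with fewer than two eligible
  classes, or without two distinct pooled values, are dropped and recorded.
  Missing query values mask the gene for that query only.
- **Integration.** All areas are trapezoidal on the shared grid; weights in
  $(-10^{-6}, 0)$ or $(1, 1+10^{-6})$ from floating point are clamped,
  larger excursions raise an internal error. The test suite checks the
  weight integral against an independent quadrature oracle on a 100× finer
  grid.
- **Serialization.** Models round-trip through R's native serialization
  (`write_model()`/`read_model()`), which is lossless for every grid,
  density array and configuration field. Numeric TSVs written by the CLI
  use 17 significant digits, so file-mediated pipelines reproduce in-memory
  results bit-identically.

## Leave-one-out cross-validation

`loocv()` removes each sample in turn, rebuilds its class's densities — and,
by default, the entire weight matrix, since weights derive from densities —
without it, then scores and classifies the sample. Two design points are
deliberate:

- **Fixed grids across folds.** Evaluation grids are computed once from the
  full cohort and held fixed during refits. Removing one sample whose values
  lie inside the pooled range then leaves every other class's density array
  exactly unchanged, which is both the natural reading of "reconstruct the
  densities without the sample" and the fast path: one class's curves and
  the weight matrix are all that change per fold. (A from-scratch rebuild
  would shift every grid slightly through the pooled-SD padding, perturbing
  all densities by interpolation error while changing no substance.)
- **Refit weights by default.** Freezing the full-cohort weights
  (`recompute_weights = FALSE`) is available for speed, but the default
  refits them per fold so the held-out sample cannot leak into its own
  classification through the weights.

Samples whose class would fall below `min_class_n` after holdout are
skipped, with the reason recorded in the result's `skipped` attribute.

## The synthetic-data generator

Real reference databases of thousands of curated, cross-normalized tumor
profiles are not redistributable, so the package ships a seeded generator
that emulates the *structure* such data exercise in the method:
class-specific marker genes (disjoint blocks, means shifted by `delta`
background SDs), shared background genes, optional missing values, and
"drift" — queries whose markers are partially redrawn from background,
mimicking the metastatic loss of origin-specific expression.

The named scenarios fix the study conditions used throughout the tests:

| scenario | classes | genes | markers/class | n/class | delta | drift |
|----------|--------:|------:|--------------:|--------:|------:|-------|
| easy     | 8       | 1000  | 100           | 30      | 3     | 0 |
| noisy    | 8       | 1000  | 25            | 30      | 1.5   | 0 |
| graded   | 8       | 1000  | 100           | 30      | 3     | uniform(0,1) |

"Easy" (20% background genes) is the parameter-recovery setting: with 3-SD
marker shifts, full LOOCV should recover essentially every sample. "Noisy"
makes 80% of the panel pure background and halves the marker shift; this is
the setting where gene weighting should earn its keep, because the
unweighted mean dilutes the few informative ts-scores across hundreds of
noise genes. "Graded" spreads query quality over the whole drift range so
that best-hit scores span the reliability tiers. Sample sizes (30/class,
about the scale of a mid-sized reference class) keep a full LOOCV with
per-fold weight refits to a couple of minutes on one core; the drift and
retention property tests average over at least five seeds.

What the generator does *not* emulate: platform/batch effects, probe-level
noise, heavy-tailed or multimodal within-class expression, correlated gene
modules, and class imbalance. Passing tests therefore demonstrate the
method's correctness and its behavior under controlled signal/noise/drift —
not performance on any real cohort, which depends on reference curation and
cross-sample normalization that are out of scope here.

One empirically visible caveat the tests do encode: at small class sizes
(n ≈ 20), KDE sampling noise alone can push a non-specific gene's weight
above 0.25, so specific-gene lists from small references should be read with
that threshold's noise floor in mind; at n = 200 interchangeable classes
stay below 0.15.

## Known limitations

- The tm/ts formulations implement the documented semantics (mode-normalized
  density fit; margin over the best competitor) and are isolated in
  `tm_score()`/`ts_score()` so alternative formulations can be swapped in
  without touching the rest of the pipeline.
- Expression is assumed log-scale and cross-comparable; no normalization is
  performed. Harmonizing heterogeneous platforms is a prerequisite, not a
  feature, of this package.
- Weights above 0.5 are not exclusive to one class per gene: two classes
  with mutually disjoint expression ranges both deserve (and get) weights
  near 1.
- Densities are univariate per gene; gene-gene correlation is ignored by
  construction, as in the underlying method.
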