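---
title: "Modulewise functional connectivity: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modulewise functional connectivity: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(modfc)
```

## The analysis in one paragraph

`modfc` compares resting-state functional connectivity between two subject
groups on a node-and-module brain parcellation. Each subject contributes a
full signed Pearson correlation matrix over ~200 spherical nodes assigned to
nine canonical resting-state networks ("modules"). The unique edges are
partitioned into the 45 module–module blocks; within each block, the
edge-by-subject matrix is row-demeaned and reduced by SVD to one
principal-component coordinate per subject. Groups are compared on these
coordinates with Cohen's *d* (screened at |d| ≥ 0.5) and Wilcoxon rank-sum
tests; the same group contrast is inspected edge by edge through a
sign-stratified directional-consistency metric; a linear SVM classifies
subjects from the 45 coordinates and produces dimensional classification
scores; and the coordinates are screened against behavioral measures at
|r| ≥ 0.5. A block-covariance simulator with planted effects exercises the
whole chain and quantifies its recovery behavior.

## Node summarization and the connectome

Per node, voxel series are detrended against Legendre polynomials of degree
0–2 on time rescaled to [−1, 1], demeaned and variance-normalized, and
summarized by the first left singular vector of the time × voxel matrix.
Two conventions are deliberately fixed:

* **"Whitening" is per-series variance normalization**, not temporal
  pre-whitening. Pearson correlation is scale-invariant, so this choice
  cannot change any downstream result; an AR(1) pre-whitening routine
  (`prewhiten_ar1()`) is provided separately for sensitivity analyses.
* **SVD sign**: a singular vector is defined up to sign, but the final
  graph is sign-sensitive. The representative series is aligned to correlate
  positively with the mean voxel series; in the degenerate case of a
  near-zero mean series (e.g. two voxels in perfect antiphase) the sign of
  the largest-magnitude voxel loading decides, and the fallback is reported
  via a warning.

The connectome is the full signed correlation matrix: no threshold is
applied, since downstream stages either use all edges (block SVD, means) or
impose their own effect-size screens.

## Block summarization

For block *i* with *m<sub>i</sub>* edges and *n* subjects, the
*m<sub>i</sub>* × *n* matrix of edge strengths is row-demeaned and
decomposed once across **all** subjects jointly (both groups in the same
SVD). The first left singular vector gives edge loadings; the per-subject
coordinates are the first right singular vector **scaled by the first
singular value** (principal-component scores). The scale does not affect
Cohen's *d*, rank-sum tests, correlations, or the z-scored SVM inputs; it is
fixed purely so that written outputs are reproducible to the digit.
Row-demeaning puts the all-ones vector in the matrix null space, so each
block's coordinates sum to zero to machine precision — asserted in the test
suite for every block.

The SVD coordinate has an arbitrary sign, while group differences must be
reported directionally. The convention is: coordinates correlate positively
with the subject's mean block connectivity. A higher coordinate therefore
always means "stronger (more positive) block connectivity", and for blocks
whose group-mean connectivity is negative in both groups, a *negative*
coordinate difference means the first group carries the *stronger negative*
connectivity (direction label `G1->G2-`). If the alignment correlation is
exactly zero the first nonzero loading is made positive and the event is
logged.

## Group screens

* **Cohen's d** uses the classical pooled-SD formula without the Hedges
  small-sample correction, matching the "medium effect" convention that
  motivates the 0.5 threshold.
* **Rank-sum p-values** are exact for combined samples of ≤ 20 without
  ties and use the tie-corrected normal approximation otherwise (no
  continuity correction, so identical samples give p = 1). At the default
  study size of 24 subjects the approximation is used. p-values are
  reported **uncorrected**; the output headers say so. With 45 blocks and a
  non-independent node system a formal multiplicity correction is both
  impractical and overly conservative; the screens are explicitly
  exploratory, with the effect-size threshold carrying the selection logic.
* **Edgewise consistency**: edges are first classed by the sign of their
  group-average connectivity (positive in both groups / negative in both /
  mixed); mixed edges are excluded. Within each class and block, edges with
  |d| ≥ 0.5 are counted by direction, and the metric
  (N₁ − N₂)/(N₁ + N₂) is computed only for blocks retaining at least 5% of
  their edges. Two deliberate readings: the 5% denominator counts the
  block's edges *of the current sign class* (the analysis is run separately
  per class, so "total edges" is read within-analysis; this is configurable),
  and the comparison is exact — "at least 5%" retains a block sitting
  precisely on the boundary, implemented with an integer rational comparison
  rather than floating-point division. The 0.33 threshold corresponds to at
  least twice as many edges favoring one group as the other.

## MVPA

The classifier is a linear SVM with unit cost: a linear decision function is
presupposed by the use of feature weights, and no hyperparameter search is
performed (both kernel and cost are config options). Accuracy comes from
stratified fourfold cross-validation — train on 75%, test on 25%, three
subjects per group per fold at the default 12 + 12 — with fold assignment
drawn from the seed. Features are z-scored using the *training* fold's
means and SDs, applied unchanged to the test fold, because the
singular-value scaling gives coordinates block-dependent scales. Dimensional
classification scores are signed distances from the hyperplane of a
full-data refit (one model, one score per subject; held-out fold scores
would mix four different models), with positive scores pointing to the
first group level. The fold bookkeeping — no subject ever tested by a model
that saw it in training — is asserted in the tests.

## What the simulator emulates, and what it does not

The generator reproduces the data regime the analysis assumes: two groups
of 12 subjects, ~200 nodes in 9 modules (default sizes 14, 6, 16, 21, 29,
29, 38, 30, 26), 200 time points per subject, and block-structured
population correlation matrices. Defaults were chosen once as a realistic
regime and are not tuned to any particular test outcome:

* within-module correlation 0.4 — the typical magnitude of within-network
  coupling after preprocessing;
* between-module ±0.1 in a two-community pattern (sensory: the three
  visual modules, sensorimotor, auditory; association: default-mode,
  executive, both frontoparietal), giving the sign-mixed block means seen
  in real group-average connectomes;
* group differences planted in the *population correlation* of selected
  blocks (delta 0.3 in the recovery studies), so the modulewise effect size
  is controlled by the series length and delta, not by per-subject noise;
* behavior scores as linear couplings to block strengths plus Gaussian
  noise, with `coupling_noise_for_r()` to hit a target population
  correlation.

Time series are temporally white by default: the analysis consumes only
correlation matrices, for which whiteness is the minimal sufficient
structure; an AR(1) parameter adds autocorrelation when temporal structure
itself is under study. The simulator does **not** model hemodynamics,
motion, physiological noise or spatial smoothness — so passing recovery
tests demonstrate the *analytic* chain (from clean multivariate-normal data
to decisions) and say nothing about robustness to acquisition artifacts.

Implied covariance matrices are checked for positive semi-definiteness;
small violations are repaired by eigenvalue clipping with a warning, and the
repair refuses to move any target correlation by more than 0.01 (tolerance
configurable). Seeds: one master seed spawns one stream per group, and
per-subject seeds are drawn sequentially from the group stream, so adding a
subject never changes existing subjects' data.

## Numerical and degenerate-input policy

* Winner-take-all module assignment breaks argmax ties in favor of the
  earliest module in the canonical order; exact ties are measure-zero on
  real z-maps, and every tie is logged.
* The statistic read "at the node location" from a z-map is the mean over
  in-sphere voxels (radius 5 mm by default); a peak option exists.
  Coordinates are always MNI mm; voxel indices never surface in the API.
* Pruning drops unassigned nodes and modules below 2 nodes (the general
  form of removing a singleton cerebellum module) and errors if fewer than
  two modules survive. `prune(prune(x)) = prune(x)`.
* Constant series, all-zero voxel matrices, zero pooled SDs and zero-variance
  scores are errors naming the offending unit, never silent NaNs.

## Problem sizes used in the shipped checks

The recovery studies in the test suite run the full 209-node design at
1,000 time points over 50 seeds (modulewise and edgewise recovery of one
planted block) and 20 seeds (classifier accuracy with three planted
blocks, plus a 100-permutation null), and the behavior round-trip uses a
reduced 36-node design at 300 time points over 100 seeds — sizes chosen so
the entire suite documents the pipeline's statistical behavior while
remaining quick enough to run on every change.

## Known limitations

* Pearson correlation does not separate direct from indirect coupling;
  partial-correlation variants are out of scope.
* The modulewise coordinate summarizes a block by its first principal
  component only; blocks whose group difference lives in later components
  are invisible to the modulewise screen (the edgewise screen partially
  compensates).
* With 12 + 12 subjects the null rate of the |d| ≥ 0.5 screen is
  substantial (~23% per block under independence); the screens are
  hypothesis-generating, not confirmatory.
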