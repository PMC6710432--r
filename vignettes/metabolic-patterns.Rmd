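---
title: "Deriving metabolic covariance brain patterns with mbpattern"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving metabolic covariance brain patterns with mbpattern}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbpattern)
```

# The model

`mbpattern` derives a *metabolic covariance pattern* — one voxel-weight map
`p` — from a cohort of preprocessed FDG PET scans, such that the inner
product of `p` with a subject's scan summarizes that subject's expression of
a disease-related metabolic topography. Two patterns are supported by the
same machinery:

* the **disease-specific pattern** (PDSP): a soft-margin linear SVM
  *classifier* between the patient and control groups at the final
  timepoint;
* the **motor pattern** (PDMP): an ε-insensitive linear SVM *regressor* of
  a behavioral motor score on the same scans.

The pipeline is, in order:

1. **Preprocessing** (`feature_matrix()`): each scan is smoothed with an
   isotropic Gaussian (default FWHM 1.6 mm), restricted to a shared brain
   mask, vectorized in a fixed voxel order, demeaned across voxels and
   scaled to unit Euclidean norm. Demeaning-plus-normalization makes the
   feature vector exactly invariant to global intensity scaling, which
   replaces count normalization between scans.
2. **Subject-space PCA** (`fit_pca()`): with `N` scans of `D ≫ N` voxels,
   the eigendecomposition of the `N × N` Gram matrix of the row-centred data
   is mapped back to voxel space; this is algebraically identical to
   eigendecomposing the `D × D` sample covariance but costs `O(N²D)` instead
   of `O(D³)`. All components with non-negligible variance are kept (no
   component selection; at most `N − 1` exist). Component signs are fixed so
   the largest-magnitude voxel loading is positive.
3. **Linear SVM on component coordinates** (`train_svc()`/`train_svr()`):
   both duals are solved by a shared sequential-minimal-optimization core
   (maximal-violating-pair working-set selection); see *Numerical design
   decisions*. The linear kernel is `k(x, x') = ⟨x/s, x'/s⟩` with kernel
   scale `s`.
4. **Pattern reconstruction** (`metabolic_pattern()`): `p = Aᵀ(w/s)` with
   `A` the component matrix and `w` the SVM weight vector. The raw
   expression score of a scan `x` is `⟨p, x − m⟩` with `m` the training
   mean; the SVM bias is deliberately *not* part of the score (it belongs to
   the decision rule, not to pattern expression). The pattern sign is fixed
   so the patient group has the larger mean training score; a flip is
   recorded in the fitted object.
5. **Z-values** (`zscore()`, `control_reference()`): raw scores are
   standardized against the mean and SD (`N − 1` denominator) of the raw
   scores of *all control scans at all timepoints* projected on the full
   pattern.

# Validation protocol

* **Leave-one-out cross-validation** (`loocv_pattern()`): every fold refits
  the *entire* model on the remaining scans — training mean, PCA basis and
  SVM — so the held-out scan influences nothing. This is the only
  leakage-free reading of LOOCV for a pattern whose transform is estimated
  from the data. Hyperparameters are held fixed across folds (pass the
  values selected on the full training set).
* **Longitudinal projection** (`longitudinal_projection()`): scans at
  earlier timepoints are scored by direct projection of the full week-9
  pattern; at the derivation timepoint itself the held-out LOOCV raw scores
  are substituted when a report is supplied, removing training bias from the
  week-9 group comparison. Groups are compared per timepoint with a
  two-sided Wilcoxon rank-sum test at `α = 0.05`, with no multiple-testing
  correction across timepoints.
* **Wilcoxon test** (`wilcoxon_rank_sum()`): the exact null distribution is
  used for tie-free samples with `n_a + n_b ≤ 25`; otherwise the normal
  approximation with midrank tie handling and continuity correction.
* **Regional summaries** (`region_weighting()`,
  `pattern_region_correlation()`): per atlas region, the positive and
  negative weight mass as a percentage of the whole pattern's absolute mass,
  with a predominance call of `+` (or `-`) when one sign carries at least
  `predominance_ratio` (default 2) times the mass of the other, else `/`;
  and per-region Pearson correlations between two patterns.

# Hyperparameter selection

`grid_search_nested_cv()` evaluates a log-spaced grid
(`C ∈ 10^(−3..3)`, `s ∈ 2^(−3..3)`, default regression tube
`ε = 0.1·sd(targets)`) by inner k-fold cross-validation, pooling held-out
errors (misclassification rate, or mean absolute error for regression).
Folds are stratified for classification, and a fold count exceeding a class
size is an explicit error; `metabolic_pattern()` therefore caps the fold
count at `min(cv_folds, smallest class size)` — on the default phantom
(10 patients, 8 controls) the nominal 10-fold search runs as 8-fold. Ties
are broken toward the smaller `C`, then the smaller scale, then the smaller
`ε`, which prefers the least complex model among equivalent ones and makes
the search fully deterministic for a fixed fold seed.

# The synthetic phantom

Real scanner data are not distributable, so the package generates a
synthetic longitudinal cohort whose ground truth is known
(`build_phantom_atlas()`, `make_ground_truth_pattern()`,
`generate_cohort()`):

* an ellipsoidal brain mask on a 32³ grid (1 mm voxels), parcellated into
  15 regions by nearest-seed (Voronoi) assignment, with rat-brain parcel
  names;
* a planted effect map: ±10 % fractional uptake change in 14 of the 15
  regions (9 positive, 5 negative, one untouched);
* per-scan images
  `baseline_mean · (1 + subject_scale) · (1 + schedule[t] · truth) + noise`,
  smoothed with a 1.35 mm point-spread FWHM; `subject_scale ~ N(0, 0.1)` is
  a global subject effect (removed exactly by normalization),
  `noise ~ N(0, 5)` i.i.d. per voxel;
* the effect schedule `{baseline: 0, w3: 0, w4: 0.6, w6: 0.9, w9: 1}`
  mimics a lesion developing after week 3;
* motor scores: controls `~ N(50, 5)`; patients decline with the schedule
  (`50 − 30·schedule + N(0, 5)`), clipped to `[0, 100]`.

**Realism limits.** The phantom is a calibration instrument, not a
biological simulation: regions are Voronoi cells rather than anatomy, noise
is white rather than reconstruction-correlated, the subject effect is purely
multiplicative, and the planted pattern is piecewise constant. It is
designed so that recovery (cosine similarity with the planted map), regional
sign calls, the longitudinal significance timeline, type-I error under a
zero-amplitude null, and permuted-label LOOCV behaviour can all be checked
quantitatively.

# Numerical design decisions

* **SMO core**: both duals are instances of
  `min ½ zᵀ(yyᵀ∘K)z + pᵀz` s.t. `0 ≤ z ≤ C`, `yᵀz = 0` (classification:
  `p = −1`; regression: the doubled 2n-variable problem). The solver picks
  the maximal violating pair and stops when the KKT violation `m − M` drops
  below `tol` (default `1e-3`; the acceptance tests run at `1e-8`).
* **Bias recovery**: `b` is the mean of the stationarity residuals over the
  free (unbounded) support vectors; when no free vector exists, the midpoint
  of the feasible interval `[M, m]` — a canonical interior value that, in
  the degenerate all-inside-the-tube SVR case, is the midrange of the
  targets.
* **Smoothing at the boundary**: a truncated Gaussian band operator cannot
  simultaneously conserve mass and preserve constants at the volume edge if
  it is renormalized one-sidedly. The package makes the per-axis operator
  *doubly stochastic* by symmetric (Sinkhorn) scaling, so row sums and
  column sums are both 1: constants are preserved and total mass is
  conserved, to iteration tolerance. Interior rows coincide with the plain
  sum-normalized kernel. The kernel radius is `⌈4σ⌉` with
  `σ = FWHM / (2√(2 ln 2))`.
* **Sign conventions**: PCA components have their largest-|loading| voxel
  positive; the final pattern is oriented patient-positive; a decision value
  of exactly 0 classifies as `+1`.
* **Voxel order**: the R-native column-major raster of mask voxels; any
  fixed shared order is valid and this one makes
  `vectorize_image()`/`devectorize()` trivially consistent with R arrays.
* **Determinism**: fold assignment, the phantom and the pipeline are
  deterministic functions of explicit integer seeds; `run_pipeline()`
  records a config hash, the seed and package version in its manifest.

# Problem sizes and test strategy

Module tests run on a 16³/6-region phantom (sub-second); the acceptance
suite (`tests/testthat/test-acceptance.R`) uses the full 32³ default phantom
for recovery/timeline checks and 200 (type-I error) plus 100
(permuted-label) 16³ cohorts for calibration. Independent oracles:
`kernlab::ipop` for the SVM duals (dual-objective agreement within `1e-6`),
full enumeration for the exact Wilcoxon test, direct covariance
eigendecomposition for the PCA, and `e1071::svm` (libsvm) as a secondary
solver cross-check.

# Known limitations

* Linear kernels only — by design, since the pattern must be reconstructed
  as a voxel map.
* No spatial registration or template normalization: scans are assumed
  aligned and masked already (the phantom is, by construction).
* The exact Wilcoxon branch is limited to tie-free samples with
  `n_a + n_b ≤ 25`; larger or tied samples use the corrected normal
  approximation.
* No multiple-comparison correction across timepoints (a deliberate
  protocol choice, documented above).
* The LOOCV report covers the derivation timepoint only; earlier timepoints
  are scored with the full pattern and are therefore not fully out-of-sample
  with respect to pattern estimation (the standard protocol in the field).
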