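---
title: "Cerebrovascular morphometry and risk-factor analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cerebrovascular morphometry and risk-factor analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselmorph)
```

# Overview

`vesselmorph` quantifies regional cerebral artery morphology from binary
vessel segmentations of Time-of-Flight MR angiography and relates the
resulting measurements to cardiovascular risk factors. The pipeline has
two halves:

1. **Image core** — atlas-based cleaning of the segmentation,
   topology-preserving 3-D thinning to obtain centerlines, an exact
   anisotropic Euclidean distance transform to attach a local radius to
   every centerline voxel, and regional summaries: artery density and mean
   centerline radius per flow territory (ACA/MCA/PCA, left and right) and
   mean radius in 12 small main-artery masks, plus intracranial volume.
2. **Statistical layer** — multivariate partial least squares regression
   (PLSR, kernel algorithm) of the 24 regional measurements on 9 risk
   factors with leave-one-out cross-validation, RMSE-based component
   selection and jackknife coefficient inference; MANCOVA with
   Bonferroni-corrected post-hoc tests comparing carriers of the fetal
   posterior cerebral artery (PCA) variant; and sex-specific quantile
   LOESS normative curves over age.

Because no imaging cohort ships with the package, a synthetic module
generates vascular tube phantoms with known geometry and simulated
cohorts with known effect structure, so every stage is testable offline.

# Image core

## Segmentation refinement

Real vessel segmentations contain noise-related over-segmentation. Given
a probabilistic cerebrovascular atlas co-registered to the subject, every
segmented voxel whose occurrence probability is **strictly below 1%**
(configurable) is removed. Voxels at exactly the threshold survive. The
operation never adds voxels, and applying it twice changes nothing; both
properties are tested.

## Centerline extraction

Centerlines are extracted by iterative topology-preserving thinning with
26-connected foreground and 6-connected background. Each iteration visits
six border directions; a border voxel is deleted only when it is a
*simple point* — its deletion leaves exactly one 26-connected foreground
component in its neighbourhood and exactly one 6-connected background
component touching a face neighbour, which preserves local connectivity
and the Euler characteristic — and not a line endpoint (a voxel with a
single foreground neighbour). Deletions within a sub-pass are sequential
with re-checking. The skeleton is a subset of the input foreground and
preserves the number of 26-connected components.

Thinning is combinatorial and deliberately ignores voxel spacing; only
the radii attached afterwards are metric. One degenerate case is worth
knowing about: a tube whose axis lies exactly half-way between voxel
centers in two axes has a *two*-voxel-wide discrete medial locus, and a
directional thinning can retract it axially. This is a property of the
algorithm family, not of this implementation — the standard reference
implementation returns an empty skeleton on the same fixture, while ours
at least preserves the component. The phantom generator used by the
pipeline therefore snaps tube axes to voxel centers; real vasculature,
which is never exactly grid-aligned over long runs, does not exhibit the
degeneracy.

## Radii

The Euclidean distance transform is computed exactly (separable
lower-envelope algorithm on squared distances) with per-axis spacing
weights, giving each foreground voxel its distance in mm to the nearest
*background voxel center*. The radius of a centerline voxel is the
distance-map value there; no half-voxel correction is applied. On tube
phantoms the recovered mean radius is within half a voxel plus one voxel
of the true radius, and the error shrinks with grid resolution —
both are asserted in the tests, with tube caps excluded since end effects
are not part of the measurement's contract.

## Regional measurements

* **Artery density**: 100 × (segmented voxels inside the territory) /
  (territory voxels). The full segmentation enters, not the centerline.
  Voxel-count ratio and volume ratio coincide on a common grid.
* **Territory mean radius**: the average of radii at centerline voxels
  inside the territory only, so a single large artery cannot dominate
  through its cross-sectional bulk.
* **Artery-mask mean radius**: the same, restricted to small masks at
  characteristic locations of the main arteries; no density is computed
  there.
* **Intracranial volume**: voxel count × voxel volume, in cm³.

Proximal/middle/distal sub-territory labels are unioned before
measurement. A region containing no centerline voxel yields a *missing
value* that propagates to the statistics by listwise deletion — never a
silent zero. Voxel indices are 1-based (R convention); the world
coordinate of a voxel center is `(index − 1) × spacing + origin`. All
volumes are assumed co-registered; registration itself is out of scope.

# Statistical layer

## Preprocessing

Predictors are centered and scaled to unit SD; responses are min–max
normalized to [0, 1]. Inside every leave-one-out fold the transforms are
re-estimated from the training rows only — anything else would leak the
held-out subject into the model. Held-out values may map outside [0, 1]
and are not clamped.

## Kernel PLSR

The PLSR is computed with a cross-product ("kernel") algorithm that
works entirely on the p × p and p × q matrices `X'X` and `X'Y`, making
the thousands of leave-one-out refits cheap. Scores are mutually
orthogonal; at `k = rank(X)` the fitted values equal ordinary least
squares, and the betas match an independent NIPALS implementation to
1e-6 — both checked in the tests.

## Component selection

The component count is chosen by leave-one-out cross-validation: the
smallest k whose response-averaged RMSE is within 0.1% (relative,
configurable) of the global minimum. The tolerance implements "ties go
to the smaller k" on continuous CV curves, where exact ties never occur
and differences of ~1e-4 normalized-RMSE units are fold noise, not model
structure.

In simulation studies we use a three-latent-factor design
(`factor_effect_design()`): three correlated Gaussian predictor pairs
(ICV+age, BMI+WHR, systolic BP+heart rate, within-pair r = 0.6) whose
pair-sum directions carry all effects, 0.15 response units per predictor
SD. The pair sums are eigendirections of the predictor covariance, so
exactly three PLS components carry signal and the CV minimum sits at
k = 3. Effects are kept off the discretised predictors (sex, drinks
category) and the zero-clipped smoking duration: their nonlinear
distortion would route genuine signal into a fourth component and
contradict the design's own premise. The residual SD of 0.25 puts the
cross-validated RMSE near 0.10 on the normalized scale, the magnitude
typical for this kind of cohort data.

## Jackknife inference

Coefficient variances come from the n leave-one-out refits with the
Tukey (n−1)/n factor; t = beta/se is referred to a t distribution with
n − 1 degrees of freedom. Because each fold re-estimates its own min–max
and SD transforms, per-fold betas are first mapped back to the raw scale
(response units per predictor unit), where they are comparable; the
reported beta stays on the full-fit preprocessed scale, as in the
conventional table layout. Significance is marked at p < 0.05 and
p < 0.01.

Under a null simulation the test holds its nominal 5% size at
`k = rank(X)`, where the PLS estimator is linear. At smaller k the PLS
shrinkage makes the jackknife *conservative* (observed null rates
0.01–0.03) — it never becomes anti-conservative, which the tests assert
separately. This mirrors the known behaviour of jackknife inference for
PLS coefficients.

## MANCOVA and adjusted means

Group differences between variant carriers and non-carriers are tested
with MANCOVA: Wilks' lambda with Rao's F approximation, age and sex as
covariates, the group factor entered last. Post-hoc, each measurement
gets a univariate ANCOVA with the same covariates; raw p-values are
compared against 0.05/24 ≈ 0.002 (the Bonferroni multiplier stays fixed
at 24 — the number of regional measurements — regardless of how many
responses enter a particular call). With a single response the
multivariate test reduces exactly to the ANCOVA F test. Adjusted group
means are least-squares means: fitted values at the covariate sample
means, with standard errors from the coefficient covariance.

The end-to-end pipeline feeds the MANCOVA all subjects but excludes
variant carriers from the PLSR fits. Phantom-derived measurements can be
nearly collinear across regions, so the pipeline screens the MANCOVA
responses down to a maximal well-conditioned subset (QR with pivoting at
a 1e-6 relative tolerance) and records what was dropped.

## Quantile LOESS

Normative curves are local-linear quantile fits: at each of 100 grid
points over the observed age range, the span-nearest 75% of points (both
configurable) are weighted by the tricube kernel and the 25th/50th/75th
conditional quantiles are estimated by minimising the weighted pinball
loss. The minimisation uses a lightly smoothed check function (smoothing
~1e-6 of the response scale) with analytic gradient, warm-started from
the weighted least-squares fit; this leaves the median exact and
perturbs the outer quantiles by an amount far below the sampling noise.
Windows with fewer than 5 points yield missing values. Monotonicity
across quantiles is enforced by re-sorting fitted values per grid point,
so curves never cross.

# Synthetic data: what it does and does not emulate

`make_tube_phantom()` rasterizes capsule segments by the voxel-center
rule (a voxel is foreground iff its center is within the radius of the
segment axis, inclusive), records the ground-truth centerline and radius,
and builds a toy probabilistic atlas (0.95 on and near the vessel, 0.001
elsewhere), six flow-territory labels, twelve 3³ artery masks along the
vessels, and an ellipsoidal intracranial mask. Requested noise voxels are
placed only where the atlas is below 1% and 26-disconnected from
everything, so the refinement rule provably removes exactly them.

`make_cohort()` draws 9 predictors from a latent multivariate normal
with configurable correlation; sex (M = 1, F = 2) and the drinks-per-day
category (ordinal 0–5) are discretised by thresholding their latent
normals at the reference marginal frequencies, smoking duration is
clipped at zero, and the continuous marginals match the reference cohort
means and SDs (e.g. age 50.2 ± 13.8 years, ICV 1402 ± 136 cm³).
Responses are `Y = mu + scale(X) B + E` with per-response Gaussian noise,
generated from the *observed* (discretised) predictors so ordinary least
squares recovers B exactly when noise is zero. Variant carriers (default
12.5%) receive a shift on the basilar (−0.087 mm) and right internal
carotid (+0.088 mm) radii, the pattern reported for the fetal-PCA
variant.

What the synthetic data does **not** emulate: MRA intensities and
partial-volume effects, curved or branching vasculature, registration
error, spatially varying atlas quality, and any nonlinearity in the
risk-factor effects (e.g. J-shaped alcohol effects). Passing tests
therefore demonstrate correctness of the measurement and inference
machinery under the stated generative model, not robustness to every
property of real TOF MRA.

# Numerical choices and problem sizes

* Atlas threshold 0.01 (fraction), strict-below removal.
* EDT is exact; the test oracle is an O(n²) brute-force search on masks
  up to 16³.
* CV tie tolerance 0.001 (relative); LOESS span 0.75, 100 grid points,
  smoothing 1e-6 × response scale; QR screening tolerance 1e-6.
* Simulation sizes used by the test-suite and the acceptance script:
  cohorts of n = 1500 for component selection (10–20 seeds), n = 100 ×
  200–500 replicates for null calibration, n = 400 × 10–20 seeds for the
  MANCOVA recovery, n = 2000 for LOESS coverage, 100–200 random masks
  for the EDT oracle. These sizes give stable Monte-Carlo estimates
  while keeping a full run in the minutes range on one core.

# Known limitations

* Radii are lumen radii by construction of TOF MRA; wall thickening or
  plaque is invisible to the measurements.
* The EDT measures to background voxel *centers*; radii carry a
  half-voxel convention that the recovery tolerances account for.
* Thinning can shorten vessels at their free ends by roughly one radius
  (cap erosion); regional means are robust to this, but measurements in
  masks placed at vessel tips are not.
* The jackknife test is conservative below full rank (see above).
* The LOESS quantiles are pointwise estimates; no simultaneous band is
  provided.
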