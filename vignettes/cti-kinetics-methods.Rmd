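---
title: "CTI contour kinetics: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CTI contour kinetics: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctikin)
```

## The measurement problem

The cavotricuspid isthmus (CTI) — the band of right-atrial tissue between
the Eustachian valve / inferior vena cava (EV/IVC) and the tricuspid-valve
(TV) hinge — is the ablation target in typical atrial flutter, yet its
motion during the cardiac cycle is poorly characterized. `ctikin` analyses
CTI wall motion from contour-point cine series: for each patient, an
ordered set of P contour points (default 49: a critical point near the IVC
with 24 points on each side) tracked over F cine frames (default 25,
covering one cardiac cycle), in a 2-D coordinate system with x the
anterior–posterior (AP) axis and y the caudo-cranial (CC) axis, in
millimetres.

From these tracks the package computes:

* **Curvilinear CTI length** — the cumulated distance between consecutive
  CTI points; measured at RA systole and RA diastole.
* **Linear CTI length** — the straight IVC-to-TV-hinge distance, and
  **pouch depth** — the maximum perpendicular distance of CTI points from
  that straight line (both reported on the diastolic frame).
* **Elongation** `E = L_dia - L_sys` and **normalized elongation**
  `NE = E / L_sys`, a dimensionless strain-like compliance measure: a CTI
  that doubles its length between systole and diastole has NE = 1.
* **Segmental kinetics** — the CTI is divided into five contiguous
  segments (1 near the EV, 5 near the TV); per point, trajectory
  differentials `Δ_n = pos(t_n) - pos(t_{n-1})`, instantaneous velocities
  `Δ_n / dt`, and displacements; per segment, means of per-point maxima.
* **Cohort statistics** (Spearman, point-biserial, two-sample KS),
  **NE-based k-means clustering** with elbow selection, and two
  supervised models (ridge-logistic classification of recent electrical
  cardioversion (EC) from differential vectors; Lasso prediction of CTI
  length).

## Conventions the data model fixes

Several quantities are conventions rather than measurements; they are
deliberately explicit and pluggable:

* **CTI index range.** Which of the 49 contour points constitute the CTI
  is per-patient metadata (`cti_range`, half-open and 0-based as on
  disk). The default runs from the IVC midpoint index `(P-1)/2` to the
  contour end on the TV side. Nothing in the exported point tables
  identifies the anatomical landmarks, so this mapping is a modelling
  choice that users with landmark positions should override.
* **Phase frames.** RA systole is the frame minimizing the curvilinear
  CTI length and RA diastole the frame maximizing it, ties broken to the
  earliest frame. A per-frame criterion vector can be supplied to
  `select_phase_frames()` to plug in an alternative (e.g. RA-area
  extremes).
* **Displacement reference.** Cines are cyclic, so the net
  (final-minus-initial) displacement is near zero and uninformative;
  segmental summaries therefore use the per-point maximum displacement
  relative to frame 1, the only universally defined anchor. Both net and
  maximum values are computed and kept.
* **Segment partition.** Five contiguous runs of near-equal size; when
  the CTI point count is not divisible by five, the larger runs are
  placed TV-side, where motion is larger and finer sampling is the
  conservative choice.
* **Median split.** Even cohorts split at the midpoint of the two central
  order statistics; the low group is strictly below the threshold.

## The synthetic generator

Patient contour data of this kind cannot be shared, so the package ships
a generator (`synth_config()`, `generate_cine()`, `generate_cohort()`)
that emulates the cohort's statistical structure with known ground truth.
The motion model is phenomenological — the goal is testability of every
pipeline stage, not tissue mechanics.

**Base geometry.** The CTI half of the contour is a gently inclined chord
with a parabolic pouch (depth drawn at 3.2 ± 2.0 mm), scaled so the
25-point polyline length equals the drawn diastolic length (40 ± 11.4
mm); the other half of the RA wall is a smooth static arc. The IVC
critical point sits at the junction and anchors all motion.

**Two motion mechanisms**, both following one shared raised-cosine
systolic pulse `φ(t)` (zero outside a systolic window, default frames
9–17 of 25, peaking at frame 13, returning to baseline so the cine is
cyclic):

1. *Contraction*: the CTI sub-contour scales uniformly about the IVC
   anchor by `1 - φ(t)·(1 - s)`, with `s` the per-patient contraction
   ratio. Because a uniform scaling multiplies every chord exactly, the
   curvilinear length ratio at the pulse peak is exactly `s` and the
   ground-truth NE is exactly `1/s - 1` — the parameter-recovery tests
   rely on this identity holding to machine precision at zero noise.
   (Tangential sliding of points along a curved contour, the obvious
   alternative, cannot deliver exact length ratios on sampled
   polylines.)
2. *Segmental displacement*: an additive per-point displacement field
   whose AP/CC amplitudes are linear interpolations through the five
   segment centres of the configured per-segment amplitudes (defaults:
   AP 8.1 → 17.2 mm, CC 1.6 → 4.5 mm from EV to TV, the cohort segmental
   means, with intermediate segments interpolated linearly between the
   reported endpoints). For a linear amplitude gradient the segment mean
   of the interpolated point amplitudes equals the segment parameter
   exactly, so at zero noise the measured per-segment maximum
   displacement reproduces the configured amplitudes exactly.

**The two mechanisms describe the same physical motion seen through
different summaries**, so they are not superimposed blindly: the reported
segmental displacements are *totals* that already include contraction
motion (at the TV end the contraction alone displaces points by up to
~15 mm AP). Runs that calibrate displacements therefore disable the
contraction (`synth_config_displacement()`, contraction ratio 1) so the
amplitude parameters are not double-counted, and runs that probe NE use
the pure-contraction regime (`synth_config_contraction()`, additive field
off), where the NE ground truth is exact. The full default configuration
keeps both mechanisms on; its realized NE and displacements are then
joint outcomes and the ground-truth table records the generating
parameters.

`synth_config_displacement()` also neutralizes the EC attenuation: the
calibration amplitudes are cohort-wide averages that already include EC
patients, so attenuating individual patients would count the EC effect
twice.

**Clinical linkage.** Covariates are drawn at the cohort prevalences
(smokers 53%, dyslipidaemia 53%, BMI 29 ± 4 kg/m², age 66 ± 10 y, EC in
46.9%) and act multiplicatively on the contraction depth `1 - s`: smoker
× 0.70, dyslipidaemia × 0.72, BMI × (1 − 0.045·(BMI − 29)), EC ×
`ec_attenuation` (default 0.5, the "stunning" effect, which also scales
the displacement amplitudes and hence all differentials and velocities).
These effect sizes were chosen once so that the downstream point-biserial
correlations of NE with each covariate reproduce the magnitudes reported
for the clinical cohort (≈ −0.2 to −0.5, all negative); at n = 32 this
makes each sign stable in well over 90% of simulated cohorts.
Independence of the covariates from one another is assumed — the true
covariance structure of the cohort is unknown. When a contraction ratio
is passed explicitly it is treated as a probe and the covariate/EC
modulation is skipped.

**Noise** is i.i.d. Gaussian on every coordinate of every frame (default
sd 0.5 mm). Note one estimator-level consequence: the per-point maximum
displacement is a maximum over frames, so noise biases it upward by an
amount that grows as the amplitude shrinks toward the noise floor:
at noise sd 0.5 mm the bias is a few tenths of a millimetre for
amplitudes near 2 mm and negligible from about 8 mm up. The windowed
pulse keeps this selection bias small by concentrating the peak in few
frames.

**What the generator does not emulate**: between-patient amplitude
heterogeneity is off by default (`amplitude_cv = 0`; the real cohort's
segmental sds are of the same order as the means), there is no
within-cycle variability beyond one systolic pulse, no contour-tracking
artefacts, and no covariate correlations. Passing tests therefore
demonstrate correct *recovery of the generating process*, not clinical
validity on real cines.

## Clustering: k selection and the outlier path

Patients are clustered on scalar NE (`cluster_ne()`), the discriminant
the cohort analysis used; a 2-D (systolic, diastolic) feature view is a
presentation device, not the clustering space. `kmeans_1d()` runs Lloyd
iterations with random restarts (deterministic given the seed) and is
tested against the exhaustive contiguous-partition optimum, which in one
dimension contains the global optimum.

The elbow criterion is formalized as the k (searched over
`2..k_max - 1`) maximizing the second difference of **log** WCSS. The
absolute-scale second difference — the textbook formalization — is
dominated by the largest-scale drops of the curve: on cohorts with three
NE groups plus one extreme outlier it always elects k = 2 or 3 (the drop
from "everything in one cluster" to "outlier split off" dwarfs later
curvature), and never finds the four-cluster structure that visual elbow
reading identifies. The log-scale second difference measures *relative*
curvature — where the marginal-improvement ratio collapses — and selects
k = 4 on ~77% of calibrated cohorts (k = 3 on ~20%, merging the two
lower groups while still isolating the outlier). No algorithmic rule
reproduces visual elbow reading perfectly; `scale = "raw"` and
`k_override` expose the alternatives.

Clusters of size 1 are flagged as outliers and removed *without*
re-clustering — mirroring a workflow in which an extreme patient
(NE 3.38, versus a cohort mean of ~0.74) is excluded from downstream
analysis after inspection. Remaining clusters are relabelled low /
intermediate / high by ascending centroid.

## Statistics

Spearman and point-biserial correlations are implemented from their
defining formulas (rank-then-Pearson with mean ranks; the
point-biserial/Pearson-dummy identity is asserted in tests) with
p-values from the t approximation on n − 2 degrees of freedom; the
two-sample KS test uses the asymptotic p-value only (exact small-sample
p-values are not computed — at n = 30 the asymptotic test's measured
type-I error is ≈ 3.3% at nominal 5%, slightly conservative). EC versus
non-EC comparisons pool raw point × transition values by default
(patient-level means are an option), because the distributional claim
being tested concerns the raw velocity and differential distributions.
Ordinal covariates are binarized at declared cuts (NYHA ≥ 2,
BMI ≥ 30 kg/m²) for the point-biserial screen; no multiple-testing
correction is applied, matching the descriptive intent.

## Prediction models

**Lasso length model.** `lasso_cd()` minimizes
`(1/2n)·Σ(yᵢ − ŷᵢ)² + α·Σ|βⱼ|` by cyclic coordinate descent on
standardized features (tolerance 1e-6 on the coefficients), with
coefficients reported on both scales; every returned solution is
KKT-checked in the tests and cross-checked against an independent
solver. `alpha = "cv"` minimizes mean 10-fold CV squared error (MAE by
flag) over a log-spaced grid; held-out MAE and R² come from out-of-fold
predictions. The feature sets are the geometric trio
(opposite-phase curvilinear length, pouch depth, linear length) with or
without the clinical trio (EC, smoker, dyslipidaemia), and
`ablation_report()` compares the two fits.

**EC classifier.** One observation per (patient, segment): the
concatenated per-transition differentials of the segment's points on the
chosen axis (`plane` = per-transition norms). The train/test split is
grouped by patient (default 70/30) so no patient contributes to both
sides. Ridge-logistic regression (glmnet) with `standardize = FALSE`:
the features share one unit (mm) and standardization inflates
transitions that carry only noise. One structural caveat: all segments
share feature columns, so a hypokinetic patient's TV-side segments can
resemble an attenuated (EC) patient's — this cross-segment confound
bounds per-segment-observation accuracy well below 1 even when the EC
effect is strong. At the default attenuation 0.5 the mean held-out
accuracy on simulated cohorts clears 0.75; at attenuation 1.0 it is
statistically indistinguishable from chance.

## Problem sizes and numerical choices

The verification suites run at the scales that make their Monte Carlo
error small relative to what they assert: 200-patient cohorts for
segmental calibration (mean standard errors ≪ the 0.3–0.5 mm
tolerances), 60 calibrated cohorts for clustering recovery, 20,000 null
draws for type-I error (estimator sd 0.13% against a [3%, 7%] band), and
15–25 cohorts per condition for classifier detection. Degenerate inputs
error early with typed conditions (`ctikin_validation_error`,
`ctikin_domain_error`, …): empty point sets, coincident pouch endpoints,
zero systolic length (NE undefined), constant inputs to correlations,
k exceeding the number of distinct values, single-class training sets.
Ties in phase-frame selection and in ranks follow the stated
conventions; the WCSS curve is clamped at 1e-12 before taking logs.

## Known limitations

* The CTI landmark-to-index mapping and the phase-frame criterion are
  conventions; on real exports they should be set from the imaging
  context.
* The generator's displacement field is piecewise-linear in arc position
  and shares one cardiac phase across segments; real CTIs show richer
  phase lags and the generator's defaults suppress between-patient
  amplitude scatter.
* Clustering k selection is heuristic; for cohorts unlike the calibrated
  structure (e.g. no outlier, or > 4 groups) the manual override is the
  honest instrument.
* The asymptotic KS p-value is conservative for small pooled samples.
* The prediction models are descriptive of the synthetic cohort
  structure; their headline numbers on real patient data depend on an
  observation-unit convention the exported tables do not pin down.
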