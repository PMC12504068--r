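# ctikin — cavotricuspid isthmus contour kinetics

`ctikin` analyses the motion of the cavotricuspid isthmus (CTI) — the
right-atrial tissue band between the Eustachian valve / inferior vena cava
(EV/IVC) and the tricuspid-valve (TV) hinge, the ablation target in typical
atrial flutter — from contour-point cine series as exported by cardiac-MR
contouring software: per patient, an ordered set of P contour points
(default 49) tracked over F cine frames (default 25) in a 2-D
anterior–posterior (x) / caudo-cranial (y) coordinate system, in mm.

It is written for electrophysiology and imaging groups who have such
exports and want reproducible CTI kinetics, and it ships a synthetic
cohort generator with known ground truth so the entire pipeline is
testable without patient data.

## What it computes

With `L_sys` and `L_dia` the curvilinear CTI lengths (cumulated
consecutive-point distances) on the systolic and diastolic frames:

* elongation `E = L_dia − L_sys` and **normalized elongation**
  `NE = E / L_sys`, a dimensionless strain-like measure of CTI
  compliance;
* linear CTI length (straight IVC–TV distance) and pouch depth (maximum
  perpendicular distance of CTI points from that line), on the diastolic
  frame;
* five-segment wall-motion analysis (segment 1 at the EV, 5 at the TV):
  per-point trajectory differentials `Δ_n = pos(t_n) − pos(t_{n−1})`,
  instantaneous velocities `Δ_n / dt`, and per-segment means of per-point
  maximum displacements per axis;
* cohort statistics (Spearman, point-biserial, two-sample
  Kolmogorov–Smirnov, including EC vs non-EC distribution comparisons of
  velocities and differentials);
* NE-based k-means patient clustering with elbow selection and
  singleton-outlier removal;
* prediction models: ridge-logistic classification of recent electrical
  cardioversion (EC) from trajectory-differential vectors, and Lasso
  (coordinate descent, 10-fold CV alpha selection) prediction of CTI
  systolic/diastolic length with and without clinical features.

## Worked example

```r
library(ctikin)

cfg    <- synth_config(n_patients = 32, seed = 7)   # study-calibrated defaults
coh    <- generate_cohort(cfg)                      # cines + clinical + truth
geom   <- compute_geometry_table(coh$cines)
kin    <- segment_kinetics_table(coh$cines)
cohort <- build_cohort_table(geom, kin$segments, coh$clinical)

head(cohort, 3)[, c(1, 4, 5, 9, 15)]
#>   patient_id curvilinear_systolic_mm curvilinear_diastolic_mm    ne ec_within_12h
#> 1 P001                          20.3                     34.4 0.697 FALSE
#> 2 P002                          27.8                     42.2 0.517 TRUE
#> 3 P003                          32.7                     47.3 0.448 FALSE

cluster_ne(cohort, k_max = 8, seed = 7)
#> <cluster_result> k = 3, 3 final groups, 0 outlier(s) removed
#> centroids:
#>          low intermediate         high
#>        0.334        0.609        1.004

scr <- cohort_association_screen(cohort)
scr[scr$comparison %in% c("ec_within_12h_vs_ne", "smoker_vs_ne"), c(1, 3, 4)]
#>            comparison statistic  p_value
#> 1 ec_within_12h_vs_ne    -0.683 1.67e-05
#> 2        smoker_vs_ne    -0.620 1.53e-04

fit_lasso_length(cohort, "systolic", alpha = 0.17, seed = 7)
#> <lasso_fit> target systolic, alpha 0.17, MAE 2.61 mm, R2 0.856 (n = 32)
#> curvilinear_diastolic_mm           pouch_depth_mm      linear_diastolic_mm
#>                    0.709                    0.041                    0.000
#>            ec_within_12h                   smoker            dyslipidaemia
#>                    5.674                    4.011                    1.166
```

Patients cluster into low / intermediate / high NE groups; recent EC and
smoking correlate negatively with NE (the generator links covariates to
contraction depth, emulating post-cardioversion "stunning"); and EC /
smoker status carry positive Lasso coefficients for systolic length
(stunned CTIs stay long in systole). A full pipeline run
(`run_pipeline()`, or `inst/scripts/ctikin.R` from a shell) writes
geometry, kinetics, statistics, cluster and fit reports to an output
directory.

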