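Package: ctikin
Title: Cavotricuspid Isthmus Contour Kinetics from Cardiac Cine Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of cavotricuspid isthmus (CTI) wall motion from
    right-atrial contour-point cine series: curvilinear and linear CTI
    lengths, pouch depth, elongation and normalized elongation (NE, a
    strain-like compliance metric), five-segment wall-motion analysis with
    trajectory differentials and instantaneous velocities, NE-based
    k-means patient clustering with elbow selection and singleton-outlier
    removal, cohort statistics (Spearman, point-biserial,
    Kolmogorov-Smirnov), and supervised models (L2 logistic regression of
    cardioversion status from trajectory-differential vectors; Lasso
    prediction of CTI length). Includes a synthetic contour-cine and
    covariate generator with known ground truth so every pipeline stage
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    yaml,
    withr,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
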