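test_that("lasso at alpha 0 reproduces least squares (lm oracle)", {
  x <- withr::with_seed(1, matrix(rnorm(200), 50, 4,
                                  dimnames = list(NULL, paste0("f", 1:4))))
  y <- 2 * x[, 1] + 1
  fit <- lasso_cd(x, y, 0)
  expect_equal(unname(fit$coef_raw), c(2, 0, 0, 0), tolerance = 1e-6)
  expect_equal(fit$intercept, 1, tolerance = 1e-6)
  # general response: compare against lm
  y2 <- withr::with_seed(2, 1.5 * x[, 2] - 0.7 * x[, 4] + rnorm(50, 0, 0.3))
  ls <- stats::lm(y2 ~ x)
  fit2 <- lasso_cd(x, y2, 0)
  expect_equal(unname(fit2$coef_raw), unname(stats::coef(ls)[-1]),
               tolerance = 1e-5)
  expect_equal(fit2$intercept, unname(stats::coef(ls)[1]), tolerance = 1e-5)
})

test_that("large alpha shrinks everything to the mean predictor", {
  x <- withr::with_seed(3, matrix(rnorm(120), 30, 4))
  y <- withr::with_seed(4, rnorm(30, 5, 2))
  fit <- lasso_cd(x, y, 1e4)
  expect_equal(unname(fit$coef_raw), rep(0, 4))
  expect_equal(predict_lasso(fit, x), rep(mean(y), 30))
})

test_that("returned solutions satisfy the KKT conditions of the objective", {
  for (seed in 1:5) {
    x <- withr::with_seed(seed, matrix(rnorm(40 * 6), 40, 6))
    y <- withr::with_seed(seed + 100,
                          x %*% c(1.5, -2, 0, 0, 0.5, 0) + rnorm(40, 0, 0.5))
    for (alpha in c(0.01, 0.1, 0.5)) {
      fit <- lasso_cd(x, as.vector(y), alpha)
      expect_lt(lasso_kkt_residual(x, as.vector(y), fit), 1e-6)
    }
  }
})

test_that("sparsity is monotone in alpha and glmnet agrees at matched alpha", {
  x <- withr::with_seed(6, matrix(rnorm(60 * 5), 60, 5))
  y <- withr::with_seed(7, as.vector(x %*% c(3, -1, 0.5, 0, 0) + rnorm(60, 0, 0.4)))
  grid <- c(0.01, 0.05, 0.1, 0.3, 0.6, 1, 2)
  nz <- vapply(grid, function(a) sum(lasso_cd(x, y, a)$coef_std != 0), integer(1))
  expect_true(all(diff(nz) <= 0))
  # independent cross-check: glmnet solves the same objective
  for (a in c(0.05, 0.3)) {
    mine <- lasso_cd(x, y, a, tol = 1e-9)
    gn <- glmnet::glmnet(x, y, alpha = 1, lambda = a, standardize = TRUE,
                         thresh = 1e-12, intercept = TRUE)
    expect_equal(unname(mine$coef_raw), as.vector(stats::coef(gn))[-1],
                 tolerance = 1e-4)
    expect_equal(mine$intercept, as.vector(stats::coef(gn))[1], tolerance = 1e-4)
  }
})

test_that("EC design builds one observation per patient-segment", {
  cfg <- synth_config(n_patients = 2, seed = 51)
  coh <- generate_cohort(cfg)
  kin <- segment_kinetics_table(coh$cines)
  des <- build_ec_design(kin$per_point, coh$clinical, axis = "x")
  expect_equal(nrow(des$features), 2L * 5L)
  expect_equal(ncol(des$features), 5L * 24L)   # 5 points x 24 transitions
  expect_equal(nrow(des$obs), length(des$labels))
  # plane features are norms, hence nonnegative
  des_p <- build_ec_design(kin$per_point, coh$clinical, axis = "plane")
  expect_true(all(des_p$features >= 0))
  # zero-motion patient gives an all-zero feature vector
  flat <- cine_from_frames(rep(list(cbind(0:24, rep(0, 25))), 4),
                           patient_id = "Z", cti_range = c(15L, 25L))
  kin_z <- segment_kinetics_table(list(Z = flat), dt = 0.04)
  des_z <- build_ec_design(kin_z$per_point, toy_clinical("Z"), axis = "x")
  expect_true(all(des_z$features == 0))
})

test_that("logistic EC classifier separates a separable rule and is calibrated at chance", {
  # separable toy: label by the sign of the first feature
  x <- withr::with_seed(8, matrix(rnorm(400), 100, 4))
  lab <- x[, 1] > 0
  fit <- fit_ec_classifier(x, lab, seed = 2, lambda = 1e-4)
  expect_gt(fit$accuracy, 0.95)
  expect_equal(sum(fit$confusion), fit$n_test)
  expect_equal(unname(fit$accuracy),
               unname((fit$confusion[["tn"]] + fit$confusion[["tp"]]) / fit$n_test))
  # shuffled labels: accuracy near chance on average (20 seeds)
  accs <- vapply(1:20, function(s) {
    lab_s <- withr::with_seed(300 + s, sample(lab))
    fit_ec_classifier(x, lab_s, seed = s, lambda = 0.1)$accuracy
  }, numeric(1))
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
  # single-class training data errors
  expect_error(fit_ec_classifier(x, rep(TRUE, 100), seed = 1),
               class = "ctikin_domain_error")
})

test_that("lasso length model fits cohorts and reports ablation deltas", {
  cfg <- synth_config(n_patients = 26, seed = 61)
  coh <- generate_cohort(cfg)
  geom <- compute_geometry_table(coh$cines)
  kin <- segment_kinetics_table(coh$cines)
  cohort <- build_cohort_table(geom, kin$segments, coh$clinical)
  fit <- fit_lasso_length(cohort, "systolic", alpha = 0.17, seed = 5)
  expect_s3_class(fit, "lasso_fit")
  expect_equal(fit$alpha, 0.17)
  expect_gte(fit$mae_mm, 0)
  expect_length(fit$coefficients, 6L)
  fit_no <- fit_lasso_length(cohort, "systolic", alpha = 0.17, seed = 5,
                             with_clinical = FALSE)
  expect_length(fit_no$coefficients, 3L)
  rep_same <- ablation_report(fit, fit)
  expect_equal(rep_same$delta_mae_mm, 0)
  expect_equal(rep_same$delta_r2, 0)
  rep2 <- ablation_report(fit, fit_no)
  expect_equal(rep2$target, "systolic")
  fit_d <- fit_lasso_length(cohort, "diastolic", alpha = "cv", seed = 5)
  expect_true(is.numeric(fit_d$alpha) && fit_d$alpha > 0)
  expect_error(ablation_report(fit, fit_d), class = "ctikin_domain_error")
})
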