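#' Lasso by coordinate descent
#'
#' Solves `min (1/(2n)) * sum((y - b0 - X b)^2) + alpha * sum(|b|)` with
#' cyclic coordinate descent and soft-thresholding. Features are
#' standardized to zero mean and unit (population) variance before the
#' penalty is applied; coefficients are reported on both the standardized
#' and the raw scale. Iterations stop when the largest coefficient change
#' is below `tol`.
#'
#' @param x Numeric feature matrix (n x p).
#' @param y Numeric response.
#' @param alpha Penalty weight `>= 0`.
#' @param tol Convergence tolerance on the coefficients.
#' @param max_iter Maximum sweeps.
#' @return List with `coef_std`, `coef_raw`, `intercept` (raw scale),
#'   `alpha`, and the standardization (`center`, `scale`, `y_mean`).
#' @export
lasso_cd <- function(x, y, alpha, tol = 1e-6, max_iter = 100000L) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n != length(y)) abort_domain("nrow(x) must match length(y)")
  if (alpha < 0) abort_domain("alpha must be >= 0")
  if (stats::sd(y) == 0) abort_domain("constant response: lasso fit degenerate")
  center <- colMeans(x)
  scale_ <- sqrt(colMeans(x^2) - center^2)
  if (any(scale_ == 0)) abort_domain("constant feature column")
  xs <- sweep(sweep(x, 2L, center), 2L, scale_, "/")
  y_mean <- mean(y)
  yc <- y - y_mean
  beta <- numeric(p)
  resid <- yc
  for (iter in seq_len(max_iter)) {
    delta_max <- 0
    for (j in seq_len(p)) {
      bj_old <- beta[j]
      rho <- mean(xs[, j] * (resid + xs[, j] * bj_old))
      bj <- sign(rho) * max(abs(rho) - alpha, 0)   # col variance is 1
      if (bj != bj_old) {
        resid <- resid - xs[, j] * (bj - bj_old)
        delta_max <- max(delta_max, abs(bj - bj_old))
      }
      beta[j] <- bj
    }
    if (delta_max < tol) break
  }
  coef_raw <- beta / scale_
  list(coef_std = stats::setNames(beta, colnames(x)),
       coef_raw = stats::setNames(coef_raw, colnames(x)),
       intercept = y_mean - sum(coef_raw * center),
       alpha = alpha, center = center, scale = scale_, y_mean = y_mean)
}

#' @rdname lasso_cd
#' @param fit A fit returned by `lasso_cd()` on the same `x`, `y`.
#' @return `lasso_kkt_residual()`: the largest violation of the
#'   Karush-Kuhn-Tucker conditions of the stated objective (0 at the
#'   exact solution): for active coefficients
#'   `|grad_j + alpha * sign(b_j)|`, for zero coefficients
#'   `max(|grad_j| - alpha, 0)`, with `grad_j` the smooth-part gradient
#'   on the standardized scale.
#' @export
lasso_kkt_residual <- function(x, y, fit) {
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2L, fit$center), 2L, fit$scale, "/")
  resid <- (y - fit$y_mean) - xs %*% fit$coef_std
  grad <- -colMeans(xs * as.vector(resid))
  active <- fit$coef_std != 0
  viol_active <- if (any(active)) {
    max(abs(grad[active] + fit$alpha * sign(fit$coef_std[active])))
  } else 0
  viol_zero <- if (any(!active)) max(pmax(abs(grad[!active]) - fit$alpha, 0)) else 0
  max(viol_active, viol_zero)
}

#' Predict from a `lasso_cd()` fit
#' @param fit Fit from [lasso_cd()].
#' @param x New feature matrix.
#' @return Numeric predictions.
#' @export
predict_lasso <- function(fit, x) {
  as.vector(as.matrix(x) %*% fit$coef_raw) + fit$intercept
}

cv_folds_assign <- function(n, folds, seed) {
  withr::with_seed(seed, sample(rep_len(seq_len(folds), n)))
}

# alpha grid and k-fold CV error curve for lasso_cd
cv_lasso_alpha <- function(x, y, folds = 10L, seed = 1L,
                           criterion = c("mse", "mae"), n_alpha = 50L) {
  criterion <- match.arg(criterion)
  x <- as.matrix(x)
  center <- colMeans(x)
  scale_ <- sqrt(colMeans(x^2) - center^2)
  xs <- sweep(sweep(x, 2L, center), 2L, scale_, "/")
  alpha_max <- max(abs(crossprod(xs, y - mean(y)))) / nrow(x)
  alphas <- exp(seq(log(alpha_max), log(alpha_max * 1e-3), length.out = n_alpha))
  fold_id <- cv_folds_assign(nrow(x), folds, seed)
  err <- sapply(alphas, function(a) {
    pred <- numeric(nrow(x))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- lasso_cd(x[tr, , drop = FALSE], y[tr], a)
      pred[!tr] <- predict_lasso(fit, x[!tr, , drop = FALSE])
    }
    if (criterion == "mse") mean((y - pred)^2) else mean(abs(y - pred))
  })
  list(alphas = alphas, error = err, alpha_best = alphas[which.min(err)])
}

#' Lasso prediction of CTI length
#'
#' Fits the CTI-length prediction model: the target is the curvilinear
#' systolic (or diastolic) CTI length; geometric features are the
#' opposite-phase curvilinear length, the pouch depth and the linear CTI
#' length, optionally joined by the clinical features (EC within 12 h,
#' smoker status, dyslipidaemia status). `alpha = "cv"` selects the
#' penalty by minimal mean cross-validated squared error (MAE criterion
#' by flag) over a log-spaced grid; a numeric `alpha` is used as is.
#' Held-out performance (MAE, R2) is computed from out-of-fold
#' predictions at the chosen alpha.
#'
#' @param cohort Cohort tibble (see [build_cohort_table()]).
#' @param target `"systolic"` or `"diastolic"`.
#' @param alpha Numeric penalty or `"cv"`.
#' @param folds CV folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @param with_clinical Include the clinical features?
#' @param cv_criterion `"mse"` (default) or `"mae"`.
#' @return List of class `lasso_fit`: `target`, `features`, `alpha`,
#'   `coefficients` (raw scale), `coef_std`, `intercept`, `cv_folds`,
#'   `mae_mm`, `r2`, `with_clinical`, and the underlying `fit`.
#' @export
fit_lasso_length <- function(cohort, target = c("systolic", "diastolic"),
                             alpha = "cv", folds = 10L, seed = 1L,
                             with_clinical = TRUE,
                             cv_criterion = c("mse", "mae")) {
  target <- match.arg(target)
  cv_criterion <- match.arg(cv_criterion)
  y_col <- if (target == "systolic") "curvilinear_systolic_mm" else "curvilinear_diastolic_mm"
  other <- if (target == "systolic") "curvilinear_diastolic_mm" else "curvilinear_systolic_mm"
  feats <- c(other, "pouch_depth_mm", "linear_diastolic_mm")
  if (with_clinical) feats <- c(feats, "ec_within_12h", "smoker", "dyslipidaemia")
  dat <- cohort[stats::complete.cases(cohort[, c(y_col, feats)]), , drop = FALSE]
  if (nrow(dat) < folds) abort_domain("fewer complete rows than CV folds")
  x <- as.matrix(dplyr::mutate(dat[, feats], dplyr::across(dplyr::everything(), as.numeric)))
  y <- dat[[y_col]]
  if (identical(alpha, "cv")) {
    alpha <- cv_lasso_alpha(x, y, folds = folds, seed = seed,
                            criterion = cv_criterion)$alpha_best
  }
  fit <- lasso_cd(x, y, alpha)
  fold_id <- cv_folds_assign(nrow(x), folds, seed)
  oof <- numeric(nrow(x))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    oof[!tr] <- predict_lasso(lasso_cd(x[tr, , drop = FALSE], y[tr], alpha),
                              x[!tr, , drop = FALSE])
  }
  structure(list(
    target = target, features = feats, alpha = alpha,
    coefficients = fit$coef_raw, coef_std = fit$coef_std,
    intercept = fit$intercept, cv_folds = as.integer(folds),
    mae_mm = mean(abs(y - oof)),
    r2 = 1 - sum((y - oof)^2) / sum((y - mean(y))^2),
    with_clinical = with_clinical, n = nrow(x), fit = fit
  ), class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("<lasso_fit> target %s, alpha %.4g, MAE %.2f mm, R2 %.3f (n = %d)\n",
              x$target, x$alpha, x$mae_mm, x$r2, x$n))
  print(round(x$coefficients, 3))
  invisible(x)
}

#' Compare Lasso fits with and without clinical features
#'
#' Deltas are `with - without`, so a negative `delta_mae_mm` and a
#' positive `delta_r2` mean the clinical features improved prediction.
#'
#' @param fit_with,fit_without Two [fit_lasso_length()] fits on the same
#'   target.
#' @return One-row tibble of the two performances and their deltas.
#' @export
ablation_report <- function(fit_with, fit_without) {
  if (!identical(fit_with$target, fit_without$target)) {
    abort_domain("ablation_report: fits target different quantities")
  }
  tibble::tibble(
    target = fit_with$target,
    mae_with = fit_with$mae_mm, mae_without = fit_without$mae_mm,
    delta_mae_mm = fit_with$mae_mm - fit_without$mae_mm,
    r2_with = fit_with$r2, r2_without = fit_without$r2,
    delta_r2 = fit_with$r2 - fit_without$r2
  )
}

#' Design matrix for EC classification from trajectory differentials
#'
#' One observation per (patient, CTI segment): the concatenated
#' per-transition trajectory differentials of the segment's points on the
#' chosen axis (`"plane"` uses the per-transition Euclidean norms). All
#' observations must have the same feature length; with `pad = TRUE`
#' shorter vectors are right-padded with zeros instead of erroring.
#'
#' @param per_point Long per-point tibble from [segment_kinetics_table()].
#' @param clinical Clinical tibble with `patient_id`, `ec_within_12h`.
#' @param axis `"x"`, `"y"` or `"plane"`.
#' @param pad Pad ragged feature vectors with zeros?
#' @return List with `features` (matrix), `labels` (logical EC flags),
#'   `obs` (tibble `patient_id`, `segment`).
#' @export
build_ec_design <- function(per_point, clinical, axis = c("x", "y", "plane"),
                            pad = FALSE) {
  axis <- match.arg(axis)
  dat <- dplyr::inner_join(per_point,
                           clinical[, c("patient_id", "ec_within_12h")],
                           by = "patient_id")
  dat$value <- switch(axis, x = dat$dx, y = dat$dy,
                      plane = sqrt(dat$dx^2 + dat$dy^2))
  dat <- dat[order(dat$patient_id, dat$segment, dat$point_index, dat$transition), ]
  split_key <- paste(dat$patient_id, dat$segment, sep = "\r")
  chunks <- split(dat$value, factor(split_key, levels = unique(split_key)))
  lens <- lengths(chunks)
  if (length(unique(lens)) > 1L) {
    if (!pad) abort_domain("ragged feature lengths; set pad = TRUE to zero-pad")
    chunks <- lapply(chunks, function(v) c(v, numeric(max(lens) - length(v))))
  }
  first_rows <- dat[!duplicated(split_key), ]
  list(features = do.call(rbind, unname(chunks)),
       labels = first_rows$ec_within_12h,
       obs = tibble::tibble(patient_id = first_rows$patient_id,
                            segment = first_rows$segment))
}

#' L2-regularized logistic classification of EC status
#'
#' Ridge-penalized logistic regression of EC status from
#' trajectory-differential feature vectors, evaluated on a held-out set.
#' The train/test split is grouped by patient (all of a patient's
#' segments fall on the same side) to avoid within-patient leakage;
#' `group = NULL` splits by observation.
#'
#' @param features Numeric feature matrix.
#' @param labels Logical labels.
#' @param groups Grouping vector for the split (typically patient ids).
#' @param train_frac Fraction of groups in the training set.
#' @param seed Integer seed for the split.
#' @param lambda Ridge penalty passed to glmnet.
#' @param standardize Standardize feature columns before the penalty?
#'   Defaults to `FALSE`: the trajectory-differential features share one
#'   physical unit (mm), and standardization inflates transitions that
#'   carry only noise.
#' @return List of class `ec_classifier_fit`: `accuracy`, `confusion`
#'   (`tn`, `fp`, `fn`, `tp`), `coefficients`, `observation_unit`, `n_train`,
#'   `n_test`.
#' @export
fit_ec_classifier <- function(features, labels, groups = NULL,
                              train_frac = 0.7, seed = 1L, lambda = 0.1,
                              standardize = FALSE) {
  labels <- as.logical(labels)
  n <- nrow(features)
  unit <- if (is.null(groups)) "observation" else "group"
  if (is.null(groups)) groups <- seq_len(n)
  ug <- unique(groups)
  train_groups <- withr::with_seed(seed,
    sample(ug, size = max(2L, round(train_frac * length(ug)))))
  tr <- groups %in% train_groups
  if (length(unique(labels[tr])) < 2L) {
    abort_domain("training set contains a single class; re-seed the split")
  }
  fit <- glmnet::glmnet(features[tr, , drop = FALSE], factor(labels[tr]),
                        family = "binomial", alpha = 0, lambda = lambda,
                        standardize = standardize)
  prob <- as.vector(stats::predict(fit, features[!tr, , drop = FALSE],
                                   type = "response"))
  pred <- prob > 0.5
  truth <- labels[!tr]
  conf <- c(tn = sum(!pred & !truth), fp = sum(pred & !truth),
            fn = sum(!pred & truth), tp = sum(pred & truth))
  structure(list(
    accuracy = (conf[["tn"]] + conf[["tp"]]) / length(truth),
    confusion = conf,
    coefficients = as.vector(stats::coef(fit)),
    observation_unit = unit,
    n_train = sum(tr), n_test = sum(!tr), lambda = lambda
  ), class = "ec_classifier_fit")
}

#' @export
print.ec_classifier_fit <- function(x, ...) {
  cat(sprintf("<ec_classifier_fit> held-out accuracy %.3f (train %d / test %d)\n",
              x$accuracy, x$n_train, x$n_test))
  print(x$confusion)
  invisible(x)
}
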