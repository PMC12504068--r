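#' Spearman rank correlation
#'
#' Rho is the Pearson correlation of average-rank-transformed data (ties
#' receive mean ranks); the p-value uses the t approximation with `n - 2`
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return Tibble with `method`, `statistic` (rho), `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort_domain("x and y must have equal length")
  if (length(x) < 3L) abort_domain("spearman needs n >= 3")
  if (anyNA(x) || anyNA(y)) abort_domain("missing values not allowed")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    abort_domain("spearman undefined for constant input")
  }
  rho <- stats::cor(rx, ry)
  stat_result("spearman", rho, p_from_t(rho, length(x)), n = length(x))
}

#' Point-biserial correlation
#'
#' Correlation between a dichotomous grouping and a continuous variable:
#' `r_pb = (M1 - M0) / s_n * sqrt(n1 * n0 / n^2)` with the population
#' standard deviation `s_n`; identical to the Pearson correlation of the
#' values with a 0/1 dummy. The p-value uses the t approximation with
#' `n - 2` degrees of freedom.
#'
#' @param group Logical vector (TRUE = group 1).
#' @param values Numeric vector of the same length.
#' @return Tibble with `method`, `statistic`, `p_value`, `n`, `n0`, `n1`.
#' @export
point_biserial <- function(group, values) {
  if (length(group) != length(values)) abort_domain("inputs must have equal length")
  if (anyNA(group) || anyNA(values)) abort_domain("missing values not allowed")
  group <- as.logical(group)
  n <- length(values); n1 <- sum(group); n0 <- n - n1
  if (n1 == 0L || n0 == 0L) abort_domain("both groups must be nonempty")
  if (n < 3L) abort_domain("point_biserial needs n >= 3")
  s_n <- sqrt(mean((values - mean(values))^2))
  if (s_n == 0) abort_domain("point_biserial undefined for zero-variance values")
  r <- (mean(values[group]) - mean(values[!group])) / s_n * sqrt(n1 * n0 / n^2)
  stat_result("point_biserial", r, p_from_t(r, n), n = n, n0 = n0, n1 = n1)
}

p_from_t <- function(r, n) {
  r <- min(max(r, -1), 1)
  if (abs(r) >= 1) return(0)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum of the absolute difference between the two
#' empirical CDFs; the two-sided p-value uses the asymptotic Kolmogorov
#' distribution (exact small-sample p-values are not computed).
#'
#' @param a,b Numeric samples, both nonempty.
#' @return Tibble with `method`, `statistic` (D), `p_value`, `n`, `n0`,
#'   `n1`.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) abort_domain("both samples must be nonempty")
  if (anyNA(a) || anyNA(b)) abort_domain("missing values not allowed")
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  stat_result("ks_two_sample", unname(res$statistic), unname(res$p.value),
              n = length(a) + length(b), n0 = length(a), n1 = length(b))
}

stat_result <- function(method, statistic, p_value, n, n0 = NA_integer_,
                        n1 = NA_integer_) {
  tibble::tibble(method = method, statistic = statistic,
                 p_value = min(max(p_value, 0), 1),
                 n = as.integer(n), n0 = as.integer(n0), n1 = as.integer(n1))
}

#' Compare kinetic distributions between EC and non-EC patients
#'
#' Pools per-point, per-transition trajectory differentials and
#' instantaneous velocities by electrical-cardioversion (EC) status and
#' runs a two-sample KS test per axis and quantity (`dx`, `dy`, `vx`,
#' `vy`). The pooling unit is point x transition (raw distributions);
#' `unit = "patient"` instead pools per-patient means.
#'
#' @param per_point Long per-point tibble from [segment_kinetics_table()].
#' @param clinical Clinical tibble with `patient_id` and `ec_within_12h`.
#' @param unit `"point"` (default) or `"patient"`.
#' @return Tidy tibble, one KS result row per quantity.
#' @export
compare_ec_distributions <- function(per_point, clinical, unit = c("point", "patient")) {
  unit <- match.arg(unit)
  dat <- dplyr::inner_join(per_point,
                           clinical[, c("patient_id", "ec_within_12h")],
                           by = "patient_id")
  if (length(unique(dat$ec_within_12h)) < 2L) {
    abort_domain("need at least one patient in each EC group")
  }
  if (unit == "patient") {
    dat <- dplyr::summarise(
      dplyr::group_by(dat, .data$patient_id, .data$ec_within_12h),
      dplyr::across(c("dx", "dy", "vx", "vy"), mean), .groups = "drop")
  }
  rows <- lapply(c("dx", "dy", "vx", "vy"), function(q) {
    out <- ks_two_sample(dat[[q]][dat$ec_within_12h],
                         dat[[q]][!dat$ec_within_12h])
    out$comparison <- paste0(q, "_ec_vs_non_ec")
    out
  })
  dplyr::bind_rows(rows)[, c("comparison", "method", "statistic", "p_value",
                             "n", "n0", "n1")]
}

#' Cohort association screen of NE against clinical covariates
#'
#' Reproduces the cohort statistics: Spearman correlations of NE and
#' elongation with procedural time, and point-biserial correlations of NE
#' with EC, smoker status, dyslipidaemia, NYHA class and BMI class.
#' Ordinal covariates are binarized at declared cut points (default
#' NYHA >= 2, BMI >= 30 kg/m2).
#'
#' @param cohort Cohort tibble (see [build_cohort_table()]).
#' @param nyha_cut,bmi_cut Binarization cut points.
#' @return Tidy tibble of test results with a `comparison` column.
#' @export
cohort_association_screen <- function(cohort, nyha_cut = 2, bmi_cut = 30) {
  rows <- list()
  add <- function(res, label) {
    res$comparison <- label
    rows[[length(rows) + 1L]] <<- res
  }
  add(spearman_cor(cohort$procedural_time_min, cohort$ne), "procedural_time_vs_ne")
  add(spearman_cor(cohort$procedural_time_min, cohort$elongation_mm),
      "procedural_time_vs_elongation")
  for (v in c("ec_within_12h", "smoker", "dyslipidaemia")) {
    add(point_biserial(cohort[[v]], cohort$ne), paste0(v, "_vs_ne"))
  }
  add(point_biserial(cohort$nyha_class >= nyha_cut, cohort$ne), "nyha_class_vs_ne")
  add(point_biserial(cohort$bmi >= bmi_cut, cohort$ne), "bmi_class_vs_ne")
  add(point_biserial(cohort$nyha_class >= nyha_cut, cohort$elongation_mm),
      "nyha_class_vs_elongation")
  dplyr::bind_rows(rows)[, c("comparison", "method", "statistic", "p_value",
                             "n", "n0", "n1")]
}
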