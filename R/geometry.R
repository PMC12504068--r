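#' Curvilinear length of a polyline
#'
#' Cumulated Euclidean distance between consecutive contour points — the
#' "curvilinear" CTI length when applied to the CTI sub-contour.
#'
#' @param points Numeric matrix with columns `x`, `y` (mm), ordered along
#'   the contour.
#' @return Length in mm; 0 for a single point.
#' @export
curvilinear_length <- function(points) {
  points <- as_point_matrix(points)
  if (nrow(points) < 1L) abort_domain("curvilinear_length needs >= 1 point")
  if (nrow(points) == 1L) return(0)
  d <- diff(points)
  sum(sqrt(rowSums(d^2)))
}

#' Linear length of a contour span
#'
#' Euclidean distance between the first and last point — the straight
#' IVC-to-TV-hinge distance when applied to the CTI sub-contour.
#'
#' @inheritParams curvilinear_length
#' @return Length in mm.
#' @export
linear_length <- function(points) {
  points <- as_point_matrix(points)
  if (nrow(points) < 2L) abort_domain("linear_length needs >= 2 points")
  sqrt(sum((points[nrow(points), ] - points[1, ])^2))
}

#' Pouch depth of a contour span
#'
#' Maximum perpendicular distance from the interior contour points to the
#' infinite straight line through the first and last point (the line that
#' defines the linear CTI length). Describes the concavity (pouch) of the
#' CTI.
#'
#' @inheritParams curvilinear_length
#' @return Depth in mm, `>= 0`.
#' @export
pouch_depth <- function(points) {
  points <- as_point_matrix(points)
  if (nrow(points) < 3L) abort_domain("pouch_depth needs >= 3 points")
  a <- points[1, ]; b <- points[nrow(points), ]
  ab <- b - a
  nrm <- sqrt(sum(ab^2))
  if (nrm == 0) abort_domain("pouch_depth: coincident endpoints")
  interior <- points[-c(1L, nrow(points)), , drop = FALSE]
  # perpendicular distance via the 2-D cross product
  max(abs((interior[, 1] - a[1]) * ab[2] - (interior[, 2] - a[2]) * ab[1]) / nrm)
}

as_point_matrix <- function(points) {
  m <- as.matrix(points)
  if (ncol(m) != 2L) abort_domain("points must be an n x 2 matrix")
  if (nrow(m) > 0L && !all(is.finite(m))) abort_domain("points must be finite")
  storage.mode(m) <- "double"
  m
}

#' Curvilinear CTI length per frame
#'
#' @param cine A [`contour_cine`].
#' @return Numeric vector, one CTI curvilinear length per frame.
#' @export
cti_length_per_frame <- function(cine) {
  vapply(seq_len(n_frames(cine)),
         function(f) curvilinear_length(cti_points(cine, f)), numeric(1))
}

#' Select RA systolic and diastolic frames
#'
#' RA systole is identified as the frame with the shortest curvilinear CTI
#' length and RA diastole as the frame with the longest; ties break to the
#' earliest frame. This length-extreme criterion is a declared convention
#' (the alternative, RA-area extremes, can be plugged in via `lengths`).
#'
#' @param cine A [`contour_cine`].
#' @param lengths Optional per-frame criterion values to minimize/maximize
#'   instead of CTI curvilinear length.
#' @return List with integer `systole_frame` and `diastole_frame`
#'   (1-based).
#' @export
select_phase_frames <- function(cine, lengths = NULL) {
  len <- lengths %||% cti_length_per_frame(cine)
  list(systole_frame = which.min(len), diastole_frame = which.max(len))
}

#' Per-patient CTI geometry
#'
#' Computes the geometric summary of one cine: systolic/diastolic frames,
#' curvilinear CTI length in both phases, elongation (diastolic minus
#' systolic curvilinear length), normalized elongation
#' `NE = elongation / systolic curvilinear length`, and — on the diastolic
#' frame — the linear CTI length and pouch depth.
#'
#' @param cine A [`contour_cine`].
#' @return One-row tibble with fields `patient_id`, `systole_frame`,
#'   `diastole_frame`, `curvilinear_systolic_mm`, `curvilinear_diastolic_mm`,
#'   `linear_diastolic_mm`, `pouch_depth_mm`, `elongation_mm`, `ne`.
#' @export
compute_geometry <- function(cine) {
  validate_contour_cine(cine)
  phases <- select_phase_frames(cine)
  sys_len <- curvilinear_length(cti_points(cine, phases$systole_frame))
  dia_pts <- cti_points(cine, phases$diastole_frame)
  dia_len <- curvilinear_length(dia_pts)
  if (sys_len <= 0) {
    abort_domain(sprintf("patient %s: systolic curvilinear length is 0, NE undefined",
                         cine$patient_id))
  }
  elong <- dia_len - sys_len
  tibble::tibble(
    patient_id = cine$patient_id,
    systole_frame = phases$systole_frame,
    diastole_frame = phases$diastole_frame,
    curvilinear_systolic_mm = sys_len,
    curvilinear_diastolic_mm = dia_len,
    linear_diastolic_mm = linear_length(dia_pts),
    pouch_depth_mm = pouch_depth(dia_pts),
    elongation_mm = elong,
    ne = elong / sys_len
  )
}

#' Geometry for a collection of cines
#' @param cines List of [`contour_cine`] objects.
#' @return Tibble, one row per patient (see [compute_geometry()]).
#' @export
compute_geometry_table <- function(cines) {
  dplyr::bind_rows(lapply(cines, compute_geometry))
}

#' Split a cohort at a threshold and summarize NE
#'
#' Divides the cohort into a low group (`value < threshold`) and a high
#' group (`value >= threshold`). With `threshold = "median"` the split
#' point is the sample median of `field` (even cohorts: midpoint of the
#' two central order statistics). Patients on `exclude` are dropped before
#' splitting — e.g. an extreme-NE outlier excluded from a group
#' comparison.
#'
#' @param cohort Tibble with a `patient_id` column and the fields to split
#'   and summarize.
#' @param field Name of the column to split on.
#' @param threshold Numeric cut point, or `"median"`.
#' @param summary_field Column summarized per group (default `"ne"`).
#' @param exclude Character vector of patient ids to drop first.
#' @return List with `threshold`, `low`/`high` tibbles, and a `summary`
#'   tibble of per-group n, mean and sd of `summary_field`.
#' @export
median_split <- function(cohort, field, threshold = "median",
                         summary_field = "ne", exclude = character()) {
  if (nrow(cohort) == 0L) abort_domain("median_split: empty cohort")
  cohort <- cohort[!cohort$patient_id %in% exclude, , drop = FALSE]
  if (nrow(cohort) == 0L) abort_domain("median_split: all patients excluded")
  v <- cohort[[field]]
  if (anyNA(v)) abort_validation(sprintf("median_split: missing values in %s", field))
  thr <- if (identical(threshold, "median")) stats::median(v) else as.numeric(threshold)
  low <- cohort[v < thr, , drop = FALSE]
  high <- cohort[v >= thr, , drop = FALSE]
  summarize_group <- function(g, label) {
    s <- g[[summary_field]]
    tibble::tibble(group = label, n = nrow(g),
                   mean = if (nrow(g)) mean(s) else NA_real_,
                   sd = if (nrow(g) > 1) stats::sd(s) else NA_real_)
  }
  list(threshold = thr, low = low, high = high,
       summary = dplyr::bind_rows(summarize_group(low, "low"),
                                  summarize_group(high, "high")))
}
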