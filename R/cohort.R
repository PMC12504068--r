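#' Assemble the cohort analysis table
#'
#' Joins per-patient geometry, segmental-kinetics summaries (spread to
#' wide `seg<k>_max_ap_mm` / `seg<k>_max_cc_mm` columns) and clinical
#' covariates into one row per patient. Patients lacking either a cine or
#' a clinical record are dropped with a warning: the cohort table only
#' contains complete patients.
#'
#' @param geometry Tibble from [compute_geometry_table()].
#' @param segments Per-segment tibble from [segment_kinetics_table()].
#' @param clinical Clinical tibble from [read_clinical_table()].
#' @return Cohort tibble keyed by `patient_id`.
#' @export
build_cohort_table <- function(geometry, segments, clinical) {
  wide <- tidyr::pivot_wider(
    segments[, c("patient_id", "segment", "mean_max_disp_ap_mm",
                 "mean_max_disp_cc_mm")],
    names_from = "segment",
    values_from = c("mean_max_disp_ap_mm", "mean_max_disp_cc_mm")
  )
  names(wide) <- sub("^mean_max_disp_(ap|cc)_mm_(\\d+)$", "seg\\2_max_\\1_mm",
                     names(wide))
  cohort <- dplyr::inner_join(geometry, wide, by = "patient_id")
  cohort <- dplyr::inner_join(cohort, clinical, by = "patient_id")
  dropped <- setdiff(union(geometry$patient_id, clinical$patient_id),
                     cohort$patient_id)
  if (length(dropped)) {
    warning(sprintf("dropped %d patient(s) without both a cine and a clinical record: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  cohort
}
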