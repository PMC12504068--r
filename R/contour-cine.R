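#' Contour cine data model
#'
#' A `contour_cine` holds one patient's right-atrial (RA) wall contour as an
#' ordered set of 2-D points tracked over the frames of a cardiac cine: an
#' `F x P x 2` coordinate array in millimetres, where the first axis is the
#' cine frame, the second the contour point and the third the spatial axis
#' (`x` = anterior(+)/posterior(-), `y` = cranial(+)/caudal(-)).
#'
#' The contour has an odd number of points (default 49): a critical point
#' near the inferior vena cava (IVC) flanked by an equal number of points on
#' each side. Which points constitute the cavotricuspid isthmus (CTI) is
#' per-patient metadata: `cti_range` is a half-open, 0-based index interval
#' `[start, end)` matching the on-disk indexing; the default runs from the
#' IVC midpoint index `(P-1)/2` to the contour end on the tricuspid-valve
#' (TV) side.
#'
#' @param patient_id Single string identifying the patient.
#' @param coords Numeric array `F x P x 2` (frames x points x xy), in mm.
#' @param frame_interval Seconds between consecutive frames, or `NA` when
#'   unknown (velocity computations then need an explicit `dt`).
#' @param cti_range Integer vector `c(start, end)`: half-open 0-based index
#'   interval of the CTI points, EV/IVC end first, TV end last.
#'
#' @return An object of class `contour_cine`.
#' @export
contour_cine <- function(patient_id, coords, frame_interval = NA_real_,
                         cti_range = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 2L) {
    abort_validation("`coords` must be an F x P x 2 array")
  }
  n_points <- dim(coords)[2]
  if (is.null(cti_range)) cti_range <- default_cti_range(n_points)
  x <- structure(
    list(
      patient_id = as.character(patient_id),
      coords = coords,
      frame_interval = as.numeric(frame_interval),
      cti_range = as.integer(cti_range)
    ),
    class = "contour_cine"
  )
  validate_contour_cine(x)
}

#' Default CTI index range
#'
#' Half-open 0-based interval from the IVC midpoint index `(P-1)/2` to the
#' contour end on the TV side. The mapping of anatomical landmarks onto
#' contour indices is a modelling choice, not a measured quantity; override
#' it per patient when landmark positions are known.
#'
#' @param n_points Number of contour points P.
#' @return Integer `c(start, end)`.
#' @export
default_cti_range <- function(n_points) {
  c((n_points - 1L) %/% 2L, as.integer(n_points))
}

#' @rdname contour_cine
#' @param x A `contour_cine`.
#' @export
validate_contour_cine <- function(x) {
  d <- dim(x$coords)
  n_frames <- d[1]; n_points <- d[2]
  if (length(x$patient_id) != 1L || is.na(x$patient_id) || !nzchar(x$patient_id)) {
    abort_validation("patient_id must be a non-empty string")
  }
  if (n_frames < 2L) {
    abort_validation(sprintf("patient %s: cine needs >= 2 frames, got %d",
                             x$patient_id, n_frames))
  }
  if (n_points %% 2L != 1L) {
    abort_validation(sprintf("patient %s: point count must be odd, got %d",
                             x$patient_id, n_points))
  }
  if (!all(is.finite(x$coords))) {
    abort_validation(sprintf("patient %s: non-finite coordinates", x$patient_id))
  }
  r <- x$cti_range
  if (length(r) != 2L || r[1] < 0L || r[2] > n_points || r[2] - r[1] < 2L) {
    abort_validation(sprintf(
      "patient %s: cti_range [%s, %s) must lie within [0, %d) and contain >= 2 points",
      x$patient_id, r[1], r[2], n_points))
  }
  if (!is.na(x$frame_interval) && x$frame_interval <= 0) {
    abort_validation(sprintf("patient %s: frame_interval must be positive", x$patient_id))
  }
  invisible(x)
}

#' @export
print.contour_cine <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("<contour_cine> patient %s: %d frames x %d points, CTI indices [%d, %d)\n",
              x$patient_id, d[1], d[2], x$cti_range[1], x$cti_range[2]))
  invisible(x)
}

#' Number of frames / points of a cine
#' @param cine A `contour_cine`.
#' @return Integer count.
#' @export
n_frames <- function(cine) dim(cine$coords)[1]

#' @rdname n_frames
#' @export
n_points <- function(cine) dim(cine$coords)[2]

# 1-based point indices of the CTI sub-contour, EV/IVC end -> TV end
cti_indices <- function(cine) {
  seq.int(cine$cti_range[1] + 1L, cine$cti_range[2])
}

#' Extract the CTI point set of one frame
#'
#' @param cine A `contour_cine`.
#' @param frame 1-based frame index.
#' @return Numeric matrix with columns `x`, `y` (mm), CTI points in order
#'   from the EV/IVC end to the TV end.
#' @export
cti_points <- function(cine, frame) {
  stopifnot(frame >= 1L, frame <= n_frames(cine))
  m <- cine$coords[frame, cti_indices(cine), , drop = FALSE]
  m <- matrix(m, ncol = 2L, dimnames = list(NULL, c("x", "y")))
  m
}

# error helpers ---------------------------------------------------------

abort_validation <- function(msg) {
  rlang::abort(msg, class = "ctikin_validation_error")
}

abort_malformed <- function(msg) {
  rlang::abort(msg, class = "ctikin_malformed_input")
}

abort_parse <- function(msg) {
  rlang::abort(msg, class = "ctikin_parse_error")
}

abort_domain <- function(msg) {
  rlang::abort(msg, class = "ctikin_domain_error")
}
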