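#' Read a long-format contour table
#'
#' Reads per-patient contour cines from a long-format CSV with columns
#' `patient_id, frame, point_index, x_mm, y_mm`. Frame and point indices are
#' 0-based in the file. Every patient must have a complete
#' `frames x points` grid of cells; missing or duplicated cells raise a
#' malformed-input error naming the patient and cell.
#'
#' @param path Path to the CSV file.
#' @param expected_points,expected_frames Optional integer checks on the
#'   per-patient point and frame counts; a mismatch raises a validation
#'   error.
#' @param frame_interval Seconds between frames to attach to every cine
#'   (`NA` to leave unset).
#' @param cti_range Optional CTI index range applied to every cine
#'   (half-open, 0-based); default is [`default_cti_range()`].
#'
#' @return Named list of [`contour_cine`] objects (names are patient ids,
#'   in order of first appearance).
#' @export
read_contour_table <- function(path, expected_points = NULL,
                               expected_frames = NULL,
                               frame_interval = NA_real_,
                               cti_range = NULL) {
  if (!file.exists(path)) abort_malformed(sprintf("file not found: %s", path))
  tab <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    frame = readr::col_integer(),
    point_index = readr::col_integer(),
    x_mm = readr::col_character(),
    y_mm = readr::col_character()
  ))
  need <- c("patient_id", "frame", "point_index", "x_mm", "y_mm")
  if (!all(need %in% names(tab))) {
    abort_malformed(sprintf("contour table must have columns %s",
                            paste(need, collapse = ", ")))
  }
  for (col in c("x_mm", "y_mm")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !is.na(tab[[col]]))
    if (length(bad)) {
      abort_parse(sprintf("non-numeric %s '%s' (patient %s, frame %d, point %d)",
                          col, tab[[col]][bad[1]], tab$patient_id[bad[1]],
                          tab$frame[bad[1]], tab$point_index[bad[1]]))
    }
    if (anyNA(v)) abort_parse(sprintf("missing %s value in contour table", col))
    tab[[col]] <- v
  }

  ids <- unique(tab$patient_id)
  cines <- lapply(ids, function(id) {
    sub <- tab[tab$patient_id == id, , drop = FALSE]
    frames <- sort(unique(sub$frame))
    points <- sort(unique(sub$point_index))
    if (!identical(frames, seq.int(0L, length(frames) - 1L)) ||
        !identical(points, seq.int(0L, length(points) - 1L))) {
      abort_malformed(sprintf("patient %s: frame/point indices must be 0..n-1", id))
    }
    key <- paste(sub$frame, sub$point_index)
    dup <- key[duplicated(key)]
    if (length(dup)) {
      abort_malformed(sprintf("patient %s: duplicate cell (frame %s, point %s)",
                              id, sub("^(\\S+) .*", "\\1", dup[1]),
                              sub("^\\S+ ", "", dup[1])))
    }
    grid <- expand.grid(frame = frames, point_index = points)
    missing_cell <- setdiff(paste(grid$frame, grid$point_index), key)
    if (length(missing_cell)) {
      abort_malformed(sprintf("patient %s: missing cell (frame %s, point %s)",
                              id, sub("^(\\S+) .*", "\\1", missing_cell[1]),
                              sub("^\\S+ ", "", missing_cell[1])))
    }
    if (!is.null(expected_points) && length(points) != expected_points) {
      abort_validation(sprintf("patient %s: expected %d points, got %d",
                               id, expected_points, length(points)))
    }
    if (!is.null(expected_frames) && length(frames) != expected_frames) {
      abort_validation(sprintf("patient %s: expected %d frames, got %d",
                               id, expected_frames, length(frames)))
    }
    coords <- array(NA_real_, c(length(frames), length(points), 2L),
                    dimnames = list(NULL, NULL, c("x", "y")))
    coords[cbind(sub$frame + 1L, sub$point_index + 1L, 1L)] <- sub$x_mm
    coords[cbind(sub$frame + 1L, sub$point_index + 1L, 2L)] <- sub$y_mm
    contour_cine(id, coords, frame_interval = frame_interval,
                 cti_range = cti_range %||% default_cti_range(length(points)))
  })
  stats::setNames(cines, ids)
}

#' Write contour cines to a long-format CSV
#'
#' Inverse of [read_contour_table()]: coordinates are written at full
#' double precision so a read/write round trip is bit-exact.
#'
#' @param cines List of [`contour_cine`] objects (may be empty).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contour_table <- function(cines, path) {
  rows <- lapply(cines, function(cine) {
    d <- dim(cine$coords)
    grid <- expand.grid(point_index = seq_len(d[2]) - 1L,
                        frame = seq_len(d[1]) - 1L)
    tibble::tibble(
      patient_id = cine$patient_id,
      frame = grid$frame,
      point_index = grid$point_index,
      x_mm = as.vector(t(cine$coords[, , 1])),
      y_mm = as.vector(t(cine$coords[, , 2]))
    )
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(patient_id = character(), frame = integer(),
                   point_index = integer(), x_mm = double(), y_mm = double())
  # format full precision; readr would round-trip doubles anyway but keep
  # explicit 17 significant digits so the file itself is exact
  out$x_mm <- sprintf("%.17g", out$x_mm)
  out$y_mm <- sprintf("%.17g", out$y_mm)
  if (nrow(out) == 0L) {
    out$x_mm <- character(); out$y_mm <- character()
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Read the clinical covariate table
#'
#' Columns: `patient_id, ec_within_12h, smoker, dyslipidaemia, bmi,
#' nyha_class, age, procedural_time_min, ablation_duration_min`. Boolean
#' columns accept `0/1`, `true/false`, `yes/no` case-insensitively.
#'
#' @param path CSV path.
#' @return Tibble of typed clinical records, one row per patient.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) abort_malformed(sprintf("file not found: %s", path))
  tab <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    .default = readr::col_character()
  ))
  need <- c("patient_id", "ec_within_12h", "smoker", "dyslipidaemia", "bmi",
            "nyha_class", "age", "procedural_time_min", "ablation_duration_min")
  if (!all(need %in% names(tab))) {
    abort_malformed(sprintf("clinical table must have columns %s",
                            paste(need, collapse = ", ")))
  }
  for (col in c("ec_within_12h", "smoker", "dyslipidaemia")) {
    tab[[col]] <- parse_boolean(tab[[col]], col)
  }
  for (col in c("bmi", "age", "procedural_time_min", "ablation_duration_min")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v)) abort_parse(sprintf("non-numeric value in column %s", col))
    tab[[col]] <- v
  }
  nyha <- suppressWarnings(as.integer(tab$nyha_class))
  if (anyNA(nyha)) abort_parse("non-numeric value in column nyha_class")
  tab$nyha_class <- nyha
  validate_clinical(tab)
  tab[need]
}

parse_boolean <- function(x, col) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("1", "true", "yes")] <- TRUE
  out[lx %in% c("0", "false", "no")] <- FALSE
  if (anyNA(out)) {
    bad <- x[which(is.na(out))[1]]
    abort_parse(sprintf("unknown boolean token '%s' in column %s", bad, col))
  }
  out
}

validate_clinical <- function(tab) {
  if (anyDuplicated(tab$patient_id)) {
    abort_validation("duplicate patient_id in clinical table")
  }
  if (any(tab$bmi <= 0)) abort_validation("bmi must be > 0")
  if (any(!tab$nyha_class %in% 1:4)) {
    abort_validation(sprintf("nyha_class must be in 1..4 (patient %s)",
                             tab$patient_id[which(!tab$nyha_class %in% 1:4)[1]]))
  }
  if (any(tab$procedural_time_min < 0) || any(tab$ablation_duration_min < 0)) {
    abort_validation("procedure times must be >= 0")
  }
  invisible(tab)
}

#' Write a clinical covariate table
#' @param clinical Tibble as returned by [read_clinical_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(clinical, path) {
  out <- clinical
  for (col in c("ec_within_12h", "smoker", "dyslipidaemia")) {
    out[[col]] <- as.integer(out[[col]])
  }
  readr::write_csv(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
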