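#' Trajectory differentials of one point track
#'
#' The trajectory differential of a contour point at frame `n` is its
#' position change between consecutive frames,
#' `delta_n = pos(t_n) - pos(t_{n-1})`. The differentials telescope: their
#' sum equals the net displacement `pos(t_F) - pos(t_1)`.
#'
#' @param track Numeric matrix `F x 2` of per-frame positions (mm).
#' @return Matrix `(F-1) x 2` of per-transition deltas (mm).
#' @export
trajectory_differentials <- function(track) {
  track <- as_point_matrix(track)
  if (nrow(track) < 2L) abort_domain("trajectory_differentials needs >= 2 frames")
  diff(track)
}

#' Instantaneous velocity of one point track
#'
#' Trajectory differentials divided by the frame interval.
#'
#' @inheritParams trajectory_differentials
#' @param dt Seconds per frame, `> 0`.
#' @return Matrix `(F-1) x 2` of velocities (mm/s).
#' @export
instantaneous_velocity <- function(track, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0) {
    abort_domain("dt must be a positive number of seconds")
  }
  trajectory_differentials(track) / dt
}

#' Net and maximum displacement of one point track
#'
#' Net displacement is final minus initial position. Maximum displacements
#' are taken relative to the first frame: per axis the max of
#' `|x(t_n) - x(t_1)|` over frames (similarly `y`), and `euclid` the max
#' 2-D norm of `pos(t_n) - pos(t_1)`. The first frame is the reference
#' because a cine is cyclic (net displacement is near zero and
#' uninformative) and frame 1 is the only universally defined anchor.
#'
#' @inheritParams trajectory_differentials
#' @return List with `net` (named `ap`, `cc`, in mm) and `max` (named
#'   `ap`, `cc`, `euclid`).
#' @export
point_displacement <- function(track) {
  track <- as_point_matrix(track)
  if (nrow(track) < 2L) abort_domain("point_displacement needs >= 2 frames")
  rel <- sweep(track, 2L, track[1, ])
  list(
    net = c(ap = track[nrow(track), 1] - track[1, 1],
            cc = track[nrow(track), 2] - track[1, 2]),
    max = c(ap = max(abs(rel[, 1])),
            cc = max(abs(rel[, 2])),
            euclid = max(sqrt(rowSums(rel^2))))
  )
}

#' Partition the CTI points into contiguous segments
#'
#' Splits the CTI point range into `n_segments` contiguous runs of
#' near-equal size, segment 1 at the EV/IVC end and segment `n_segments`
#' at the TV end. When the point count is not divisible, the larger runs
#' are placed on the TV side, where motion is larger and finer sampling is
#' conservative.
#'
#' @param cine A [`contour_cine`].
#' @param n_segments Number of segments (default 5).
#' @return List of integer vectors of 1-based point indices (into the full
#'   contour), one per segment.
#' @export
segment_partition <- function(cine, n_segments = 5L) {
  idx <- cti_indices(cine)
  n <- length(idx)
  if (n < n_segments) {
    abort_domain(sprintf("CTI has %d points, need >= %d for %d segments",
                         n, n_segments, n_segments))
  }
  base <- n %/% n_segments
  r <- n %% n_segments
  sizes <- c(rep(base, n_segments - r), rep(base + 1L, r))
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_len(n_segments), function(k) idx[starts[k]:ends[k]])
}

#' Segmental kinetics of one cine
#'
#' Computes, for each of the five CTI segments (1 near the Eustachian
#' valve, 5 near the tricuspid valve), the segment means of per-point
#' maximum displacements (AP, CC, Euclidean) and net displacement norm,
#' and retains the per-point trajectory differentials and instantaneous
#' velocities for downstream distribution comparisons.
#'
#' @param cine A [`contour_cine`].
#' @param dt Seconds per frame; defaults to the cine's `frame_interval`.
#' @param n_segments Number of segments.
#' @return List of class `segment_kinetics` with elements
#'   `patient_id`, `segments` (summary tibble), `per_point` (long tibble
#'   of per-transition `dx`, `dy`, `vx`, `vy` per point with its segment).
#' @export
segment_kinetics <- function(cine, dt = NULL, n_segments = 5L) {
  validate_contour_cine(cine)
  dt <- dt %||% cine$frame_interval
  if (is.null(dt) || is.na(dt)) {
    abort_domain(sprintf("patient %s: no frame_interval; supply dt", cine$patient_id))
  }
  parts <- segment_partition(cine, n_segments)
  seg_rows <- vector("list", n_segments)
  pp_rows <- vector("list", n_segments)
  for (k in seq_len(n_segments)) {
    pts <- parts[[k]]
    disp <- lapply(pts, function(p) point_displacement(cine$coords[, p, ]))
    max_ap <- vapply(disp, function(d) d$max[["ap"]], numeric(1))
    max_cc <- vapply(disp, function(d) d$max[["cc"]], numeric(1))
    max_eu <- vapply(disp, function(d) d$max[["euclid"]], numeric(1))
    net <- vapply(disp, function(d) sqrt(sum(d$net^2)), numeric(1))
    seg_rows[[k]] <- tibble::tibble(
      patient_id = cine$patient_id, segment = k,
      n_points = length(pts),
      mean_max_disp_ap_mm = mean(max_ap),
      mean_max_disp_cc_mm = mean(max_cc),
      mean_max_disp_euclid_mm = mean(max_eu),
      mean_net_disp_mm = mean(net)
    )
    deltas <- lapply(pts, function(p) trajectory_differentials(cine$coords[, p, ]))
    nd <- nrow(deltas[[1]])
    pp_rows[[k]] <- tibble::tibble(
      patient_id = cine$patient_id, segment = k,
      point_index = rep(pts - 1L, each = nd),      # 0-based, as on disk
      transition = rep(seq_len(nd), times = length(pts)),
      dx = unlist(lapply(deltas, function(d) d[, 1])),
      dy = unlist(lapply(deltas, function(d) d[, 2]))
    )
  }
  per_point <- dplyr::bind_rows(pp_rows)
  per_point$vx <- per_point$dx / dt
  per_point$vy <- per_point$dy / dt
  structure(list(patient_id = cine$patient_id, dt = dt,
                 segments = dplyr::bind_rows(seg_rows),
                 per_point = per_point),
            class = "segment_kinetics")
}

#' @export
print.segment_kinetics <- function(x, ...) {
  cat(sprintf("<segment_kinetics> patient %s (dt = %.4f s)\n", x$patient_id, x$dt))
  print(x$segments)
  invisible(x)
}

#' Segmental kinetics for a cohort of cines
#' @param cines List of [`contour_cine`] objects.
#' @inheritParams segment_kinetics
#' @return List with `segments` (stacked per-segment tibble) and
#'   `per_point` (stacked per-point tibble).
#' @export
segment_kinetics_table <- function(cines, dt = NULL, n_segments = 5L) {
  sks <- lapply(cines, segment_kinetics, dt = dt, n_segments = n_segments)
  list(segments = dplyr::bind_rows(lapply(sks, `[[`, "segments")),
       per_point = dplyr::bind_rows(lapply(sks, `[[`, "per_point")))
}

#' Default motion-pattern thresholds for a cohort
#'
#' Amplitude cut points are the cohort 25th/75th percentiles of the
#' per-patient overall amplitude (mean over segments of the mean maximum
#' Euclidean displacement); axis-dominance cut points default to ratios
#' 1/2 and 2. The cohort-relative amplitude thresholds reflect that hypo-
#' and hyperkinesia are defined against the study population, not an
#' absolute scale.
#'
#' @param segments Stacked per-segment tibble from
#'   [segment_kinetics_table()].
#' @param probs Lower/upper amplitude percentiles.
#' @param r_lo,r_hi AP/CC ratio cut points.
#' @return Named list `t_low`, `t_high`, `r_lo`, `r_hi`.
#' @export
motion_thresholds <- function(segments, probs = c(0.25, 0.75),
                              r_lo = 0.5, r_hi = 2) {
  amp <- dplyr::summarise(
    dplyr::group_by(segments, .data$patient_id),
    a = mean(.data$mean_max_disp_euclid_mm), .groups = "drop")$a
  q <- stats::quantile(amp, probs, names = FALSE)
  list(t_low = q[1], t_high = q[2], r_lo = r_lo, r_hi = r_hi)
}

#' Classify a patient's CTI motion pattern
#'
#' Computes the overall amplitude `A` (mean over segments of the mean max
#' Euclidean displacement) and the axis ratio `R` (mean AP max over mean
#' CC max). The label is `hypokinetic` if `A < t_low`, `hyperkinetic` if
#' `A > t_high`, otherwise `ap_dominant` if `R > r_hi`, `cc_dominant` if
#' `R < r_lo`, and `ap_dominant` by default (AP motion dominates the
#' cohort).
#'
#' @param sk A `segment_kinetics` object.
#' @param thresholds Named list as from [motion_thresholds()].
#' @return List with `label` and `scores` (`amplitude_mm`, `ap_cc_ratio`).
#' @export
classify_motion_pattern <- function(sk, thresholds) {
  seg <- sk$segments
  a <- mean(seg$mean_max_disp_euclid_mm)
  cc <- mean(seg$mean_max_disp_cc_mm)
  r <- if (cc > 0) mean(seg$mean_max_disp_ap_mm) / cc else Inf
  label <- if (a < thresholds$t_low) "hypokinetic"
  else if (a > thresholds$t_high) "hyperkinetic"
  else if (r < thresholds$r_lo) "cc_dominant"
  else "ap_dominant"
  list(label = label, scores = c(amplitude_mm = a, ap_cc_ratio = r))
}
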