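# build a cine from a list of F point matrices (P x 2 each)
cine_from_frames <- function(frames, patient_id = "T1", ...) {
  p <- nrow(frames[[1]])
  coords <- array(NA_real_, c(length(frames), p, 2),
                  dimnames = list(NULL, NULL, c("x", "y")))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  contour_cine(patient_id, coords, ...)
}

# random smooth-ish cine: a jittered arc with P points over F frames
random_cine <- function(seed, n_frames = 6L, n_points = 13L,
                        patient_id = "R1", ...) {
  withr::with_seed(seed, {
    s <- seq(0, 1, length.out = n_points)
    base <- cbind(40 * s, 8 * sin(pi * s))
    frames <- lapply(seq_len(n_frames), function(f) {
      base + matrix(stats::rnorm(2 * n_points, 0, 0.8), n_points, 2)
    })
    cine_from_frames(frames, patient_id = patient_id, ...)
  })
}

# write a long-format contour CSV from explicit rows for IO error tests
write_contour_rows <- function(df, path) {
  readr::write_csv(df, path)
  path
}

# minimal valid clinical tibble for n patients
toy_clinical <- function(ids, ec = rep(FALSE, length(ids))) {
  tibble::tibble(
    patient_id = ids, ec_within_12h = ec,
    smoker = FALSE, dyslipidaemia = FALSE, bmi = 29, nyha_class = 2L,
    age = 66, procedural_time_min = 45, ablation_duration_min = 19
  )
}

# exhaustive 1-D k-means oracle: in one dimension the optimal partition is
# contiguous in sorted order, so enumerate all contiguous splits
brute_force_wcss_1d <- function(values, k) {
  v <- sort(values)
  n <- length(v)
  splits <- utils::combn(n - 1, k - 1, simplify = FALSE)
  best <- Inf
  for (sp in splits) {
    bounds <- c(0, sp, n)
    wcss <- 0
    for (g in seq_len(k)) {
      seg <- v[(bounds[g] + 1):bounds[g + 1]]
      wcss <- wcss + sum((seg - mean(seg))^2)
    }
    best <- min(best, wcss)
  }
  best
}
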