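test_that("curvilinear length matches hand-computed polylines", {
  expect_equal(curvilinear_length(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(curvilinear_length(rbind(c(0, 0))), 0)
  expect_equal(curvilinear_length(rbind(c(0, 0), c(1, 0), c(1, 1), c(2, 1))), 3)
  expect_error(curvilinear_length(matrix(numeric(), 0, 2)),
               class = "ctikin_domain_error")
})

test_that("curvilinear length equals brute-force pairwise sum on random polylines", {
  for (seed in 1:5) {
    pts <- withr::with_seed(seed, matrix(rnorm(24, sd = 10), 12, 2))
    brute <- sum(vapply(2:nrow(pts), function(i) {
      sqrt(sum((pts[i, ] - pts[i - 1, ])^2))
    }, numeric(1)))
    expect_equal(curvilinear_length(pts), brute)
  }
})

test_that("linear length is the endpoint distance and bounded by curvilinear", {
  expect_equal(linear_length(rbind(c(0, 0), c(5, 0))), 5)
  loop <- rbind(c(0, 0), c(2, 3), c(-1, 4), c(0, 0))
  expect_equal(linear_length(loop), 0)
  expect_error(linear_length(rbind(c(0, 0))), class = "ctikin_domain_error")
  for (seed in 6:10) {
    pts <- withr::with_seed(seed, matrix(rnorm(20, sd = 5), 10, 2))
    expect_gte(curvilinear_length(pts), linear_length(pts) - 1e-12)
  }
  # collinear contour: the two lengths coincide
  s <- withr::with_seed(3, sort(runif(8)))
  pts <- cbind(2 + 3 * s, -1 + 0.5 * s)
  expect_equal(curvilinear_length(pts), linear_length(pts))
})

test_that("pouch depth is the max perpendicular distance to the endpoint line", {
  expect_equal(pouch_depth(rbind(c(0, 0), c(1, 0), c(2, 0))), 0)
  expect_equal(pouch_depth(rbind(c(0, 0), c(1, 1), c(2, 0))), 1)
  expect_equal(pouch_depth(rbind(c(0, 0), c(1, -1), c(1, 2), c(2, 0))), 2)
  expect_error(pouch_depth(rbind(c(0, 0), c(1, 1), c(0, 0))),
               class = "ctikin_domain_error")
  # brute-force oracle over interior points, random polylines
  for (seed in 11:15) {
    pts <- withr::with_seed(seed, matrix(rnorm(16, sd = 4), 8, 2))
    a <- pts[1, ]; b <- pts[8, ]
    brute <- max(vapply(2:7, function(i) {
      p <- pts[i, ]
      abs((p[1] - a[1]) * (b[2] - a[2]) - (p[2] - a[2]) * (b[1] - a[1])) /
        sqrt(sum((b - a)^2))
    }, numeric(1)))
    expect_equal(pouch_depth(pts), brute)
  }
})

test_that("phase frames are the CTI length extremes with earliest-frame ties", {
  base <- cbind(seq(0, 10, length.out = 9), rep(0, 9))
  scale_frame <- function(s) base * s
  cine <- cine_from_frames(lapply(c(1.0, 0.8, 1.2), scale_frame))
  ph <- select_phase_frames(cine)
  expect_equal(ph$systole_frame, 2L)
  expect_equal(ph$diastole_frame, 3L)
  flat <- cine_from_frames(lapply(c(1, 1, 1), scale_frame))
  ph2 <- select_phase_frames(flat)
  expect_equal(ph2$systole_frame, 1L)
  expect_equal(ph2$diastole_frame, 1L)
})

test_that("geometry fields satisfy their defining identities", {
  base <- cbind(seq(0, 10, length.out = 9), sin(seq(0, pi, length.out = 9)))
  cine <- cine_from_frames(list(base, base * 0.5, base * 1.0))
  g <- compute_geometry(cine)
  expect_equal(g$elongation_mm,
               g$curvilinear_diastolic_mm - g$curvilinear_systolic_mm)
  expect_equal(g$ne, g$elongation_mm / g$curvilinear_systolic_mm)
  # diastole = 2x systole => NE = 1
  expect_equal(g$ne, 1)
  # zero motion => elongation and NE are 0
  g0 <- compute_geometry(cine_from_frames(list(base, base)))
  expect_equal(g0$elongation_mm, 0)
  expect_equal(g0$ne, 0)
})

test_that("geometry is scale-equivariant and rigid-motion invariant", {
  cine <- random_cine(21, n_frames = 5L, n_points = 13L)
  g <- compute_geometry(cine)
  s <- 2.7
  g_scaled <- compute_geometry(
    contour_cine(cine$patient_id, cine$coords * s, cti_range = cine$cti_range))
  for (f in c("curvilinear_systolic_mm", "curvilinear_diastolic_mm",
              "linear_diastolic_mm", "pouch_depth_mm", "elongation_mm")) {
    expect_equal(g_scaled[[f]], s * g[[f]], tolerance = 1e-12)
  }
  expect_equal(g_scaled$ne, g$ne, tolerance = 1e-12)

  th <- 0.73
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  coords_r <- cine$coords
  for (f in seq_len(dim(coords_r)[1])) {
    coords_r[f, , ] <- cine$coords[f, , ] %*% rot +
      matrix(c(13, -4), dim(coords_r)[2], 2, byrow = TRUE)
  }
  g_rigid <- compute_geometry(
    contour_cine(cine$patient_id, coords_r, cti_range = cine$cti_range))
  for (f in c("curvilinear_systolic_mm", "curvilinear_diastolic_mm",
              "linear_diastolic_mm", "pouch_depth_mm", "elongation_mm", "ne")) {
    expect_equal(g_rigid[[f]], g[[f]], tolerance = 1e-9)
  }
})

test_that("NE recovers 1/s - 1 exactly for uniform noise-free contraction", {
  for (s in c(0.3, 0.5, 0.8, 1.0)) {
    cfg <- synth_config_contraction(noise_sd_mm = 0, contraction_ratio = s,
                                    seed = 13)
    g <- compute_geometry(generate_cine(cfg)$cine)
    expect_equal(g$ne, 1 / s - 1, tolerance = 1e-12)
  }
})

test_that("median split follows the strict-less-than rule with exclusions", {
  cohort <- tibble::tibble(patient_id = paste0("P", 1:4),
                           value = c(1, 2, 3, 4), ne = c(0.2, 0.4, 0.6, 0.8))
  sp <- median_split(cohort, "value")
  expect_equal(sp$threshold, 2.5)
  expect_setequal(sp$low$patient_id, c("P1", "P2"))
  expect_setequal(sp$high$patient_id, c("P3", "P4"))
  expect_equal(sp$summary$mean[sp$summary$group == "low"], 0.3)

  # all-equal values: nothing is strictly below the threshold
  flat <- tibble::tibble(patient_id = paste0("P", 1:3), value = c(5, 5, 5),
                         ne = c(0.1, 0.2, 0.3))
  sp2 <- median_split(flat, "value")
  expect_equal(nrow(sp2$low), 0L)
  expect_equal(nrow(sp2$high), 3L)

  # excluded outlier appears in neither group
  cohort$ne[4] <- 3.38
  sp3 <- median_split(cohort, "value", exclude = "P4")
  expect_false("P4" %in% c(sp3$low$patient_id, sp3$high$patient_id))
  expect_error(median_split(cohort[0, ], "value"), class = "ctikin_domain_error")
})
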