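test_that("trajectory differentials subtract consecutive positions and telescope", {
  track <- rbind(c(0, 0), c(1, 0), c(1, 2))
  d <- trajectory_differentials(track)
  expect_equal(d, rbind(c(1, 0), c(0, 2)), ignore_attr = TRUE)
  expect_equal(trajectory_differentials(rbind(c(2, 3), c(2, 3), c(2, 3))),
               matrix(0, 2, 2), ignore_attr = TRUE)
  expect_error(trajectory_differentials(rbind(c(0, 0))),
               class = "ctikin_domain_error")
  # telescoping: sum of deltas equals final - initial, random tracks
  for (seed in 1:5) {
    tr <- withr::with_seed(seed, matrix(rnorm(20), 10, 2))
    expect_equal(colSums(trajectory_differentials(tr)), tr[10, ] - tr[1, ])
  }
})

test_that("instantaneous velocity scales differentials by 1/dt", {
  track <- rbind(c(0, 0), c(1, 0))
  expect_equal(instantaneous_velocity(track, 0.5), rbind(c(2, 0)),
               ignore_attr = TRUE)
  expect_error(instantaneous_velocity(track, 0), class = "ctikin_domain_error")
  tr <- withr::with_seed(8, matrix(rnorm(16), 8, 2))
  expect_equal(instantaneous_velocity(tr, 0.08),
               2 * instantaneous_velocity(tr, 0.16))
})

test_that("point displacement separates net from first-frame-referenced max", {
  out_back <- rbind(c(0, 0), c(3, 0), c(0, 0))
  d <- point_displacement(out_back)
  expect_equal(d$net, c(ap = 0, cc = 0))
  expect_equal(d$max[["ap"]], 3)
  # monotone track: max equals |net| componentwise
  mono <- rbind(c(0, 0), c(1, -1), c(2, -3))
  dm <- point_displacement(mono)
  expect_equal(unname(dm$max[c("ap", "cc")]), abs(unname(dm$net)))
  # brute-force: max Euclidean >= norm of net on random tracks
  for (seed in 1:5) {
    tr <- withr::with_seed(seed, matrix(rnorm(14), 7, 2))
    rel <- sweep(tr, 2, tr[1, ])
    brute <- max(sqrt(rowSums(rel^2)))
    dd <- point_displacement(tr)
    expect_equal(dd$max[["euclid"]], brute)
    expect_gte(dd$max[["euclid"]], sqrt(sum(dd$net^2)) - 1e-12)
  }
})

test_that("segment partition is contiguous, near-equal, remainder TV-side", {
  cine10 <- random_cine(31, n_points = 19L, cti_range = c(9L, 19L))  # 10 CTI pts
  parts <- segment_partition(cine10)
  expect_equal(lengths(parts), rep(2L, 5))
  cine12 <- random_cine(32, n_points = 23L, cti_range = c(11L, 23L)) # 12 CTI pts
  parts12 <- segment_partition(cine12)
  expect_equal(lengths(parts12), c(2L, 2L, 2L, 3L, 3L))
  # partition property: union = CTI points, pairwise disjoint, contiguous
  all_idx <- sort(unlist(parts12))
  expect_equal(all_idx, 12:23)
  expect_equal(anyDuplicated(unlist(parts12)), 0L)
  expect_error(segment_partition(random_cine(33, n_points = 9L,
                                             cti_range = c(5L, 9L))),
               class = "ctikin_domain_error")
})

test_that("segment kinetics reduce to identical values under rigid translation", {
  base <- cbind(seq(0, 24, length.out = 25), rep(0, 25))
  shift <- c(2, -1)
  frames <- list(base, sweep(base, 2, -shift), base)
  cine <- cine_from_frames(lapply(frames, identity), cti_range = c(12L, 25L))
  sk <- segment_kinetics(cine, dt = 0.04)
  expect_equal(sk$segments$mean_max_disp_ap_mm, rep(2, 5))
  expect_equal(sk$segments$mean_max_disp_cc_mm, rep(1, 5))
  expect_equal(sk$segments$mean_net_disp_mm, rep(0, 5))
})

test_that("zero-noise generator amplitudes are recovered per segment exactly", {
  cfg <- synth_config_displacement(noise_sd_mm = 0,
                                   segment_ap_amplitude_mm = 1:5,
                                   segment_cc_amplitude_mm = (1:5) / 2,
                                   seed = 17)
  sk <- segment_kinetics(generate_cine(cfg)$cine)
  expect_equal(sk$segments$mean_max_disp_ap_mm, 1:5, tolerance = 1e-9)
  expect_equal(sk$segments$mean_max_disp_cc_mm, (1:5) / 2, tolerance = 1e-9)
  # strictly increasing EV -> TV
  expect_true(all(diff(sk$segments$mean_max_disp_ap_mm) > 0))
})

test_that("per-point differentials have length F-1 and velocities use dt", {
  cine <- random_cine(35, n_frames = 7L, n_points = 13L)
  sk <- segment_kinetics(cine, dt = 0.1)
  per_track <- dplyr::count(sk$per_point, point_index)
  expect_true(all(per_track$n == 6L))
  expect_equal(sk$per_point$vx, sk$per_point$dx / 0.1)
  expect_error(segment_kinetics(cine), class = "ctikin_domain_error") # no dt
})

test_that("motion patterns label amplitude and axis dominance", {
  thresholds <- list(t_low = 1, t_high = 10, r_lo = 0.5, r_hi = 2)
  mk <- function(ap, cc) {
    base <- cbind(seq(0, 24, length.out = 25), rep(0, 25))
    frames <- list(base, sweep(base, 2, -c(ap, cc)), base)
    segment_kinetics(cine_from_frames(frames, cti_range = c(12L, 25L)), dt = 0.04)
  }
  expect_equal(classify_motion_pattern(mk(0.01, 0.01), thresholds)$label,
               "hypokinetic")
  expect_equal(classify_motion_pattern(mk(20, 1), thresholds)$label,
               "hyperkinetic")
  expect_equal(classify_motion_pattern(mk(5, 0), thresholds)$label,
               "ap_dominant")
  expect_equal(classify_motion_pattern(mk(0, 5), thresholds)$label,
               "cc_dominant")
  # cohort-relative thresholds: quartiles of per-patient amplitude
  segs <- dplyr::bind_rows(lapply(1:8, function(i) {
    sk <- mk(i, i / 4); sk$segments$patient_id <- paste0("P", i); sk$segments
  }))
  th <- motion_thresholds(segs)
  expect_lt(th$t_low, th$t_high)
})
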