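test_that("constant background subtraction recovers the original signal", {
  d <- seq(0, 100, by = 0.25)
  bump <- 1000 * exp(-(d - 40)^2 / 8)
  p <- intensity_profile(d, bump + 7, "lane")
  out <- subtract_background(p, "constant")
  expect_equal(out$intensity_au, bump, tolerance = 1e-6)

  zero <- intensity_profile(d, rep(0, length(d)))
  expect_true(all(subtract_background(zero, "constant")$intensity_au == 0))
})

test_that("linear baseline subtraction preserves the band integral", {
  d <- seq(0, 100, by = 0.25)
  band <- 800 * exp(-(d - 50)^2 / 18)
  p <- intensity_profile(d, band + 10 + 0.5 * d, "lane")
  out <- subtract_background(p, "linear_baseline")
  reg <- d > 35 & d < 65
  expect_equal(trapz(d[reg], out$intensity_au[reg]),
               trapz(d[reg], band[reg]), tolerance = 0.02)
})

test_that("empty-lane subtraction requires an empty lane", {
  p <- intensity_profile(0:10, rep(1, 11))
  expect_error(subtract_background(p, "empty_lane"), "empty")
})

test_that("the smoothing spline reproduces polynomials and constants", {
  d <- seq(0, 100, by = 0.5)
  cubic <- 1 + 0.5 * d + 0.02 * d^2 + 1e-4 * d^3
  sm <- smooth_profile(intensity_profile(d, cubic))
  expect_equal(sm$intensity_au, cubic, tolerance = 1e-4)

  const <- smooth_profile(intensity_profile(d, rep(5, length(d))))
  expect_equal(const$intensity_au, rep(5, length(d)), tolerance = 1e-8)

  expect_error(smooth_profile(intensity_profile(1:10, rnorm(10))),
               "at least")
})

test_that("smoothing preserves the lane integral of a noisy render", {
  set <- sim_lane_set(8403, seed = 120)
  clean <- render_lane(set$frags, gel_render_config())
  noisy <- subtract_background(set$lane, "empty_lane", empty = set$empty)
  sm <- smooth_profile(noisy)
  expect_equal(trapz(sm$distance_mm, sm$intensity_au),
               trapz(clean$distance_mm, clean$intensity_au),
               tolerance = 0.03)
  # smoothing a smoothed profile is a near no-op
  sm2 <- smooth_profile(sm)
  expect_equal(trapz(sm2$distance_mm, sm2$intensity_au),
               trapz(sm$distance_mm, sm$intensity_au), tolerance = 1e-3)
})

test_that("interval resampling integrates the profile", {
  cal <- exact_calibration()
  d <- seq(0, 10, by = 0.1)
  flat <- resample_intervals(intensity_profile(d, rep(1, length(d))), cal)
  expect_equal(nrow(flat), 10L)
  expect_equal(flat$intensity_au, rep(1, 10), tolerance = 1e-10)

  # characteristic size is the calibrated size of the midpoint
  expect_equal(flat$size_nt, as.numeric(size_at(flat$mid_mm, cal)))

  p <- intensity_profile(seq(0, 120, 0.25),
                         500 * exp(-(seq(0, 120, 0.25) - 60)^2 / 50))
  iv <- resample_intervals(p, cal)
  expect_equal(sum(iv$intensity_au),
               trapz(p$distance_mm, p$intensity_au), tolerance = 0.01)
  expect_error(resample_intervals(p, cal, delta_d = 0), "delta_d")
})

test_that("estimates are stable under halving the interval width", {
  set <- sim_lane_set(8403, seed = 121)
  f1 <- quantify_set(set, delta_d = 1)
  f05 <- quantify_set(set, delta_d = 0.5)
  expect_equal(f05$estimate$N_corr, f1$estimate$N_corr, tolerance = 0.01)
})

test_that("cutoff lands where lane fluctuations meet the empty lane", {
  cal <- exact_calibration()
  # bands spanning ~48-72 mm with signal-dependent noise; nothing below
  gel <- gel_render_config(background = 50, poisson_gain = 30, seed = 77)
  lane <- render_lane(rep(c(3000, 5000, 8000), each = 400), gel, "lane")
  empty <- render_empty_lane(gel_render_config(background = 50,
                                               poisson_gain = 30,
                                               seed = 78))
  iv <- resample_intervals(smooth_profile(
    subtract_background(lane, "empty_lane", empty = empty)), cal)
  iv <- determine_cutoff(iv, lane, empty)
  co <- attr(iv, "cutoff")
  end_of_signal <- gel$a + gel$b * log(3000) + 3 * gel$band_sigma
  expect_lt(abs(co$d_max_mm - end_of_signal), 6)
  expect_true(all(iv$excluded[iv$mid_mm > co$d_max_mm]))
})

test_that("degenerate cutoff cases behave as specified", {
  cal <- exact_calibration()
  gel <- gel_render_config(background = 20, noise_sd = 4, seed = 5)
  lane <- render_empty_lane(gel, "fake_sample")
  iv <- resample_intervals(smooth_profile(lane), cal)

  # lane identical to empty: everything excluded from the start
  same <- determine_cutoff(iv, lane, lane)
  expect_lt(attr(same, "cutoff")$d_max_mm, 6)

  # unreachable threshold: d_max at the lane end, warning recorded
  expect_warning(all_in <- determine_cutoff(iv, lane, lane,
                                            ratio_threshold = 0),
                 "lane end")
  expect_equal(attr(all_in, "cutoff")$d_max_mm, max(lane$distance_mm))
  expect_false(any(all_in$excluded))

  # manual override wins
  man <- determine_cutoff(iv, d_max = 40)
  expect_equal(attr(man, "cutoff")$d_max_mm, 40)
  expect_true(attr(man, "cutoff")$manual)
})

test_that("sz_min decreases as d_max grows when b < 0", {
  cal <- exact_calibration()
  sz <- vapply(seq(40, 120, by = 10), function(dm)
    as.numeric(size_at(dm, cal)), numeric(1))
  expect_true(all(diff(sz) < 0))
})
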