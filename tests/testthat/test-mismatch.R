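# mismatch generation, response-curve estimation and offset calibration

test_that("mismatch draws are reproducible, truncated and well-centred", {
  mm0 <- sample_mismatch(100, sigma_off = 0, sigma_slope = 0, seed = 1)
  expect_true(all(mm0$offset_w == 0))
  expect_true(all(mm0$slope_s == 0.0185))

  mm <- sample_mismatch(2048, seed = 7)
  expect_identical(mm, sample_mismatch(2048, seed = 7))
  expect_true(all(mm$slope_s > 0))
  expect_true(all(abs(mm$slope_s - 0.0185) <= 3 * 0.0068 + 1e-12))
  # CLT bound on the sample mean of slopes
  expect_lt(abs(mean(mm$slope_s) - 0.0185), 3 * 0.0068 / sqrt(2048))
})

test_that("offset estimation recovers injected offsets to one code", {
  # noiseless curves: nominal crossing at 60, injected offset +10
  mm <- data.frame(neuron = 0:1, offset_w = c(0, 10), slope_s = 0.0185)
  cv <- synth_response_curves(mm, stochastic = FALSE)
  off <- estimate_offset(cv)
  expect_equal(off[1], 60, tolerance = 0.5)
  expect_lt(abs(off[2] - 70), 1)

  # a curve that never crosses the criterion is flagged
  flat <- list(codes = 0:255,
               rates = matrix(rep(1, 256), 1), input_rate = 1e4)
  class(flat) <- "ifat_curves"
  expect_warning(o <- estimate_offset(flat), "uncalibratable")
  expect_true(is.na(o))
})

test_that("slope estimation recovers the generative slope", {
  mm <- data.frame(neuron = 0:2, offset_w = c(-5, 0, 5),
                   slope_s = c(0.012, 0.0185, 0.025))
  cv <- synth_response_curves(mm, duration = 1, seed = 2)
  sl <- estimate_slope(cv)
  expect_lt(max(abs(sl - mm$slope_s)), 0.001)

  # a pure gain change (log offset) leaves the slope untouched
  cv2 <- cv
  cv2$rates <- cv$rates * 2
  expect_lt(max(abs(estimate_slope(cv2, sat_fraction = 1) -
                    estimate_slope(cv))), 0.002)
})

test_that("ideal PWAM neuron shows the log10(2)/16 response slope", {
  # event-engine weight sweep in the amplitude-modulated regime: rate is
  # proportional to conductance, so the decades-per-code slope of the
  # response matches the conductance ladder
  np <- test_neuron()
  cv <- measure_response_curve(np, codes = seq(64L, 96L, by = 8L),
                               input_rate = 1e4, duration = 0.4, seed = 17)
  sl <- estimate_slope(cv, min_points = 3)
  expect_lt(abs(sl - log10(2) / 16), 0.004)
})

test_that("calibration aligns offsets to the mean and is idempotent", {
  expect_equal(calibrate(c(3, 3, 3))$correction, c(0L, 0L, 0L))
  expect_equal(calibrate(c(-5, 5))$correction, c(5L, -5L))

  # calibration sweeps integrate 16 s per code: offset interpolation for
  # the shallowest-slope neurons is counting-noise limited
  mm <- sample_mismatch(256, seed = 31)
  cv <- synth_response_curves(mm, duration = 16, seed = 32)
  off_pre <- estimate_offset(cv)
  cal <- calibrate(off_pre)
  cv_post <- synth_response_curves(mm, duration = 16, seed = 33,
                                   correction = cal$correction)
  off_post <- estimate_offset(cv_post)
  # re-centred curves: spread shrinks by an order of magnitude
  expect_lt(stats::sd(off_post, na.rm = TRUE),
            0.1 * stats::sd(off_pre, na.rm = TRUE))
  # idempotence (a property of the estimator/correction pair, checked on
  # noiseless measurements): recalibrating gives corrections of 0 +/- 1
  cvn <- synth_response_curves(mm, stochastic = FALSE)
  caln <- calibrate(estimate_offset(cvn))
  cvn2 <- synth_response_curves(mm, stochastic = FALSE,
                                correction = caln$correction)
  cal2 <- calibrate(estimate_offset(cvn2))
  expect_true(all(abs(cal2$correction) <= 1))
})

test_that("end-to-end core calibration returns a full table", {
  cal <- calibrate_core(n = 64, seed = 44)
  expect_s3_class(cal, "ifat_calibration")
  expect_named(cal, c("neuron", "offset_est", "slope_est", "correction"))
  expect_equal(nrow(cal), 64)
  mm <- attr(cal, "mismatch")
  expect_equal(stats::cor(cal$offset_est - 60, mm$offset_w), 1,
               tolerance = 0.05)
})

test_that("corrections pre-distort routing-table strengths with clamping", {
  tab <- routing_table(pre_id = c(0, 1, 2), core = 0,
                       neuron = c(0, 1, 2), syn_type = 2,
                       strength = c(10, 128, 250))
  cal <- calibrate(c(10, 0, -10))
  cal$correction <- c(20L, 0L, -20L)  # force clamping at both ends
  out <- apply_calibration(tab, cal, ids = c(0, 1, 2))
  expect_equal(out$strength, c(0L, 128L, 255L))
})
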