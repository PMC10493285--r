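# stimulus/kernel generation, encoders and projections (rate-model mode;
# cross-mode agreement against the event engine lives in the acceptance
# suite)

test_that("gabor kernels are zero-mean with the grid symmetries", {
  for (th in c(0, 45, 90, 135)) {
    g <- gabor_patch(th)
    expect_equal(dim(g), c(15, 15))
    expect_equal(sum(g), 0, tolerance = 1e-12)
  }
  expect_equal(t(gabor_patch(0)), gabor_patch(90), tolerance = 1e-9)
  expect_equal(gabor_patch(30), gabor_patch(210), tolerance = 1e-9)
  expect_error(gabor_patch(0, size = 14), "size")
})

test_that("bar stimuli are periodic, centred and mass-preserving", {
  expect_equal(bar_stimulus(0), bar_stimulus(180), tolerance = 1e-9)
  angles <- seq(0, 175, by = 5)
  mass <- vapply(angles, function(a) sum(bar_stimulus(a)), numeric(1))
  for (a in angles) {
    b <- bar_stimulus(a)
    expect_equal(b[8, 8], max(b))     # bar passes through the center
  }
  expect_lt((max(mass) - min(mass)) / mean(mass), 0.1)  # +/- 5% of mean
})

test_that("stimulus encoder maps darkest to 0, brightest to 63 linearly", {
  b <- bar_stimulus(30)
  r <- encode_stimulus(b)
  expect_equal(min(r), 0)
  expect_equal(max(r), 63 * 31.25)
  expect_equal(encode_stimulus(matrix(0, 15, 15)), matrix(0, 15, 15))
  # linearity: doubling exactly-representable intensities doubles rates
  patch <- matrix(seq(0, 56, by = 8), 8, 8)[1:8, 1:8]
  r1 <- encode_stimulus(patch, max_intensity = 255)
  r2 <- encode_stimulus(2 * patch, max_intensity = 255)
  expect_equal(r2, 2 * r1)
})

test_that("kernel encoder realizes signed weights as nearby PWAM codes", {
  g <- gabor_patch(45)
  k <- encode_kernel(g)
  expect_equal(sign(k$weight)[abs(g) > 0.05], sign(g)[abs(g) > 0.05])
  expect_equal(max(abs(k$weight)), 160, tolerance = 0.04)
  # realized effective weight within a half mantissa step of its target
  tgt <- g / max(abs(g)) * 160
  on <- !is.na(k$byte)
  expect_lt(max(abs(k$weight[on] - tgt[on]) / abs(tgt[on])), 1 / 32)
  expect_true(all(k$byte[on] >= 0 & k$byte[on] <= 255))
  expect_error(encode_kernel(matrix(0, 15, 15)), "zero")
})

test_that("patch projection is selective for the kernel orientation", {
  p <- rate_model_params(G_wnom = 0.03)
  k90 <- encode_kernel(gabor_patch(90))
  aligned <- project_patch(encode_stimulus(bar_stimulus(90)), k90,
                           mode = "rate_model", p = p)
  ortho <- project_patch(encode_stimulus(bar_stimulus(0)), k90,
                         mode = "rate_model", p = p)
  expect_gt(aligned, 0)
  expect_lt(ortho, 0.05 * aligned)
  # uniform stimulus on a zero-mean kernel cancels (up to code rounding)
  unif <- project_patch(matrix(1000, 15, 15), k90, mode = "rate_model", p = p)
  expect_lt(unif, 0.02 * aligned)
  expect_error(project_patch(matrix(0, 5, 5), k90), "shape")
})

test_that("rate-model tuning curves peak at the kernel orientation", {
  p <- rate_model_params(G_wnom = 0.03)
  for (th in c(0, 45, 90, 135)) {
    tc <- tuning_curve(th, trials = 1, mode = "rate_model", p = p)
    expect_equal(nrow(tc), 37)
    peaks <- tc$angle[tc$mean == max(tc$mean)]
    # 180-degree periodicity folds 0 and 180 together
    dist <- min(abs(((peaks - th + 90) %% 180) - 90))
    expect_lte(dist, 5)
    expect_equal(tc$mean[tc$angle == 0], tc$mean[tc$angle == 180],
                 tolerance = 1e-9)
  }
})

test_that("boundary maps highlight edges and transform equivariantly", {
  p <- rate_model_params(G_wnom = 0.03)
  # constant image: nothing to detect
  bd0 <- detect_boundaries(matrix(128, 20, 20), thetas = c(0, 90), p = p)
  expect_true(all(unlist(bd0$rates) == 0))
  # vertical step edge: the odd-phase (edge-selective) vertical kernel
  # peaks on the edge column
  img <- matrix(30, 31, 31)
  img[, 16:31] <- 220
  bd <- detect_boundaries(img, thetas = c(90), p = p, phase = pi / 2)
  m <- bd$rates[[1]]
  expect_true(all(abs(apply(m, 1, which.max) - 8.5) <= 1))  # edge at center
  # rotating the image by 90 degrees and swapping the 0/90 kernels
  # transposes the maps
  set.seed(8)
  img2 <- matrix(runif(625, 0, 255), 25, 25)
  bd_a <- detect_boundaries(img2, thetas = c(0, 90), p = p)
  bd_b <- detect_boundaries(t(img2), thetas = c(0, 90), p = p)
  expect_equal(bd_a$rates[[1]], t(bd_b$rates[[2]]), tolerance = 1e-9)
  expect_equal(bd_a$rates[[2]], t(bd_b$rates[[1]]), tolerance = 1e-9)
  expect_error(detect_boundaries(matrix(1, 10, 10), p = p), "smaller")
})

test_that("the synthetic scene has the documented shape and range", {
  img <- synthetic_test_image()
  expect_equal(dim(img), c(75, 113))
  expect_true(all(img >= 0 & img <= 255))
  expect_gt(stats::sd(img), 10)   # non-trivial contrast
})
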