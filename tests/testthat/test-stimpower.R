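test_that("the Gaussian envelope attenuates as advertised", {
  d <- experiment_design()
  ones <- stimulus_image(matrix(1, d$n_px, d$n_px), d$n_px / d$field_size)
  env <- apply_envelope(ones, d)
  # reconstruct pixel-centre coordinates independently
  ppd <- d$n_px / d$field_size
  ax <- ((seq_len(d$n_px) - 1) + 0.5 - d$n_px / 2) / ppd
  i0 <- which.min(abs(ax)) # pixel nearest the centre
  r2 <- ax[i0]^2 + ax^2
  expect_equal(env$pixels[i0, ], exp(-r2 / (2 * d$envelope_sd^2)),
               tolerance = 1e-12)
  # applying the envelope twice squares it (not idempotent)
  twice <- apply_envelope(env, d)
  expect_true(all(twice$pixels <= env$pixels + 1e-15))
  expect_gt(max(env$pixels - twice$pixels), 0.1)
})

test_that("grating profiles peak at the grating orientation", {
  d <- experiment_design()
  for (th in c(0, 30, 60, 90, 120, 150)) {
    p <- orientation_power_profile(render_gabor(th, 0.4, 0, d), d)
    expect_equal(attr(p, "orientation")[which.max(p)], th)
  }
  # 10 degrees clockwise of vertical lands within one bin of 100
  p <- orientation_power_profile(render_gabor(100, 0.4, 0.7, d), d)
  expect_lte(abs(attr(p, "orientation")[which.max(p)] - 100), 3)
  # annulus pooling agrees on the peak
  pa <- orientation_power_profile(render_gabor(60, 0.4, 0, d), d,
                                  method = "annulus")
  # annulus pooling quantizes angles to spectrum cells: within one bin
  expect_lte(abs(attr(pa, "orientation")[which.max(pa)] - 60), 3)
})

test_that("profile peak agrees with a raw-FFT oracle", {
  d <- experiment_design()
  img <- render_gabor(120, 0.4, 1.1, d)
  # oracle: locate the strongest spectral cell directly in the raw FFT and
  # convert its position to an axial grating orientation
  P <- Mod(stats::fft(img$pixels))^2
  n <- d$n_px
  f <- c(0:(n / 2 - 1), -(n / 2):-1) # cycles/image per index
  P[1, 1] <- 0
  ij <- arrayInd(which.max(P), dim(P))
  fy <- f[ij[1]]; fx <- f[ij[2]]
  expect_equal(sqrt(fx^2 + fy^2), d$spatial_freq * d$field_size,
               tolerance = 0.1)
  ori <- (atan2(fy, fx) * 180 / pi + 90) %% 180
  prof <- orientation_power_profile(img, d)
  # the oracle's angle is quantized to integer spectrum cells, whose spacing
  # at radius 7 cycles/image is atan(1/7) ~ 8 degrees: agree within half that
  # plus one profile bin
  expect_lte(min(abs(attr(prof, "orientation")[which.max(prof)] - ori),
                 180 - abs(attr(prof, "orientation")[which.max(prof)] - ori)),
             5)
})

test_that("white-noise profiles are flat in expectation", {
  d <- experiment_design()
  m <- colMeans(noise_profile_stack(1000, d, seed = 8))
  expect_true(all(abs(m / mean(m) - 1) < 0.15))
})

test_that("profiles are invariant to circular translation of the noise", {
  d <- experiment_design()
  set.seed(2)
  px <- matrix(runif(d$n_px^2, -0.6, 0.6), d$n_px, d$n_px)
  sh <- px[c(6:d$n_px, 1:5), c(10:d$n_px, 1:9)]
  p1 <- orientation_power_profile(stimulus_image(px, 1), d)
  p2 <- orientation_power_profile(stimulus_image(sh, 1), d)
  expect_equal(as.numeric(p1), as.numeric(p2), tolerance = 1e-8)
})

test_that("relative band power normalizes means over the band", {
  flat <- structure(rep(2, 60), orientation = orientation_bins())
  expect_equal(relative_band_power(flat), 1)
  one <- structure(c(rep(0, 30), 5, rep(0, 29)),
                   orientation = orientation_bins()) # bin centre 90
  expect_equal(relative_band_power(one), 60 / 21) # 21 bins in [60, 120]
  expect_equal(relative_band_power(one, mode = "sums"), 1)
  outside <- structure(c(5, rep(0, 59)), orientation = orientation_bins())
  expect_equal(relative_band_power(outside), 0)
  expect_error(relative_band_power(structure(rep(0, 60),
                                             orientation = orientation_bins())),
               "zero total power")
  expect_error(relative_band_power(flat, band = c(-10, 60)), "band")
})

test_that("classification images difference condition means exactly", {
  set.seed(3)
  pr <- matrix(rexp(200 * 60), 200, 60)
  attr(pr, "orientation") <- orientation_bins()
  resp <- rep(c(1, 0), 100)
  ci <- classification_image(pr, resp)
  expect_equal(as.numeric(ci),
               colMeans(pr[resp == 1, ]) - colMeans(pr[resp == 0, ]))
  expect_equal(attr(ci, "n_alarm"), 100)
  # label swap negates exactly
  expect_equal(as.numeric(classification_image(pr, 1 - resp)),
               -as.numeric(ci))
  # linearity: pooled CI equals the count-weighted combination of subgroups
  m <- rep(c(TRUE, FALSE), each = 100)
  ci_a <- classification_image(pr, resp, m)
  ci_b <- classification_image(pr, resp, !m)
  na <- c(attr(ci_a, "n_alarm"), attr(ci_b, "n_alarm"))
  nr <- c(attr(ci_a, "n_reject"), attr(ci_b, "n_reject"))
  alarm_pool <- (na[1] * (as.numeric(ci_a) + colMeans(pr[m & !resp, ])) +
                   na[2] * (as.numeric(ci_b) + colMeans(pr[!m & !resp, ]))) /
    sum(na)
  rej_pool <- (nr[1] * colMeans(pr[m & !resp, ]) +
                 nr[2] * colMeans(pr[!m & !resp, ])) / sum(nr)
  expect_equal(as.numeric(ci), alarm_pool - rej_pool, tolerance = 1e-12)
  # random labels on identical distributions: small deltas everywhere
  se <- sqrt(apply(pr, 2, var) * (1 / 100 + 1 / 100))
  expect_true(all(abs(as.numeric(ci)) < 4 * se))
  expect_error(classification_image(pr, rep(1, 200)), "rejection")
})

test_that("average vectors summarize classification images correctly", {
  th <- orientation_bins()
  one <- structure(c(rep(0, 30), 5, rep(0, 29)), orientation = th)
  expect_equal(average_vector(one)$angle, 90)
  sym <- structure(exp(-(th - 90)^2 / 200), orientation = th)
  expect_equal(average_vector(sym)$angle, 90, tolerance = 1e-8)
  bump <- structure(exp(-((th - 110)^2) / (2 * 6^2)), orientation = th)
  expect_lte(abs(average_vector(bump)$angle - 110), 3)
  # invariance to uniform scaling
  av1 <- average_vector(bump)
  av2 <- average_vector(structure(7 * unclass(bump), orientation = th))
  expect_equal(av1$angle, av2$angle)
  expect_equal(7 * av1$magnitude, av2$magnitude)
  # negative-bin conventions move the angle only slightly for a clean bump
  noisy <- structure(exp(-((th - 105)^2) / 72) - 0.1, orientation = th)
  a_shift <- average_vector(noisy, negative = "shift")$angle
  a_clip <- average_vector(noisy, negative = "clip")$angle
  expect_lt(abs(a_shift - a_clip), 6)
  expect_error(average_vector(structure(rep(0, 60), orientation = th)),
               "all-zero")
  # axial angle doubling keeps a symmetric bump at its centre
  expect_equal(average_vector(bump, double_angle = TRUE)$angle, 110,
               tolerance = 3)
})

test_that("conditional shifts combine CW and CCW displacements", {
  expect_equal(conditional_shift(90, 90), 0)
  expect_equal(conditional_shift(100, 80), 10)
  expect_equal(conditional_shift(c(95, 100), c(85, 90)), c(5, 5))
  expect_equal(conditional_shift(104, 88), 8)
  expect_error(conditional_shift(100, c(80, 90)), "pair up")
  expect_error(conditional_shift(NA, 80), "missing")
})
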