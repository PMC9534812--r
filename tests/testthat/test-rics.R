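test_that("the 2D Gaussian shape factor is 2^(-3/2)", {
  expect_identical(gamma_2d(), 2^(-3 / 2))
})

test_that("moving-average correction is exact on constants and drifts", {
  g <- raster_geom()
  const <- image_series(array(7, c(5, 6, 6)), g)
  expect_equal(moving_average_correct(const)$data[[1]],
               const$data[[1]])

  set.seed(3)
  static <- array(rpois(1 * 6 * 6, 50), c(1, 6, 6))[rep(1, 7), , ]
  noise <- array(rnorm(7 * 6 * 6, 0, 3), c(7, 6, 6))
  a0 <- static + 100 + noise
  drift <- a0 + outer(1:7, array(2, c(6, 6)))        # + 2 per frame
  s0 <- image_series(a0, g, allow_negative = TRUE)
  s1 <- image_series(drift, g, allow_negative = TRUE)
  c0 <- moving_average_correct(s0)$data[[1]]
  c1 <- moving_average_correct(s1)$data[[1]]
  # interior frames: a symmetric window cancels a linear drift entirely, up
  # to the constant shift of the global mean
  d <- (c1 - c0)[2:6, , ]
  expect_lt(diff(range(d)), 1e-9)
})

test_that("moving-average correction matches the per-pixel definition", {
  g <- raster_geom()
  set.seed(4)
  a <- array(rpois(6 * 8 * 8, 30), c(6, 8, 8))
  s <- image_series(a, g)
  out <- moving_average_correct(s)$data[[1]]
  gm <- mean(a)
  for (pt in list(c(1, 1), c(3, 5), c(8, 8))) for (f in 1:6) {
    win <- max(1, f - 1):min(6, f + 1)
    expect_equal(out[f, pt[1], pt[2]],
                 a[f, pt[1], pt[2]] - mean(a[win, pt[1], pt[2]]) + gm,
                 tolerance = 1e-12)
  }
  expect_error(moving_average_correct(image_series(a[1:2, , , drop = FALSE], g)),
               "at least")
})

test_that("masked FFT correlation equals the direct sum to 1e-10", {
  g <- raster_geom()
  set.seed(5)
  a <- array(rpois(3 * 12 * 12, 25), c(3, 12, 12))
  s <- image_series(a, g)
  # arbitrary mask with holes
  set.seed(6)
  M <- matrix(runif(144) > 0.25, 12, 12)
  acf <- spatial_correlate(s, mask_stack(M), max_xi = 5L, max_psi = 4L)
  ref <- direct_spatial_acf(s, M, 5L, 4L)
  expect_equal(acf$counts, ref$counts, ignore_attr = TRUE)
  expect_lt(max(abs(acf$G - ref$G), na.rm = TRUE), 1e-10)
  # full-true mask path too
  Mf <- matrix(TRUE, 12, 12)
  acff <- spatial_correlate(s, mask_stack(Mf), max_xi = 5L, max_psi = 4L)
  reff <- direct_spatial_acf(s, Mf, 5L, 4L)
  expect_lt(max(abs(acff$G - reff$G), na.rm = TRUE), 1e-10)
})

test_that("white noise decorrelates away from the zero lag", {
  g <- raster_geom()
  set.seed(7)
  a <- array(rpois(12 * 48 * 48, 100), c(12, 48, 48))
  s <- image_series(a, g)
  acf <- spatial_correlate(s, mask_stack(matrix(TRUE, 48, 48)),
                           max_xi = 6L, max_psi = 6L)
  off <- acf$G
  off[acf$psi == 0, acf$xi == 0] <- NA
  expect_lt(max(abs(off), na.rm = TRUE), 5e-3)
  expect_gt(acf$G[acf$psi == 0, acf$xi == 0], 5e-3)
})

test_that("a static Gaussian blob yields its analytic autocorrelation width", {
  g <- raster_geom()
  img <- matrix(0, 48, 48)
  sigma <- 2.5
  img <- add_test_spot(img, 24, 24, amp = 1000, sigma = sigma)
  a <- array(0, c(2, 48, 48)); a[1, , ] <- img; a[2, , ] <- img
  s <- image_series(a, g)
  acf <- spatial_correlate(s, mask_stack(matrix(TRUE, 48, 48)),
                           max_xi = 12L, max_psi = 2L)
  # correlation of a Gaussian with itself is a Gaussian of variance 2 sigma^2;
  # for a blob fully interior to every valid-pair region, mean subtraction
  # contributes the exactly-known pedestal 1 - 2 npix / count per lag
  # and the per-pair-count normalization rescales each lag by 1 / count
  prof <- acf$G[acf$psi == 0, acf$xi >= 0]
  cnt <- acf$counts[acf$psi == 0, acf$xi >= 0]
  prof <- (prof - (1 - 2 * 48 * 48 / cnt)) * cnt
  prof <- prof / prof[1]
  xi <- 0:12
  fit <- stats::nls(prof ~ exp(-xi^2 / (2 * s2)), start = list(s2 = 10))
  expect_equal(coef(fit)[["s2"]], 2 * sigma^2, tolerance = 0.05)
})

test_that("lags without valid pairs are undefined", {
  g <- raster_geom()
  set.seed(8)
  a <- array(rpois(2 * 10 * 10, 20), c(2, 10, 10))
  M <- matrix(FALSE, 10, 10); M[1:2, 1:2] <- TRUE
  acf <- spatial_correlate(image_series(a, g), mask_stack(M),
                           max_xi = 5L, max_psi = 5L)
  expect_true(is.na(acf$G[acf$psi == 5, acf$xi == 5]))
  expect_false(is.na(acf$G[acf$psi == 0, acf$xi == 1]))
})

test_that("the raster fit recovers a noiseless model surface exactly", {
  g <- raster_geom()
  xi <- -32:32; psi <- -16:16
  G <- outer(psi, xi, function(p, x)
    pentafluct:::rics_model(x, p, N = 50, D = 0.3, g))
  acf <- structure(list(G = G, sd = G * 0 + 1e-4, counts = G * 0 + 100,
                        xi = xi, psi = psi, n_frames = 10, delta_f = NULL),
                   class = "spatial_acf")
  fit <- fit_rics(acf, g)
  expect_true(fit$converged)
  expect_equal(fit$N, 50, tolerance = 1e-6)
  expect_equal(fit$D, 0.3, tolerance = 1e-6)
  # the model amplitude at zero lag is gamma / N
  expect_equal(pentafluct:::rics_model(0, 0, 50, 0.3, g), gamma_2d() / 50)
})

test_that("fitted D is invariant to uniform intensity rescaling", {
  s <- small_confocal_series()
  m <- mask_stack(matrix(TRUE, 64, 64))
  f1 <- fit_rics(spatial_correlate(moving_average_correct(s), m),
                 s$geometry)
  s3 <- image_series(lapply(s$data, function(a) 3 * a), s$geometry)
  f3 <- fit_rics(spatial_correlate(moving_average_correct(s3), m),
                 s$geometry)
  expect_equal(f3$D, f1$D, tolerance = 1e-8)
  expect_equal(f3$N, f1$N, tolerance = 1e-8)
})

test_that("a negative-amplitude surface is rejected", {
  g <- raster_geom()
  xi <- -8:8; psi <- -4:4
  G <- matrix(-0.1, length(psi), length(xi))
  acf <- structure(list(G = G, sd = G * 0 + 1e-3, counts = G * 0 + 10,
                        xi = xi, psi = psi, n_frames = 4, delta_f = NULL),
                   class = "spatial_acf")
  expect_error(fit_rics(acf, g), "non-positive")
})

test_that("moving-average filter lag weights match the interior analysis", {
  w <- pentafluct:::ma_lag_weights(1000L, 1L)
  # interior frames: coefficients (2/3, -8/9, 2/9) up to end effects
  expect_equal(w, c(2 / 3, -8 / 9, 2 / 9), tolerance = 2e-3)
  # the filter output has zero sum against a constant: weights sum to the
  # variance multiplier of white noise, always positive and below 1
  expect_lt(w[1], 1)
  w5 <- pentafluct:::ma_lag_weights(1000L, 5L)
  expect_equal(w5[1], 10 / 11, tolerance = 2e-3)
  expect_length(w5, 11L)
})

test_that("brightness is intensity over bias-corrected N", {
  s <- small_confocal_series()
  m <- mask_stack(matrix(TRUE, 64, 64))
  fit <- structure(list(N = 50, D = 0.3, converged = TRUE),
                   class = "rics_fit")
  br <- brightness(s, m, fit)
  F_khz <- mean(s$data[[1]]) / s$geometry$pixel_dwell / 1000
  expect_equal(br$F_khz, F_khz)
  expect_equal(br$bias_factor, 2 / 3)
  expect_equal(br$epsilon, F_khz / (50 * 2 / 3))
  # overriding the bias factor
  br1 <- brightness(s, m, fit, bias_factor = 1)
  expect_equal(br1$epsilon, F_khz / 50)
})

test_that("brightness refuses camera data", {
  g <- cam_geom()
  s <- image_series(array(10, c(3, 8, 8)), g)
  fit <- structure(list(N = 5, D = 0.1, converged = TRUE), class = "rics_fit")
  expect_error(brightness(s, mask_stack(matrix(TRUE, 8, 8)), fit),
               "raster")
})
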