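# Direct per-pixel temporal correlation oracle (Eq. written out literally,
# unbiased T - m normalization).
direct_temporal_cf <- function(a1, a2, M, max_lag) {
  nf <- dim(a1)[1]
  idx <- which(M)
  curves <- sapply(idx, function(i) {
    rc <- arrayInd(i, dim(M))
    x1 <- a1[, rc[1], rc[2]]; x2 <- a2[, rc[1], rc[2]]
    m1 <- mean(x1); m2 <- mean(x2)
    d1 <- x1 - m1; d2 <- x2 - m2
    vapply(0:max_lag, function(m)
      sum(d1[seq_len(nf - m)] * d2[seq_len(nf - m) + m]) /
        (nf - m) / (m1 * m2), numeric(1))
  })
  rowMeans(curves)
}

test_that("frame-mean detrending equalizes frame means", {
  g <- cam_geom()
  set.seed(21)
  a <- array(rpois(10 * 8 * 8, 30), c(10, 8, 8))
  a[4, , ] <- a[4, , ] + 15                 # flicker frame
  out <- detrend_frames(image_series(a, g))$data[[1]]
  fm <- apply(out, 1, mean)
  expect_equal(fm, rep(mean(a), 10), tolerance = 1e-12)
  # per-pixel fluctuations within a frame are untouched
  expect_equal(out[2, , ] - mean(out[2, , ]), a[2, , ] - mean(a[2, , ]))
  expect_error(detrend_frames(image_series(a[1, , , drop = FALSE], g)),
               "at least 2")
})

test_that("the FFT temporal correlator equals the direct per-pixel sum", {
  g <- cam_geom()
  set.seed(22)
  a <- array(rpois(30 * 6 * 6, 40), c(30, 6, 6))
  s <- image_series(a, g)
  set.seed(23)
  M <- matrix(runif(36) > 0.3, 6, 6)
  cf <- temporal_correlate(s, mask = mask_stack(M), max_lag = 10L)
  ref <- direct_temporal_cf(a, a, M, 10L)
  expect_equal(cf$G, ref, tolerance = 1e-12)
  expect_equal(cf$lag_s, (0:10) * 0.08)
  expect_identical(cf$kind, "auto")
  expect_identical(cf$n_pixels, sum(M))
})

test_that("cross-correlation of independent channels is flat", {
  g <- cam_geom(channels = 2L)
  set.seed(24)
  a1 <- array(rpois(200 * 12 * 12, 50), c(200, 12, 12))
  a2 <- array(rpois(200 * 12 * 12, 50), c(200, 12, 12))
  s <- image_series(list(a1, a2), g)
  M <- mask_stack(matrix(TRUE, 12, 12))
  ccf <- temporal_correlate(s, s, M, max_lag = 8L,
                            channel_1 = 1L, channel_2 = 2L)
  expect_identical(ccf$kind, "cross")
  ref <- direct_temporal_cf(a1, a2, matrix(TRUE, 12, 12), 8L)
  expect_equal(ccf$G, ref, tolerance = 1e-12)
  expect_lt(max(abs(ccf$G)), 2e-3)
  # the autocorrelation of the same data has a clear zero-lag peak
  acf <- temporal_correlate(s, mask = M, max_lag = 8L)
  expect_gt(acf$G[1], 5e-3)
  expect_lt(max(abs(acf$G[-1])), 2e-3)
})

test_that("zero-mean pixels are skipped with a warning", {
  g <- cam_geom()
  set.seed(25)
  a <- array(rpois(20 * 4 * 4, 30), c(20, 4, 4))
  a[, 1, 1] <- 0
  s <- image_series(a, g, allow_negative = TRUE)
  expect_warning(cf <- temporal_correlate(s, mask = mask_stack(matrix(TRUE, 4, 4)),
                                          max_lag = 5L),
                 "zero-mean")
  expect_identical(cf$n_pixels, 15L)
  M1 <- matrix(FALSE, 4, 4); M1[2, 2] <- TRUE
  expect_error(temporal_correlate(s, mask = mask_stack(M1), max_lag = 5L),
               "fewer than 2")
})

test_that("the temporal fit is exact on a noiseless model curve", {
  g <- cam_geom()
  w2 <- g$focal_waist^2
  lags <- 0:20
  tau <- lags * g$frame_time
  A_D <- 0.04; D <- 0.07; A_0 <- 0.003
  G <- A_D / (1 + 4 * D * tau / w2) + A_0
  cf <- structure(list(lag_s = tau, lags = lags, G = G,
                       ci95 = rep(1e-4, length(lags)), n_pixels = 100L,
                       kind = "auto", frame_time = g$frame_time),
                  class = "temporal_cf")
  fit <- fit_tics(cf, g)
  expect_true(fit$converged)
  expect_equal(fit$A_D, A_D, tolerance = 1e-6)
  expect_equal(fit$D, D, tolerance = 1e-6)
  expect_equal(fit$A_0, A_0, tolerance = 1e-6)
  expect_equal(fit$amplitude0, A_D + A_0, tolerance = 1e-6)
  expect_error(fit_tics(cf, g, max_lag_frames = 3L), "fewer than 4")
})

test_that("camera diffusion is recovered from a rendered scene", {
  g <- camera_geometry()
  D_true <- 0.089
  p <- scene_params(box_size = 64 * g$pixel_size * 1.25, density = 20,
                    D = D_true, brightness = 100, background = 0.5)
  tr <- simulate_trajectories(p, 150 * g$frame_time + 0.1, g$frame_time,
                              seed = 31, store = "lazy")
  s <- render_camera_series(tr, g, 150, seed = 31, dim = c(64, 64))
  cf <- temporal_correlate(detrend_frames(s),
                           mask = mask_stack(matrix(TRUE, 64, 64)),
                           max_lag = 15L)
  fit <- fit_tics(cf, g)
  expect_true(fit$converged)
  expect_lt(abs(fit$D - D_true) / D_true, 0.30)
})

test_that("relative cross-correlation reduces and floors correctly", {
  mk <- function(A_D, A_0 = 0) {
    structure(list(A_D = A_D, D = 0.05, A_0 = A_0,
                   amplitude0 = A_D + A_0, converged = TRUE),
              class = "tics_fit")
  }
  r <- relative_cc(mk(0.04), mk(0.04), mk(0.04))
  expect_equal(r$rel_cc, 1)
  r2 <- relative_cc(mk(0.02), mk(0.05), mk(0.03))
  expect_equal(r2$rel_cc, 0.02 / 0.04)
  expect_warning(r3 <- relative_cc(mk(-0.01), mk(0.04), mk(0.04)),
                 "floored")
  expect_equal(r3$rel_cc, 0)
  expect_error(relative_cc(mk(0.02), mk(-0.05), mk(0.03)), "not positive")
})
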