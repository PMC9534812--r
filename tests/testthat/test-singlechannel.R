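test_that("the low-pass kernel is normalized and attenuates -3 dB at cutoff", {
  dt <- 1e-4
  tr <- current_trace(rnorm(5000), dt)
  f <- gaussian_lowpass(tr, cutoff = 100)
  kern <- attr(f, "kernel")
  expect_equal(sum(kern), 1, tolerance = 1e-12)
  expect_equal(rev(kern), kern)          # symmetric, zero phase
  # drive with a pure sine at the cutoff: amplitude gain ~ 1/sqrt(2)
  gain_at <- function(freq) {
    tt <- (0:49999) * dt
    s <- current_trace(sin(2 * pi * freq * tt), dt)
    out <- gaussian_lowpass(s, cutoff = 100)$current
    # discard filter edges before measuring the amplitude
    max(abs(out[5000:45000]))
  }
  expect_equal(gain_at(100), 1 / sqrt(2), tolerance = 0.02)
  expect_gt(gain_at(10), 0.99)
  expect_lt(gain_at(400), 0.01)
  expect_error(gaussian_lowpass(tr, cutoff = 6000), "Nyquist")
})

test_that("filtering preserves plateau levels and reduces noise variance", {
  dt <- 2e-4
  set.seed(71)
  levels <- rep(c(0, 4), each = 2500)
  tr <- current_trace(levels + rnorm(5000, 0, 0.5), dt)
  f <- gaussian_lowpass(tr, cutoff = 100)
  # plateau interiors keep their mean
  expect_equal(mean(f$current[500:2000]), 0, tolerance = 0.05)
  expect_equal(mean(f$current[3000:4500]), 4, tolerance = 0.05)
  # white-noise variance shrinks by the kernel power sum(k^2)
  kern <- attr(f, "kernel")
  set.seed(72)
  noise <- current_trace(rnorm(2e5, 0, 1), dt)
  v <- var(gaussian_lowpass(noise, cutoff = 100)$current)
  expect_equal(v, sum(kern^2), tolerance = 0.02)
})

test_that("the double-Gaussian window analysis recovers the open amplitude", {
  p <- channel_sim_params(baseline = 0, amplitude = 4, noise_sd = 0.5)
  tr <- simulate_channel_trace(p, 2, seed = 81)
  f <- gaussian_lowpass(tr, cutoff = 500)
  w <- analyze_window(f, c(0.2, 1.0))
  expect_false(w$flagged)
  expect_equal(w$mean_current_pA, 4, tolerance = 0.25)
  expect_lt(abs(w$baseline_pA), 0.25)
  # a holding-potential offset shifts both components but not the mean
  tr2 <- current_trace(tr$current - 30, tr$dt)
  w2 <- analyze_window(gaussian_lowpass(tr2, cutoff = 500), c(0.2, 1.0))
  expect_equal(w2$mean_current_pA, w$mean_current_pA, tolerance = 0.05)
  expect_equal(w2$baseline_pA, w$baseline_pA - 30, tolerance = 0.25)
})

test_that("windows without openings are flagged, not fitted", {
  set.seed(82)
  tr <- current_trace(rnorm(5000, 0, 0.4), 2e-4)
  w <- analyze_window(tr, c(0, 1))
  expect_true(w$flagged)
  expect_true(is.na(w$mean_current_pA))
  expect_error(analyze_window(tr, c(5, 6)), "outside")
})

test_that("current grouping minimizes the number of groups in 1D", {
  g <- group_currents(c(1.0, 1.4, 1.9, 4.0, 4.5, 8.2), tolerance = 1)
  expect_length(g, 3)
  expect_equal(g[[1]]$members, c(1.0, 1.4, 1.9))
  expect_equal(g[[2]]$mean_pA, 4.25)
  expect_equal(g[[3]]$members, 8.2)
  # brute-force minimal-partition oracle on random sets
  min_groups <- function(v, tol) {
    s <- sort(v); k <- 1L; first <- s[1]
    for (x in s[-1]) if (x - first > tol) { k <- k + 1L; first <- x }
    k
  }
  set.seed(83)
  for (i in 1:20) {
    v <- runif(sample(3:12, 1), 0, 10)
    expect_length(group_currents(v, tolerance = 1.5), min_groups(v, 1.5))
  }
  expect_length(group_currents(numeric(0)), 0)
})

test_that("grouping skips flagged windows", {
  mk <- function(mean_pA, flagged = FALSE)
    structure(list(mean_current_pA = mean_pA, flagged = flagged),
              class = "current_window")
  g <- group_currents(list(mk(2.0), mk(NA, flagged = TRUE), mk(2.3)))
  expect_length(g, 1)
  expect_length(g[[1]]$members, 2)
})

test_that("variance bursts propose windows covering channel activity", {
  set.seed(84)
  dt <- 2e-4
  quiet <- rnorm(10000, 0, 0.3)
  active <- quiet
  active[4000:6000] <- active[4000:6000] + 4 * rbinom(2001, 1, 0.5)
  w <- propose_windows(current_trace(active, dt), width = 0.4)
  expect_gt(nrow(w), 0)
  mids <- rowMeans(w)
  expect_true(any(mids > 4000 * dt & mids < 6000 * dt))
  w0 <- propose_windows(current_trace(quiet, dt), width = 0.4, sd_factor = 3)
  expect_identical(nrow(w0), 0L)
})

test_that("the channel generator honors its stationary open probability", {
  p <- channel_sim_params(k_open = 5, k_close = 20)
  tr <- simulate_channel_trace(p, 60, seed = 85)
  open <- attr(tr, "open")
  expect_lt(abs(mean(open) - 5 / 25), 0.04)
  # the trace equals baseline + amplitude * open up to the noise
  resid <- tr$current - 4 * open
  expect_lt(abs(mean(resid)), 0.02)
  expect_equal(sd(resid), 0.5, tolerance = 0.02)
})
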