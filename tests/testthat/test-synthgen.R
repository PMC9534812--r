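test_that("trajectory MSD grows as 4 D t", {
  p <- scene_params(box_size = 10, density = 10, D = 0.26, brightness = 50)
  tr <- simulate_trajectories(p, duration = 5, time_step = 0.01, seed = 91,
                              store = "positions")
  msd <- ensemble_msd(tr, lags = 1:20)
  slope <- coef(lm(msd ~ lag_s + 0, data = msd))[[1]]
  expect_equal(slope, 4 * 0.26, tolerance = 0.05)
  # immobile particles do not move at all
  p0 <- scene_params(box_size = 10, density = 5, D = 0, brightness = 50)
  tr0 <- simulate_trajectories(p0, 1, 0.01, seed = 92, store = "positions")
  expect_equal(max(abs(sweep(tr0$positions, c(2, 3),
                             tr0$positions[1, , ]))), 0)
})

test_that("simulation is deterministic in the seed, per stage", {
  p <- scene_params(box_size = 4, density = 5, D = 0.3, brightness = 80)
  g <- confocal_geometry()
  mk <- function(seed) {
    tr <- simulate_trajectories(p, 3, g$line_time, seed = seed,
                                store = "lazy")
    render_confocal_series(tr, g, 2, seed, dim = c(32, 32))
  }
  expect_identical(mk(5)$data[[1]], mk(5)$data[[1]])
  expect_false(identical(mk(5)$data[[1]], mk(6)$data[[1]]))
  # stage substreams decouple the generator stages
  expect_false(substream_seed(5, "trajectories") ==
                 substream_seed(5, "render_confocal"))
  expect_identical(substream_seed(5, "trajectories"),
                   substream_seed(5, "trajectories"))
})

test_that("rendered confocal intensity matches the analytic mean rate", {
  g <- confocal_geometry()
  dens <- 50; eps <- 100; bg <- 2
  p <- scene_params(box_size = 5, density = dens, D = 0.3, brightness = eps,
                    background = bg)
  tr <- simulate_trajectories(p, 10, g$line_time, seed = 93, store = "lazy")
  s <- render_confocal_series(tr, g, 4, seed = 93, dim = c(64, 64))
  # mean detected rate: bg + density * eps * (pi w^2 / 2) kHz
  rate_khz <- mean(s$data[[1]]) / g$pixel_dwell / 1000
  expect_equal(rate_khz, bg + dens * eps * pi * g$focal_waist^2 / 2,
               tolerance = 0.15)
  expect_s3_class(attr(s, "truth"), "scene_params")
})

test_that("per-pixel and per-line rendering agree for static scenes", {
  g <- confocal_geometry()
  p <- scene_params(box_size = 4, density = 10, D = 0, brightness = 200)
  tr <- simulate_trajectories(p, 5, g$line_time, seed = 94, store = "lazy")
  s_line <- render_confocal_series(tr, g, 3, seed = 94, dim = c(48, 48))
  s_pix <- render_confocal_series(tr, g, 3, seed = 94, dim = c(48, 48),
                                  per_pixel = TRUE)
  m1 <- apply(s_line$data[[1]], c(2, 3), mean)
  m2 <- apply(s_pix$data[[1]], c(2, 3), mean)
  expect_gt(cor(as.vector(m1), as.vector(m2)), 0.99)
})

test_that("render guards reject impossible requests", {
  g <- confocal_geometry()
  p <- scene_params(box_size = 2, density = 5, D = 0.3, brightness = 50)
  tr <- simulate_trajectories(p, 0.5, g$line_time, seed = 95, store = "lazy")
  expect_error(render_confocal_series(tr, g, 10, seed = 95, dim = c(32, 32)),
               "too short")
  tr_long <- simulate_trajectories(p, 2, g$line_time, seed = 95,
                                   store = "lazy")
  expect_error(render_confocal_series(tr_long, g, 1, seed = 95,
                                      dim = c(64, 64)),
               "smaller than the field")
  cg <- camera_geometry()
  expect_error(render_camera_series(tr, cg, 10, seed = 95, dim = c(8, 8)),
               "too short")
})

test_that("dual-color camera labels follow the species model", {
  g <- acquisition_geometry(0.15, 0.3, "camera", frame_time = 0.08,
                            channels = 2L)
  p <- scene_params(box_size = 30, density = 10, D = 0.05, brightness = 80,
                    q = 1, p_m = 1)
  tr <- simulate_trajectories(p, 1, 0.08, seed = 96, store = "lazy")
  s <- render_camera_series(tr, g, 2, seed = 96, dim = c(64, 64))
  tru <- attr(s, "truth")
  expect_true(all(tru$species == "both"))
  expect_true(all(tru$bright > 0))
  expect_identical(names(s$data), c("green", "red"))
  # q = 0: no particle carries both labels
  p0 <- scene_params(box_size = 30, density = 10, D = 0.05, brightness = 80,
                     q = 0, p_m = 1)
  tr0 <- simulate_trajectories(p0, 1, 0.08, seed = 97, store = "lazy")
  s0 <- render_camera_series(tr0, g, 2, seed = 97, dim = c(64, 64))
  tru0 <- attr(s0, "truth")
  expect_false(any(tru0$species == "both"))
  expect_false(any(tru0$bright[, 1] > 0 & tru0$bright[, 2] > 0))
})

test_that("simulated step counts follow the renormalized binomial model", {
  p <- bleach_sim_params(p_m = 1, A = 1)
  expect_true(all(simulate_step_counts(p, 50, seed = 101) == 5L))
  p2 <- bleach_sim_params(p_m = 0.47, A = 0.88)
  x <- simulate_step_counts(p2, 20000, seed = 102)
  expect_true(all(x >= 1L))
  emp <- tabulate(x, 10) / length(x)
  model <- binomial_pmf(1:10, p_m = 0.47, A = 0.88, renormalize = TRUE)
  expect_lt(max(abs(emp - model)), 0.012)
  # the mixture branch lowers the mean count
  p3 <- bleach_sim_params(p_m = 0.47, A = 0.88, H = 0, het = 2L)
  x3 <- simulate_step_counts(p3, 5000, seed = 103)
  expect_lt(mean(x3), mean(x))
})

test_that("bleach traces start at the full-label level and end at baseline", {
  p <- bleach_sim_params(p_m = 0.47, A = 0.88, unit_intensity = 100,
                         baseline = 200, noise_sd = 1, trace_length = 600L)
  sim <- simulate_bleach_traces(p, 50, seed = 104)
  expect_length(sim$traces, 50)
  for (i in seq_len(50)) {
    v <- sim$traces[[i]]$values
    expect_length(v, 600)
    expect_equal(v[1], 200 + 100 * sim$true_steps[i], tolerance = 0.05)
  }
  # by 600 frames (15 mean lifetimes) essentially everything has bleached
  tails <- vapply(sim$traces, function(t) mean(t$values[580:600]), numeric(1))
  expect_lt(max(abs(tails - 200)), 5)
})
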