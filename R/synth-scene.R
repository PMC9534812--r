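#' Parameters of a synthetic membrane scene
#'
#' Describes a 2D membrane sheet carrying diffusing fluorescent complexes:
#' the ground truth against which every downstream estimator is validated.
#' The box is periodic, so the particle concentration is stationary without
#' boundary depletion.
#'
#' @param box_size Side length of the periodic box in micrometres. Must cover
#'   the rendered field of view.
#' @param density Particle density in complexes per square micrometre
#'   (membrane receptor expression in model cells spans roughly 1-200/um^2).
#' @param D True diffusion constant in um^2/s.
#' @param brightness True per-complex molecular brightness in kHz at the beam
#'   center.
#' @param background Background count rate in kHz.
#' @param clusters Optional list of cluster specs, each a list with `count`,
#'   `brightness_multiple`, `D` and `radius` (um). Clusters are rendered as
#'   co-moving groups of sub-emitters filling a disk of the given radius.
#' @param q Fraction of particles carrying both color labels (co-diffusing
#'   species) in dual-color scenes.
#' @param p_m Per-subunit fluorophore maturation probability: each label a
#'   particle nominally carries is present with this probability.
#' @param channel_offset_px Registration offset of channel 2 relative to
#'   channel 1, `(row, col)` in pixels.
#' @param waist_ratio Channel-2 focal waist divided by channel-1 waist
#'   (detection-volume overlap factor).
#' @return An object of class `scene_params`.
#' @examples
#' scene_params(box_size = 16, density = 30, D = 0.26, brightness = 50)
#' @export
scene_params <- function(box_size, density, D, brightness,
                         background = 0, clusters = list(),
                         q = 0, p_m = 1,
                         channel_offset_px = c(0, 0), waist_ratio = 1) {
  stopifnot(box_size > 0, density > 0, D >= 0, brightness > 0,
            background >= 0, q >= 0, q <= 1, p_m > 0, p_m <= 1,
            waist_ratio > 0)
  structure(list(box_size = box_size, density = density, D = D,
                 brightness = brightness, background = background,
                 clusters = clusters, q = q, p_m = p_m,
                 channel_offset_px = channel_offset_px,
                 waist_ratio = waist_ratio),
            class = "scene_params")
}

# Instantiate the particle population of a scene: positions uniform in the
# box, per-particle diffusion constant and brightness.  Clusters become
# co-moving groups of sub-emitters sharing one random-walk trajectory.
make_population <- function(params) {
  n <- max(1L, round(params$density * params$box_size^2))
  pos <- cbind(runif(n, 0, params$box_size), runif(n, 0, params$box_size))
  D <- rep(params$D, n)
  eps <- rep(params$brightness, n)
  group <- seq_len(n)
  for (cl in params$clusters) {
    n_sub <- max(1L, min(25L, round(pi * (cl$radius / 0.05)^2)))
    for (k in seq_len(cl$count)) {
      ctr <- runif(2, 0, params$box_size)
      th <- runif(n_sub, 0, 2 * pi)
      rr <- cl$radius * sqrt(runif(n_sub))
      sub <- cbind(ctr[1] + rr * cos(th), ctr[2] + rr * sin(th)) %%
        params$box_size
      pos <- rbind(pos, sub)
      D <- c(D, rep(cl$D, n_sub))
      eps <- c(eps, rep(cl$brightness_multiple * params$brightness / n_sub,
                        n_sub))
      group <- c(group, rep(max(group) + 1L, n_sub))
    }
  }
  list(pos = pos, D = D, eps = eps, group = group, n_free = n)
}

#' Simulate Brownian trajectories on a periodic membrane
#'
#' Each axis increment is drawn independently as Gaussian with standard
#' deviation \eqn{\sqrt{2 D \Delta t}}. Positions are stored unwrapped so
#' mean-squared displacements are unaffected by the periodic wrap; renderers
#' wrap them back into the box.
#'
#' @param params A [scene_params()].
#' @param duration Total simulated time in seconds.
#' @param time_step Time step in seconds; for raster rendering it should not
#'   exceed the line time.
#' @param seed Integer RNG seed.
#' @param store `"positions"` keeps the full unwrapped position array
#'   (`[step, particle, xy]`); `"lazy"` keeps only the initial state, letting
#'   renderers advance the identical physics internally (needed for scenes
#'   whose full trajectory would not fit in memory); `"auto"` picks by size.
#' @return An object of class `scene_trajectories` with elements `pos0`
#'   (wrapped initial positions), `D`, `eps` (per-particle), `positions`
#'   (unwrapped array, or `NULL` when lazy), `params`, `duration`,
#'   `time_step` and `seed`.
#' @examples
#' p <- scene_params(box_size = 4, density = 2, D = 0.1, brightness = 50)
#' tr <- simulate_trajectories(p, duration = 1, time_step = 0.01, seed = 1)
#' dim(tr$positions)
#' @export
simulate_trajectories <- function(params, duration, time_step, seed,
                                  store = c("auto", "positions", "lazy")) {
  stopifnot(inherits(params, "scene_params"))
  if (!is.numeric(time_step) || time_step <= 0)
    stop("'time_step' must be positive")
  if (duration <= 0) stop("'duration' must be positive")
  store <- match.arg(store)
  set.seed(substream_seed(seed, "trajectories"))
  pop <- make_population(params)
  n <- nrow(pop$pos)
  n_steps <- ceiling(duration / time_step)
  if (store == "auto")
    store <- if ((n_steps + 1) * n <= 5e6) "positions" else "lazy"
  positions <- NULL
  if (store == "positions") {
    positions <- array(NA_real_, c(n_steps + 1L, n, 2L))
    positions[1, , ] <- pop$pos
    cur <- pop$pos
    sds <- sqrt(2 * pop$D * time_step)
    for (s in seq_len(n_steps)) {
      # one shared increment per co-moving group
      steps <- matrix(rnorm(2 * n), ncol = 2) * sds
      for (g in unique(pop$group[duplicated(pop$group)])) {
        idx <- which(pop$group == g)
        steps[idx, 1] <- steps[idx[1], 1]
        steps[idx, 2] <- steps[idx[1], 2]
      }
      cur <- cur + steps
      positions[s + 1L, , ] <- cur
    }
  }
  structure(list(pos0 = pop$pos, D = pop$D, eps = pop$eps,
                 group = pop$group, n_free = pop$n_free,
                 positions = positions, params = params,
                 duration = duration, time_step = time_step, seed = seed),
            class = "scene_trajectories")
}

#' Ensemble mean-squared displacement of stored trajectories
#'
#' Computed on unwrapped coordinates; for 2D Brownian motion
#' `MSD(lag) = 4 D lag`.
#'
#' @param traj A [simulate_trajectories()] result with stored positions.
#' @param lags Integer vector of step lags.
#' @return Data frame with `lag_s` and `msd` (um^2).
#' @export
ensemble_msd <- function(traj, lags = 1:10) {
  if (is.null(traj$positions))
    stop("trajectories were simulated lazily; re-run with store='positions'")
  P <- traj$positions
  n_steps <- dim(P)[1]
  vapply(lags, function(m) {
    d <- P[seq_len(n_steps - m) + m, , , drop = FALSE] -
      P[seq_len(n_steps - m), , , drop = FALSE]
    mean(d[, , 1]^2 + d[, , 2]^2)
  }, numeric(1)) -> msd
  data.frame(lag_s = lags * traj$time_step, msd = msd)
}
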