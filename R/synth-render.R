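#' Render a confocal raster-scan image series from a membrane scene
#'
#' Pixels are visited in row-major raster order. Each pixel's expected count
#' is \eqn{\tau_p [bg + \sum_i \epsilon_i \exp(-2 r_i^2/\omega_r^2)]} with
#' particle positions advanced to that pixel's acquisition time, and the
#' realized count is Poisson. By default positions are updated once per scan
#' line: at D of order 1 um^2/s the RMS motion during one 4.92 ms line is
#' about 3 pixels, so line granularity is the accuracy/speed compromise; the
#' per-pixel mode backs the oracle tests.
#'
#' @param traj A [simulate_trajectories()] result. The renderer re-runs the
#'   identical Brownian physics from the trajectory's initial state at scan
#'   granularity (storing per-line positions for a full series would be
#'   prohibitive), so `traj` supplies the initial state and the ground truth.
#' @param geometry A raster [acquisition_geometry()].
#' @param n_frames Number of frames to render.
#' @param seed Integer RNG seed.
#' @param dim Frame size `(rows, cols)` in pixels.
#' @param per_pixel Logical; update particle positions at every pixel instead
#'   of every line (slow; for validation).
#' @return An [image_series()] with intensities in photon counts per pixel
#'   (convert to kHz by dividing by `pixel_dwell`). The ground-truth scene is
#'   attached as attribute `"truth"`.
#' @examples
#' p <- scene_params(box_size = 4, density = 5, D = 0.3, brightness = 50)
#' tr <- simulate_trajectories(p, 3, 0.005, seed = 1, store = "lazy")
#' g <- confocal_geometry()
#' s <- render_confocal_series(tr, g, n_frames = 2, seed = 1, dim = c(64, 64))
#' @export
render_confocal_series <- function(traj, geometry, n_frames, seed,
                                   dim = c(256L, 256L), per_pixel = FALSE) {
  stopifnot(inherits(traj, "scene_trajectories"),
            inherits(geometry, "acquisition_geometry"),
            geometry$modality == "raster")
  frame_time <- geometry$frame_time %||% (dim[1] * geometry$line_time)
  if (traj$duration < n_frames * frame_time)
    stop("trajectory duration too short for the requested frames")
  if (traj$params$box_size < dim[2] * geometry$pixel_size)
    stop("scene box smaller than the field of view")
  set.seed(substream_seed(seed, "render_confocal"))
  raw <- cpp_render_confocal(traj$pos0 %% traj$params$box_size, traj$D,
                             traj$eps, traj$params$box_size,
                             traj$params$background, as.integer(n_frames),
                             as.integer(dim[1]), as.integer(dim[2]),
                             geometry$pixel_size, geometry$pixel_dwell,
                             geometry$line_time, frame_time,
                             geometry$focal_waist, per_pixel)
  arr <- array(raw, c(n_frames, dim[1], dim[2]))
  # the rendered series carries the effective frame interval even when the
  # input geometry left it implicit (dim[1] * line_time)
  geometry$frame_time <- frame_time
  out <- image_series(arr, geometry)
  attr(out, "truth") <- traj$params
  out
}

#' Render a camera (TIRF) image series from a membrane scene
#'
#' Each frame sums, over all particles carrying a label in the channel, an
#' integrated 2D Gaussian point spread function (waist `focal_waist`)
#' evaluated at the particle's mid-exposure position, times the exposure,
#' plus background; noise is Poisson plus additive Gaussian read noise.
#' Dual-color series use alternating excitation with per-channel exposure
#' offsets within the frame. Labels follow the scene's dual-color species
#' model: a fraction `q` of particles carries both colors, the remainder is
#' split between single-color species, and each nominal label is present
#' with maturation probability `p_m`.
#'
#' @inheritParams render_confocal_series
#' @param geometry A camera [acquisition_geometry()]; its `channels` field
#'   selects single- or dual-color rendering.
#' @param exposure Per-channel exposure time in seconds.
#' @param read_noise_sd Gaussian read noise SD in counts (negative samples
#'   are clamped to zero).
#' @return An [image_series()] in camera counts, with ground truth attached
#'   as attribute `"truth"` (including per-particle label assignments).
#' @export
render_camera_series <- function(traj, geometry, n_frames, seed,
                                 dim = c(256L, 256L), exposure = 0.02,
                                 read_noise_sd = 0) {
  stopifnot(inherits(traj, "scene_trajectories"),
            inherits(geometry, "acquisition_geometry"),
            geometry$modality == "camera")
  n_ch <- geometry$channels
  if (n_ch > 2L) stop("at most two channels are supported")
  if (traj$duration < n_frames * geometry$frame_time)
    stop("trajectory duration too short for the requested frames")
  if (traj$params$box_size < dim[2] * geometry$pixel_size)
    stop("scene box smaller than the field of view")
  p <- traj$params
  set.seed(substream_seed(seed, "render_camera"))
  n <- nrow(traj$pos0)
  bright <- matrix(0, n, n_ch)
  if (n_ch == 1L) {
    lab <- rbinom(n, 1, p$p_m)
    bright[, 1] <- traj$eps * lab
    species <- rep("g", n)
  } else {
    species <- sample(c("both", "g", "r"), n, replace = TRUE,
                      prob = c(p$q, (1 - p$q) / 2, (1 - p$q) / 2))
    has_g <- species %in% c("both", "g")
    has_r <- species %in% c("both", "r")
    bright[, 1] <- traj$eps * has_g * rbinom(n, 1, p$p_m)
    bright[, 2] <- traj$eps * has_r * rbinom(n, 1, p$p_m)
  }
  ch_offsets <- if (n_ch == 2L) c(0, exposure) else 0
  omega <- c(geometry$focal_waist,
             geometry$focal_waist * p$waist_ratio)[seq_len(n_ch)]
  reg <- rbind(c(0, 0), p$channel_offset_px)[seq_len(n_ch), , drop = FALSE]
  raw <- cpp_render_camera(traj$pos0 %% p$box_size, traj$D, bright,
                           rep(p$background, n_ch), p$box_size,
                           as.integer(n_frames), as.integer(dim[1]),
                           as.integer(dim[2]), geometry$pixel_size,
                           geometry$frame_time, exposure, ch_offsets,
                           omega, read_noise_sd, reg)
  data <- lapply(raw, function(v) array(v, c(n_frames, dim[1], dim[2])))
  names(data) <- c("green", "red")[seq_len(n_ch)]
  out <- image_series(data, geometry)
  attr(out, "truth") <- c(p, list(species = species, bright = bright))
  out
}
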