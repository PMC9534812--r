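# Shared fixtures for the pentafluct test suite.  Everything is generated in
# code from fixed seeds; no binary fixtures are shipped.

# Small raster geometry matching the confocal defaults.
raster_geom <- function() confocal_geometry()

# Small camera geometry (single channel).
cam_geom <- function(channels = 1L) {
  acquisition_geometry(0.15, 0.3, "camera", frame_time = 0.08,
                       channels = channels)
}

# A tiny deterministic photon-count series (integers) for I/O tests.
tiny_count_series <- function(n_frames = 4L, nr = 8L, nc = 8L,
                              channels = 1L, seed = 1) {
  set.seed(seed)
  g <- acquisition_geometry(0.05, 0.2, "raster", pixel_dwell = 8.19e-6,
                            line_time = 4.92e-3, frame_time = 1.26,
                            channels = channels)
  data <- lapply(seq_len(channels), function(ch)
    array(rpois(n_frames * nr * nc, 20), c(n_frames, nr, nc)))
  image_series(data, g)
}

# A rendered confocal series at reduced size, cached per test file.
local({
  cache <- new.env(parent = emptyenv())
  small_confocal_series <<- function(D = 0.26, seed = 3, n_frames = 20L,
                                     dim = 64L, density = 20) {
    key <- paste(D, seed, n_frames, dim, density, sep = "_")
    if (is.null(cache[[key]])) {
      g <- confocal_geometry()
      p <- scene_params(box_size = dim * g$pixel_size * 1.25,
                        density = density, D = D, brightness = 100,
                        background = 0.1)
      tr <- simulate_trajectories(p, n_frames * g$frame_time + 0.1,
                                  g$line_time, seed = seed, store = "lazy")
      cache[[key]] <- render_confocal_series(tr, g, n_frames, seed,
                                             dim = c(dim, dim))
    }
    cache[[key]]
  }
})

# Direct-sum masked spatial correlation (quadratic-time oracle for the FFT
# path, Eq. 5 written out literally).
direct_spatial_acf <- function(series, M, max_xi, max_psi, channel = 1L) {
  a <- series$data[[channel]]
  nf <- dim(a)[1]; nr <- dim(a)[2]; nc <- dim(a)[3]
  xi <- -max_xi:max_xi; psi <- -max_psi:max_psi
  acc <- matrix(0, length(psi), length(xi))
  counts <- matrix(0L, length(psi), length(xi))
  for (ip in seq_along(psi)) for (ix in seq_along(xi)) {
    cnt <- 0L
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + psi[ip]; c2 <- c + xi[ix]
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          M[r, c] && M[r2, c2]) cnt <- cnt + 1L
    }
    counts[ip, ix] <- cnt
  }
  for (f in seq_len(nf)) {
    img <- a[f, , ]
    mu <- mean(img[M])
    d <- img - mu
    for (ip in seq_along(psi)) for (ix in seq_along(xi)) {
      if (counts[ip, ix] == 0L) next
      s <- 0
      for (r in seq_len(nr)) for (c in seq_len(nc)) {
        r2 <- r + psi[ip]; c2 <- c + xi[ix]
        if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
            M[r, c] && M[r2, c2]) s <- s + d[r, c] * d[r2, c2]
      }
      acc[ip, ix] <- acc[ip, ix] + s / counts[ip, ix] / mu^2
    }
  }
  G <- acc / nf
  G[counts == 0L] <- NA
  list(G = G, counts = counts)
}

# Place an integrated-Gaussian spot of total amplitude `amp` into `img`.
add_test_spot <- function(img, row, col, amp = 200, sigma = 1) {
  nr <- nrow(img); nc <- ncol(img)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    img[r, c] <- img[r, c] +
      amp * exp(-((r - row)^2 + (c - col)^2) / (2 * sigma^2))
  }
  img
}
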