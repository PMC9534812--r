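#' Shape factor of a 2D Gaussian focal volume
#'
#' The amplitude shape factor entering the raster correlation fit for a
#' two-dimensional Gaussian point spread function, \eqn{\gamma = 2^{-3/2}}.
#'
#' @return `2^(-3/2)`.
#' @export
gamma_2d <- function() 2^(-3 / 2)

#' Moving-average detrending of a raster image series
#'
#' Removes slow intensity drifts (cell and organelle movement) before
#' spatial correlation: each pixel's value is replaced by its deviation from
#' a short per-pixel temporal local mean (frames `f - delta_f` to
#' `f + delta_f`, truncated at the series ends) plus the global mean over
#' all frames, so the overall intensity level is preserved.
#'
#' @param series An [image_series()].
#' @param delta_f Half-width of the moving-average window in frames
#'   (default 1, i.e. a 3-frame window).
#' @return A detrended [image_series()].
#' @export
moving_average_correct <- function(series, delta_f = 1L) {
  stopifnot(inherits(series, "image_series"), delta_f >= 1)
  nf <- n_frames(series)
  if (nf < 2 * delta_f + 1)
    stop("need at least 2*delta_f + 1 frames")
  data <- lapply(series$data, function(a) {
    gm <- mean(a)
    d <- dim(a)
    flat <- matrix(a, nrow = nf)           # frames x (row*col)
    cs <- rbind(0, apply(flat, 2, cumsum))
    f1 <- pmax(seq_len(nf) - delta_f, 1L)
    f2 <- pmin(seq_len(nf) + delta_f, nf)
    local <- (cs[f2 + 1L, , drop = FALSE] - cs[f1, , drop = FALSE]) /
      (f2 - f1 + 1L)
    out <- flat - local + gm
    array(out, d)
  })
  out <- image_series(data, series$geometry, series$channels,
                      allow_negative = TRUE)
  attr(out, "delta_f") <- delta_f
  out
}

#' Masked spatial autocorrelation of a raster series (ARICS)
#'
#' Computes the spatial autocorrelation surface
#' \eqn{G(\xi, \psi) = \langle \delta I(x,y)\,\delta I(x+\xi, y+\psi)\rangle
#' / \langle I \rangle^2} per frame, restricted to an arbitrarily shaped
#' pixel mask: a lag contributes only pixel pairs where both pixels are
#' included, and each lag is normalized by its own valid-pair count. The
#' per-frame surfaces are averaged, retaining the across-frame SD per lag.
#' Computed via zero-padded FFTs, which equals the direct masked sum.
#'
#' @param series A detrended [image_series()] (see
#'   [moving_average_correct()]).
#' @param mask A [mask_stack()]; per-frame masks are reduced to their
#'   intersection.
#' @param max_xi,max_psi Largest retained lags (px) along the fast-scan
#'   (column) and line (row) axes.
#' @param channel Channel to correlate.
#' @return An object of class `spatial_acf` with elements `G` (matrix
#'   `[psi, xi]` of lag means), `sd` (across-frame SD), `counts` (valid pair
#'   counts), `xi`, `psi` (lag vectors) and `n_frames`. Lags without valid
#'   pairs are `NA`.
#' @export
spatial_correlate <- function(series, mask, max_xi = 32L, max_psi = 16L,
                              channel = 1L) {
  stopifnot(inherits(series, "image_series"), inherits(mask, "mask_stack"))
  M <- static_grid(mask)
  if (!any(M)) stop("mask is empty")
  a <- series$data[[channel]]
  nf <- dim(a)[1]; nr <- dim(a)[2]; nc <- dim(a)[3]
  stopifnot(nrow(M) == nr, ncol(M) == nc)
  max_xi <- min(max_xi, nc - 1L); max_psi <- min(max_psi, nr - 1L)
  pr <- nr + max_psi; pc <- nc + max_xi
  Mp <- matrix(0, pr, pc); Mp[1:nr, 1:nc] <- M
  FM <- fft(Mp)
  counts_full <- Re(fft(FM * Conj(FM), inverse = TRUE)) / length(Mp)
  xi <- -max_xi:max_xi; psi <- -max_psi:max_psi
  pick <- function(full) {
    # circular index of lag l along a padded axis of length n
    g <- function(l, n) ifelse(l >= 0, l + 1L, n + l + 1L)
    full[g(psi, pr), g(xi, pc), drop = FALSE]
  }
  counts <- round(pick(counts_full))
  acc <- matrix(0, length(psi), length(xi))
  acc2 <- matrix(0, length(psi), length(xi))
  for (f in seq_len(nf)) {
    img <- a[f, , ]
    mu <- mean(img[M])
    if (mu == 0) next
    dI <- matrix(0, pr, pc)
    dI[1:nr, 1:nc] <- (img - mu) * M
    Fd <- fft(dI)
    num_full <- Re(fft(Fd * Conj(Fd), inverse = TRUE)) / length(dI)
    Gf <- pick(num_full) / counts / mu^2
    Gf[counts == 0] <- 0
    acc <- acc + Gf
    acc2 <- acc2 + Gf^2
  }
  G <- acc / nf
  sdv <- sqrt(pmax(acc2 / nf - G^2, 0) * nf / max(nf - 1, 1))
  G[counts == 0] <- NA
  sdv[counts == 0] <- NA
  structure(list(G = G, sd = sdv, counts = counts, xi = xi, psi = psi,
                 n_frames = nf, delta_f = attr(series, "delta_f")),
            class = "spatial_acf")
}

# Raster correlation model: amplitude gamma/N, diffusion decay governed by
# the time |xi*tau_p + psi*tau_l| elapsed between the two pixels of a lag.
# tau_extra adds a fixed time offset (used for frame-lag correlations).
rics_model <- function(xi, psi, N, D, geometry, tau_extra = 0) {
  tau <- abs(xi * geometry$pixel_dwell + psi * geometry$line_time) + tau_extra
  w2 <- geometry$focal_waist^2
  gamma_2d() / N * (1 + 4 * D * tau / w2)^-1 *
    exp(-geometry$pixel_size^2 * (xi^2 + psi^2) / (w2 + 4 * D * tau))
}

# Frame-lag weight spectrum of the moving-average detrending filter.
# Row f of W holds the coefficients the filter applies to frames 1..nf when
# producing detrended frame f (identity minus the truncated window mean).
# Returns c[m+1] = average over f of sum_{j-k = +/-m} W[f,j] W[f,k], so the
# expected ACF of the detrended series is sum_m c[m+1] * C_m with C_m the
# true correlation between frames m apart.  For interior frames at
# delta_f = 1 this is (2/3, -8/9, 2/9).
ma_lag_weights <- function(n_frames, delta_f) {
  W <- diag(n_frames)
  for (f in seq_len(n_frames)) {
    win <- max(1L, f - delta_f):min(n_frames, f + delta_f)
    W[f, win] <- W[f, win] - 1 / length(win)
  }
  S <- crossprod(W)
  vapply(0:(2L * delta_f), function(m) {
    if (m == 0L) sum(diag(S)) / n_frames
    else 2 * sum(S[cbind(seq_len(n_frames - m), seq_len(n_frames - m) + m)]) /
      n_frames
  }, numeric(1))
}

# Expected ACF of a moving-average-detrended series, in the fitted-N
# convention (leading term is exactly rics_model, so the fitted N carries
# the standard amplitude bias 1/c0 that brightness() later undoes): the
# frame-lag correlations the filter mixes in are added with relative
# weights c_m / c0 and time offsets m * frame_time.
rics_model_detrended <- function(xi, psi, N, D, geometry, coefs, frame_time) {
  g <- rics_model(xi, psi, N, D, geometry)
  for (m in seq_along(coefs)[-1])
    g <- g + (coefs[m] / coefs[1]) *
      rics_model(xi, psi, N, D, geometry, tau_extra = (m - 1) * frame_time)
  g
}

#' Fit the 2D diffusion model to a spatial autocorrelation surface
#'
#' Weighted least squares of the one-component raster correlation model
#' (2D Gaussian point spread function, shape factor \eqn{2^{-3/2}}) over
#' lags within the fit radius. The zero lag is excluded (uncorrelated shot
#' noise). The model amplitude at zero lag is \eqn{\gamma / N}.
#'
#' When the autocorrelation was computed from a moving-average-detrended
#' series (see [moving_average_correct()]), the detrending filter mixes
#' small negative copies of the frame-lag correlations into the spatial
#' surface. The fit then uses the expected ACF of the detrended series (the
#' same model plus its exactly-known filter response at time offsets of
#' whole frame times); the leading term is unchanged, so the fitted `N`
#' still carries the standard moving-average amplitude bias that
#' [brightness()] undoes.
#'
#' @param acf A [spatial_correlate()] result.
#' @param geometry The raster [acquisition_geometry()].
#' @param fit_radius Lag window `(max |xi|, max |psi|)` in pixels.
#' @return An object of class `rics_fit` with `N`, `D`, standard errors,
#'   residuals and a convergence flag.
#' @export
fit_rics <- function(acf, geometry, fit_radius = c(16L, 8L)) {
  stopifnot(inherits(acf, "spatial_acf"),
            inherits(geometry, "acquisition_geometry"),
            geometry$modality == "raster")
  grid <- expand.grid(psi = acf$psi, xi = acf$xi)
  grid$G <- as.vector(acf$G)
  grid$sd <- as.vector(acf$sd)
  keep <- abs(grid$xi) <= fit_radius[1] & abs(grid$psi) <= fit_radius[2] &
    !(grid$xi == 0 & grid$psi == 0) & is.finite(grid$G)
  d <- grid[keep, ]
  amp0 <- mean(d$G[abs(d$xi) <= 1 & d$psi == 0], na.rm = TRUE)
  if (!is.finite(amp0) || amp0 <= 0)
    stop("non-positive correlation amplitude near zero lag")
  pos_sd <- d$sd[is.finite(d$sd) & d$sd > 0]
  w <- if (length(pos_sd)) {
    s <- pmax(d$sd, min(pos_sd))
    1 / s^2
  } else rep(1, nrow(d))
  start <- list(N = gamma_2d() / amp0, D = 0.3)
  detrended <- !is.null(acf$delta_f) && !is.null(geometry$frame_time)
  form <- if (detrended) {
    coefs <- ma_lag_weights(acf$n_frames, acf$delta_f)
    frame_time <- geometry$frame_time
    G ~ rics_model_detrended(xi, psi, N, D, geometry, coefs, frame_time)
  } else G ~ rics_model(xi, psi, N, D, geometry)
  fit <- try(minpack.lm::nlsLM(
    form, data = d, start = start, weights = w,
    lower = c(N = 1e-6, D = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(N = NA_real_, D = NA_real_, se = c(N = NA, D = NA),
                          converged = FALSE, residuals = NULL,
                          message = attr(fit, "condition")$message),
                     class = "rics_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(N = NA_real_, D = NA_real_))
  structure(list(N = unname(cf["N"]), D = unname(cf["D"]), se = se,
                 converged = TRUE, residuals = stats::resid(fit),
                 fitted = stats::fitted(fit), data = d,
                 geometry = geometry),
            class = "rics_fit")
}

#' @export
print.rics_fit <- function(x, ...) {
  cat(sprintf("<rics_fit> N = %.3g, D = %.4g um^2/s%s\n", x$N, x$D,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Molecular brightness from a raster series and its correlation fit
#'
#' The molecular brightness is the mean detected photon rate per diffusing
#' complex, \eqn{\epsilon = F / N}, with `F` the mean masked intensity in
#' kHz and `N` the fitted number of molecules in focus. Before the division,
#' `N` is corrected for the amplitude bias of the moving-average detrending:
#' subtracting a `(2 delta_f + 1)`-frame local mean multiplies the true
#' fluctuation variance of frame-uncorrelated fluctuations by
#' `2 delta_f / (2 delta_f + 1)`, so the fitted `N` overestimates the true
#' `N` by the reciprocal; the default bias factor undoes this.
#'
#' @param series The raw (uncorrected) photon-count [image_series()].
#' @param mask A [mask_stack()].
#' @param fit A [fit_rics()] result.
#' @param delta_f The moving-average half-width used upstream.
#' @param bias_factor Multiplicative correction applied to `N`; defaults to
#'   `2 * delta_f / (2 * delta_f + 1)` (the frame-uncorrelated limit).
#' @param channel Channel to analyze.
#' @return An object of class `brightness_result` with `epsilon` (kHz),
#'   `F_khz`, `N_corrected` and the bias factor applied.
#' @export
brightness <- function(series, mask, fit, delta_f = 1L,
                       bias_factor = 2 * delta_f / (2 * delta_f + 1),
                       channel = 1L) {
  stopifnot(inherits(series, "image_series"), inherits(fit, "rics_fit"))
  if (series$geometry$modality != "raster")
    stop("molecular brightness is defined for photon-counting raster data")
  if (!fit$converged || !is.finite(fit$N)) stop("invalid correlation fit")
  M <- static_grid(mask)
  a <- series$data[[channel]]
  vals <- apply(a, 1, function(img) mean(img[M]))
  F_khz <- mean(vals) / series$geometry$pixel_dwell / 1000
  N_corr <- fit$N * bias_factor
  structure(list(epsilon = F_khz / N_corr, F_khz = F_khz,
                 N_corrected = N_corr, bias_factor = bias_factor),
            class = "brightness_result")
}

#' @export
print.brightness_result <- function(x, ...) {
  cat(sprintf(
    "<brightness> epsilon = %.3g kHz (F = %.3g kHz, N = %.3g, bias %.3g)\n",
    x$epsilon, x$F_khz, x$N_corrected, x$bias_factor))
  invisible(x)
}
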