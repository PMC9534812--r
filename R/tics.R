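#' Frame-mean detrending of a camera image series
#'
#' Removes frame-to-frame intensity variation (illumination flicker, slow
#' focus drift) before temporal correlation: each frame's spatial mean is
#' replaced by the global mean, so every output frame has the same spatial
#' mean.
#'
#' @param series An [image_series()].
#' @return A detrended [image_series()].
#' @export
detrend_frames <- function(series) {
  stopifnot(inherits(series, "image_series"))
  if (n_frames(series) < 2L) stop("need at least 2 frames")
  data <- lapply(series$data, function(a) {
    gm <- mean(a)
    fm <- apply(a, 1, mean)
    sweep(a, 1, fm - gm)
  })
  image_series(data, series$geometry, series$channels,
               allow_negative = TRUE)
}

#' Per-pixel temporal auto- or cross-correlation of camera series
#'
#' For every included pixel, correlates its fluctuation time trace
#' \eqn{\delta I = I(t) - \langle I \rangle_t} with itself (autocorrelation;
#' pass the same channel twice) or with the other channel's trace
#' (cross-correlation):
#' \eqn{G(\tau) = \langle \delta I_1(t) \delta I_2(t+\tau) \rangle_t /
#' (\langle I_1 \rangle \langle I_2 \rangle)}, with unbiased normalization by
#' the `T - m` available terms per lag and no periodic wrap (zero-padded
#' FFT). Curves are averaged with equal weight over included pixels and a
#' per-lag 95\% confidence half-width across pixels is attached. Per-frame
#' masks cannot yield gap-free pixel time traces, so they are reduced to
#' their intersection over frames.
#'
#' @param series_1,series_2 Detrended single-channel matrices or
#'   [image_series()] channels: pass an `image_series` plus `channel`
#'   arguments, or two 3-d arrays.
#' @param mask A [mask_stack()].
#' @param max_lag Largest lag in frames to compute.
#' @param geometry Optional [acquisition_geometry()] (taken from `series_1`
#'   when it is an `image_series`) used to convert lags to seconds.
#' @param channel_1,channel_2 Channels used when `series_1` (and `series_2`)
#'   are `image_series` objects.
#' @return An object of class `temporal_cf` with `lag_s`, `G`, `ci95`,
#'   `n_pixels` and `kind` (`"auto"` or `"cross"`).
#' @export
temporal_correlate <- function(series_1, series_2 = series_1, mask,
                               max_lag = 25L, geometry = NULL,
                               channel_1 = 1L, channel_2 = NULL) {
  if (inherits(series_1, "image_series")) {
    geometry <- geometry %||% series_1$geometry
    a1 <- series_1$data[[channel_1]]
  } else a1 <- series_1
  if (inherits(series_2, "image_series")) {
    a2 <- series_2$data[[channel_2 %||% channel_1]]
  } else a2 <- series_2
  stopifnot(identical(dim(a1), dim(a2)), inherits(mask, "mask_stack"))
  M <- static_grid(mask)
  nf <- dim(a1)[1]
  max_lag <- min(max_lag, nf - 1L)
  idx <- which(M)
  if (length(idx) < 2L) stop("fewer than 2 included pixels")
  X1 <- matrix(a1, nrow = nf)[, idx, drop = FALSE]
  X2 <- matrix(a2, nrow = nf)[, idx, drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  ok <- m1 != 0 & m2 != 0
  if (!all(ok)) {
    warning(sum(!ok), " zero-mean pixel(s) skipped")
    X1 <- X1[, ok, drop = FALSE]; X2 <- X2[, ok, drop = FALSE]
    m1 <- m1[ok]; m2 <- m2[ok]
    if (length(m1) < 2L) stop("fewer than 2 usable pixels")
  }
  D1 <- sweep(X1, 2, m1); D2 <- sweep(X2, 2, m2)
  # lagged sums for all pixels at once via zero-padded FFT:
  # sum_t d1(t) d2(t+m) = IFFT(conj(F1) * F2)[m]
  pad <- stats::nextn(2L * nf, 2)
  F1 <- mvfft(rbind(D1, matrix(0, pad - nf, ncol(D1))))
  F2 <- mvfft(rbind(D2, matrix(0, pad - nf, ncol(D2))))
  cc <- Re(mvfft(Conj(F1) * F2, inverse = TRUE)) / pad
  lags <- 0:max_lag
  num <- cc[lags + 1L, , drop = FALSE] / (nf - lags)
  Gpix <- sweep(num, 2, m1 * m2, "/")
  G <- rowMeans(Gpix)
  ci <- 1.96 * apply(Gpix, 1, sd) / sqrt(ncol(Gpix))
  frame_time <- geometry$frame_time %||% 1
  kind <- if (identical(a1, a2)) "auto" else "cross"
  structure(list(lag_s = lags * frame_time, lags = lags, G = G, ci95 = ci,
                 n_pixels = ncol(Gpix), kind = kind,
                 frame_time = frame_time),
            class = "temporal_cf")
}

#' @export
print.temporal_cf <- function(x, ...) {
  cat(sprintf("<temporal_cf> %s, %d lags, %d pixels, G(1) = %.3g\n",
              x$kind, length(x$lags), x$n_pixels,
              if (length(x$G) > 1) x$G[2] else NA))
  invisible(x)
}

#' Fit the 2D diffusion model to a temporal correlation curve
#'
#' Weighted least squares of
#' \eqn{G(\tau) = A_D (1 + 4 D \tau / \omega_r^2)^{-1} + A_0}
#' over lags 1..`max_lag_frames`. The zero lag is excluded (uncorrelated
#' shot and read noise). The fit window default of 12 frames avoids the
#' influence of very slow motion such as cell drift. Note the model treats
#' the detection profile as a Gaussian of waist \eqn{\omega_r} and ignores
#' the finite pixel size, which biases `D` slightly when pixels are not
#' small against the waist.
#'
#' @param cf A [temporal_correlate()] result.
#' @param geometry The camera [acquisition_geometry()] (supplies
#'   \eqn{\omega_r}).
#' @param max_lag_frames Last lag (in frames) included in the fit.
#' @return An object of class `tics_fit` with `A_D`, `D`, `A_0`, standard
#'   errors and residuals. `amplitude0` is the fitted model at zero lag,
#'   `A_D + A_0`.
#' @export
fit_tics <- function(cf, geometry, max_lag_frames = 12L) {
  stopifnot(inherits(cf, "temporal_cf"),
            inherits(geometry, "acquisition_geometry"))
  use <- cf$lags >= 1L & cf$lags <= max_lag_frames
  if (sum(use) < 4L) stop("fewer than 4 usable lags")
  d <- data.frame(tau = cf$lag_s[use], G = cf$G[use], ci = cf$ci95[use])
  w2 <- geometry$focal_waist^2
  pos <- d$ci[is.finite(d$ci) & d$ci > 0]
  w <- if (length(pos)) 1 / pmax(d$ci, min(pos))^2 else rep(1, nrow(d))
  start <- list(A_D = max(d$G[1], 1e-6), D = 0.05, A_0 = min(d$G))
  fit <- try(minpack.lm::nlsLM(
    G ~ A_D / (1 + 4 * D * tau / w2) + A_0,
    data = d, start = start, weights = w,
    lower = c(A_D = -Inf, D = 0, A_0 = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(structure(list(A_D = NA_real_, D = NA_real_, A_0 = NA_real_,
                          amplitude0 = NA_real_, converged = FALSE,
                          message = attr(fit, "condition")$message),
                     class = "tics_fit"))
  }
  cfs <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  structure(list(A_D = unname(cfs["A_D"]), D = unname(cfs["D"]),
                 A_0 = unname(cfs["A_0"]),
                 amplitude0 = unname(cfs["A_D"] + cfs["A_0"]),
                 se = se, converged = TRUE,
                 residuals = stats::resid(fit), data = d),
            class = "tics_fit")
}

#' @export
print.tics_fit <- function(x, ...) {
  cat(sprintf("<tics_fit> A_D = %.3g, D = %.4g um^2/s, A_0 = %.3g%s\n",
              x$A_D, x$D, x$A_0,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Relative cross-correlation of a dual-color series
#'
#' The fitted zero-lag cross-correlation amplitude divided by the mean of
#' the two fitted autocorrelation amplitudes: a proxy for the co-diffusing
#' fraction. Even covalently linked species typically reach only ~50-60%
#' because of incomplete fluorophore maturation and partial detection-volume
#' overlap.
#'
#' @param fit_ccf,fit_acf1,fit_acf2 [fit_tics()] results for the
#'   cross-correlation and the two autocorrelations, computed on the same
#'   pixel set.
#' @return An object of class `cross_corr_result` with `rel_cc` and the
#'   three zero-lag amplitudes.
#' @export
relative_cc <- function(fit_ccf, fit_acf1, fit_acf2) {
  stopifnot(inherits(fit_ccf, "tics_fit"), inherits(fit_acf1, "tics_fit"),
            inherits(fit_acf2, "tics_fit"))
  a1 <- fit_acf1$amplitude0; a2 <- fit_acf2$amplitude0
  if (!is.finite(a1) || !is.finite(a2) || a1 + a2 <= 0)
    stop("autocorrelation amplitudes are not positive")
  cc <- fit_ccf$amplitude0
  if (!is.finite(cc) || cc < 0) {
    warning("negative cross-correlation amplitude floored at 0")
    cc <- max(cc, 0, na.rm = TRUE)
    if (!is.finite(cc)) cc <- 0
  }
  structure(list(rel_cc = cc / ((a1 + a2) / 2),
                 ccf0 = cc, acf1_0 = a1, acf2_0 = a2),
            class = "cross_corr_result")
}

#' @export
print.cross_corr_result <- function(x, ...) {
  cat(sprintf("<cross_corr> Rel.CC = %.3f (CCF %.3g / ACFs %.3g, %.3g)\n",
              x$rel_cc, x$ccf0, x$acf1_0, x$acf2_0))
  invisible(x)
}
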