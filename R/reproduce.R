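#' Closed-loop recovery experiments
#'
#' Each `recovery_*()` function regenerates one of the package's validation
#' experiments end to end: synthetic data are generated at known ground
#' truth with the full acquisition model, pushed through the corresponding
#' analysis pipeline, and the fitted parameters are tabulated against the
#' truth. They back the `reproduce` CLI subcommand and the acceptance
#' checks, and are the recommended way to re-verify the estimators after
#' any change.
#'
#' `recovery_rics()` renders raster-scanned confocal series of a diffusing
#' membrane scene and recovers the diffusion constant by masked RICS.
#' `recovery_tics()` renders camera series and recovers it by the temporal
#' correlation fit over lags 1..12. `recovery_binomial()` draws bleaching
#' step counts from the two-binomial spot model and refits the maturation
#' probability and single-complex fraction. `recovery_heteromer()` draws
#' counts from the homo/hetero mixture and refits the heteromeric fraction
#' with the branch parameters fixed.
#'
#' @param D_values True diffusion constants (um^2/s), one condition each.
#' @param seeds Integer seeds; one replicate per seed.
#' @param n_frames Frames per rendered series.
#' @param dim Frame size `(rows, cols)` in pixels.
#' @param density Particle density per um^2.
#' @param brightness Per-complex brightness in kHz.
#' @param background Background rate in kHz.
#' @param geometry Acquisition geometry of the rendered series.
#' @param verbose Print one line per replicate.
#' @return A data frame of per-replicate fits, with the per-condition means
#'   attached as attribute `"summary"`.
#' @export
recovery_rics <- function(D_values, seeds = 1:10, n_frames = 100L,
                          dim = c(256L, 256L), density = 20,
                          brightness = 100, background = 0.1,
                          geometry = confocal_geometry(), verbose = FALSE) {
  rows <- list()
  for (D in D_values) {
    p <- scene_params(box_size = dim[2] * geometry$pixel_size * 1.25,
                      density = density, D = D, brightness = brightness,
                      background = background)
    for (seed in seeds) {
      tr <- simulate_trajectories(p, n_frames * geometry$frame_time + 0.1,
                                  geometry$line_time, seed, store = "lazy")
      s <- render_confocal_series(tr, geometry, n_frames, seed, dim = dim)
      mask <- cluster_mask(s, mode = "static")
      fit <- fit_rics(spatial_correlate(moving_average_correct(s), mask),
                      geometry)
      rows[[length(rows) + 1L]] <-
        data.frame(D_true = D, seed = seed, D_fit = fit$D, N_fit = fit$N)
      if (verbose)
        message(sprintf("rics D=%.3g seed=%d -> D_fit=%.4g", D, seed,
                        fit$D))
    }
  }
  finish_recovery(do.call(rbind, rows))
}

#' @rdname recovery_rics
#' @export
recovery_tics <- function(D_values, seeds = 1:10, n_frames = 400L,
                          dim = c(64L, 64L), density = 20,
                          brightness = 100, background = 0.5,
                          geometry = camera_geometry(), verbose = FALSE) {
  rows <- list()
  for (D in D_values) {
    p <- scene_params(box_size = dim[2] * geometry$pixel_size * 1.25,
                      density = density, D = D, brightness = brightness,
                      background = background)
    for (seed in seeds) {
      tr <- simulate_trajectories(p, n_frames * geometry$frame_time + 0.1,
                                  geometry$frame_time, seed, store = "lazy")
      s <- render_camera_series(tr, geometry, n_frames, seed, dim = dim)
      mask <- cluster_mask(s, mode = "static")
      cf <- temporal_correlate(detrend_frames(s), mask = mask, max_lag = 15L)
      fit <- fit_tics(cf, geometry, max_lag_frames = 12L)
      rows[[length(rows) + 1L]] <-
        data.frame(D_true = D, seed = seed, D_fit = fit$D, N_fit = NA_real_)
      if (verbose)
        message(sprintf("tics D=%.3g seed=%d -> D_fit=%.4g", D, seed,
                        fit$D))
    }
  }
  finish_recovery(do.call(rbind, rows))
}

#' @rdname recovery_rics
#' @param n_spots Observed spots per replicate.
#' @param p_m,A True maturation probability and single-complex fraction.
#' @export
recovery_binomial <- function(seeds = 1:10, n_spots = 477L, p_m = 0.47,
                              A = 0.88) {
  rows <- lapply(seeds, function(seed) {
    params <- bleach_sim_params(p_m = p_m, A = A)
    h <- build_histogram(simulate_step_counts(params, n_spots, seed))
    fit <- fit_binomial(h, "homo")
    data.frame(seed = seed, p_m_true = p_m, A_true = A,
               p_m_fit = fit$p_m, A_fit = fit$A, p_value = fit$p_value)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- data.frame(p_m_pct = 100 * mean(out$p_m_fit),
                                     A_pct = 100 * mean(out$A_fit),
                                     n = n_spots)
  out
}

#' @rdname recovery_rics
#' @param heteromeric_fraction True heteromer fraction (`1 - H`).
#' @param het Heteromer label order.
#' @param rank_orders Also scan label orders 1..4 per replicate and record
#'   the top-ranked order.
#' @export
recovery_heteromer <- function(seeds = 1:10, n_spots = 301L,
                               heteromeric_fraction = 0.36, p_m = 0.47,
                               A = 0.88, het = 3L, rank_orders = FALSE) {
  H_true <- 1 - heteromeric_fraction
  rows <- lapply(seeds, function(seed) {
    params <- bleach_sim_params(p_m = p_m, A = A, H = H_true, het = het)
    h <- build_histogram(simulate_step_counts(params, n_spots, seed))
    fit <- fit_binomial(h, "mixture", het = het, p_m = p_m, A = A)
    top <- if (rank_orders)
      attr(scan_heteromer_orders(h, p_m = p_m, A = A), "ranking")$het[1]
    else NA_integer_
    data.frame(seed = seed, het_fraction_true = heteromeric_fraction,
               het_fraction_fit = 1 - fit$H, p_value = fit$p_value,
               top_order = top)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <-
    data.frame(het_fraction_pct = 100 * mean(out$het_fraction_fit),
               n = n_spots,
               top_order_wins = if (rank_orders) sum(out$top_order == het)
               else NA_integer_)
  out
}

finish_recovery <- function(df) {
  agg <- stats::aggregate(D_fit ~ D_true, df, mean)
  agg$rel_error <- (agg$D_fit - agg$D_true) / agg$D_true
  attr(df, "summary") <- agg
  df
}
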