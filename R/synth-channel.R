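#' Parameters of the two-state single-channel current generator
#'
#' Continuous-time Markov gating between a closed (baseline) and an open
#' level, sampled at a fixed rate with additive Gaussian noise: the
#' generative twin of the window-based double-Gaussian amplitude analysis.
#'
#' @param baseline Baseline (closed) current in pA.
#' @param amplitude Open-channel current amplitude in pA (added to baseline
#'   while open).
#' @param k_open Closed-to-open rate in 1/s.
#' @param k_close Open-to-closed rate in 1/s.
#' @param noise_sd Gaussian noise SD in pA.
#' @param sampling_rate Sampling rate in Hz.
#' @return An object of class `channel_sim_params`.
#' @export
channel_sim_params <- function(baseline = 0, amplitude = 4,
                               k_open = 5, k_close = 20,
                               noise_sd = 0.5, sampling_rate = 5000) {
  stopifnot(k_open > 0, k_close > 0, noise_sd >= 0, sampling_rate > 0)
  structure(list(baseline = baseline, amplitude = amplitude,
                 k_open = k_open, k_close = k_close,
                 noise_sd = noise_sd, sampling_rate = sampling_rate),
            class = "channel_sim_params")
}

#' Simulate a two-level single-channel current trace
#'
#' Gillespie simulation of the two-state gating chain; the stationary open
#' probability is `k_open / (k_open + k_close)`.
#'
#' @param params A [channel_sim_params()].
#' @param duration Trace duration in seconds.
#' @param seed Integer RNG seed.
#' @return A [current_trace()] with the ground-truth open-state indicator
#'   attached as attribute `"open"` and the true amplitude as `"amplitude"`.
#' @examples
#' tr <- simulate_channel_trace(channel_sim_params(), 1, seed = 1)
#' @export
simulate_channel_trace <- function(params, duration, seed) {
  stopifnot(inherits(params, "channel_sim_params"), duration > 0)
  set.seed(substream_seed(seed, "channel_trace"))
  # alternating closed/open dwells until the duration is covered
  t_acc <- 0
  bounds <- numeric(0)
  state0 <- runif(1) < params$k_open / (params$k_open + params$k_close)
  state <- state0
  while (t_acc < duration) {
    rate <- if (state) params$k_close else params$k_open
    t_acc <- t_acc + rexp(1, rate)
    bounds <- c(bounds, t_acc)
    state <- !state
  }
  dt <- 1 / params$sampling_rate
  tt <- seq(0, duration - dt, by = dt)
  n_switch <- findInterval(tt, bounds)
  # the state flips at each dwell boundary
  open <- if (state0) n_switch %% 2 == 0 else n_switch %% 2 == 1
  cur <- params$baseline + params$amplitude * open +
    rnorm(length(tt), 0, params$noise_sd)
  out <- current_trace(cur, dt)
  attr(out, "open") <- open
  attr(out, "amplitude") <- params$amplitude
  out
}
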