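#' Parameters of the photobleaching-trace generator
#'
#' Generative twin of the binomial step-count models: a diffraction-limited
#' spot contains one receptor complex with probability `A` and two with
#' probability `1 - A`; each complex is a homopentamer carrying `n` nominal
#' labels with probability `H`, otherwise a heteropentamer carrying `het`
#' labels; every nominal label is mature and unbleached at the start with
#' probability `p_m`, and each mature label bleaches in a single step at a
#' geometrically distributed frame.
#'
#' @param n Pentamer label order for homomers (default 5).
#' @param p_m Maturation probability.
#' @param A Fraction of spots containing a single complex.
#' @param H Fraction of homopentamers (`1` = homomers only).
#' @param het Heteromer label order (1..n).
#' @param unit_intensity Intensity contributed by one surviving label.
#' @param baseline Camera background level under the summed spot window
#'   (keeps the fully-bleached tail away from the zero clip).
#' @param noise_sd Gaussian noise SD added per frame.
#' @param mean_lifetime Mean bleaching lifetime in frames.
#' @param trace_length Trace length in frames.
#' @return An object of class `bleach_sim_params`.
#' @export
bleach_sim_params <- function(n = 5L, p_m = 0.47, A = 0.88, H = 1,
                              het = 3L, unit_intensity = 100,
                              baseline = 200, noise_sd = 10,
                              mean_lifetime = 40, trace_length = 400L) {
  stopifnot(p_m >= 0, p_m <= 1, A >= 0, A <= 1, H >= 0, H <= 1,
            het >= 1, het <= n, mean_lifetime > 0, trace_length >= 1,
            baseline >= 0)
  structure(list(n = as.integer(n), p_m = p_m, A = A, H = H,
                 het = as.integer(het), unit_intensity = unit_intensity,
                 baseline = baseline, noise_sd = noise_sd,
                 mean_lifetime = mean_lifetime,
                 trace_length = as.integer(trace_length)),
            class = "bleach_sim_params")
}

# Draw one spot's true label count from the generative model.
draw_label_counts <- function(params, n_spots) {
  order <- ifelse(runif(n_spots) < params$H, params$n, params$het)
  doubled <- runif(n_spots) >= params$A          # spot holds two complexes
  rbinom(n_spots, order * (1L + doubled), params$p_m)
}

#' Simulate spot step counts from the binomial stoichiometry model
#'
#' Draws per-spot label (= bleaching-step) counts from the generative twin of
#' the homo/hetero binomial mixture. Spots with zero mature labels are
#' invisible to spot detection; with `observed_only = TRUE` (default) draws
#' are rejected until `n_spots` spots with at least one step are collected,
#' matching histograms whose support starts at one step.
#'
#' @param params A [bleach_sim_params()].
#' @param n_spots Number of spots.
#' @param seed Integer RNG seed.
#' @param observed_only Keep only spots with >= 1 label.
#' @return Integer vector of true step counts.
#' @examples
#' x <- simulate_step_counts(bleach_sim_params(p_m = 1, A = 1), 10, seed = 1)
#' stopifnot(all(x == 5))
#' @export
simulate_step_counts <- function(params, n_spots, seed,
                                 observed_only = TRUE) {
  stopifnot(inherits(params, "bleach_sim_params"), n_spots >= 1)
  set.seed(substream_seed(seed, "step_counts"))
  out <- integer(0)
  while (length(out) < n_spots) {
    x <- draw_label_counts(params, max(n_spots, 100L))
    if (observed_only) x <- x[x > 0L]
    out <- c(out, x)
  }
  out[seq_len(n_spots)]
}

#' Simulate stepwise photobleaching intensity traces
#'
#' Each spot's trace is `unit_intensity` times the number of surviving labels
#' plus Gaussian noise; every label bleaches once at a geometric frame with
#' the configured mean lifetime.
#'
#' @inheritParams simulate_step_counts
#' @return A list with `traces` (list of [intensity_trace()]),
#'   `true_steps` (integer vector) and `params`.
#' @export
simulate_bleach_traces <- function(params, n_spots, seed) {
  stopifnot(inherits(params, "bleach_sim_params"), n_spots >= 1)
  set.seed(substream_seed(seed, "bleach_traces"))
  counts <- draw_label_counts(params, n_spots)
  L <- params$trace_length
  traces <- vector("list", n_spots)
  for (i in seq_len(n_spots)) {
    k <- counts[i]
    surv <- rep(k, L)
    if (k > 0L) {
      # each label is bright through its geometric bleach frame (mean
      # `mean_lifetime`) and dark afterwards
      tb <- rgeom(k, 1 / params$mean_lifetime) + 1L
      for (t in tb) if (t < L) surv[(t + 1L):L] <- surv[(t + 1L):L] - 1L
    }
    vals <- params$baseline + params$unit_intensity * surv +
      rnorm(L, 0, params$noise_sd)
    traces[[i]] <- intensity_trace(pmax(vals, 0), frame_interval = 0.1)
  }
  list(traces = traces, true_steps = counts, params = params)
}
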