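#' Zero-phase Gaussian low-pass filter for current traces
#'
#' Convolves the trace with a Gaussian kernel whose amplitude response is
#' down 3 dB at `cutoff` (sigma = sqrt(ln 2) / (2 pi f_c)). The trace is
#' reflectively padded so its length is preserved, and step plateau means
#' are preserved because the kernel is normalized and symmetric.
#'
#' @param trace A [current_trace()].
#' @param cutoff -3 dB cutoff frequency in Hz (default 100).
#' @return The filtered [current_trace()].
#' @export
gaussian_lowpass <- function(trace, cutoff = 100) {
  stopifnot(inherits(trace, "current_trace"), cutoff > 0)
  fs <- 1 / trace$dt
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  sigma_s <- sqrt(log(2)) / (2 * pi * cutoff) / trace$dt   # in samples
  half <- max(1L, ceiling(4 * sigma_s))
  kern <- exp(-((-half):half)^2 / (2 * sigma_s^2))
  kern <- kern / sum(kern)
  y <- trace$current
  n <- length(y)
  pad <- c(rev(y[seq_len(min(half, n))]), y,
           rev(y[(n - min(half, n) + 1L):n]))
  f <- stats::convolve(pad, rev(kern), type = "filter")
  # convolve 'filter' returns length(pad) - 2*half values
  out <- current_trace(f[seq_len(n)], trace$dt, trace$holding_potential)
  attr(out, "kernel") <- kern
  out
}

#' Analyze a short time window with a double-Gaussian amplitude histogram
#'
#' Histograms all samples in the window and fits the bin counts with a sum
#' of two Gaussians. The component nearer zero is the baseline; the mean
#' current of the window is the absolute difference between the peak and
#' baseline component means (so it is invariant to baseline offsets). A
#' window whose mixture collapses onto one component (no opening) is
#' flagged.
#'
#' @param trace A (filtered) [current_trace()].
#' @param window `c(start, end)` in seconds; windows are expected to be
#'   shorter than 1 s and to contain both current levels.
#' @param bin_width Histogram bin width in pA.
#' @return An object of class `current_window` with `baseline_pA`,
#'   `peak_pA`, `mean_current_pA`, `flagged` (single component) and the
#'   histogram.
#' @export
analyze_window <- function(trace, window, bin_width = 0.1) {
  stopifnot(inherits(trace, "current_trace"), length(window) == 2L,
            window[2] > window[1])
  n <- length(trace$current)
  i1 <- max(1L, floor(window[1] / trace$dt) + 1L)
  i2 <- min(n, ceiling(window[2] / trace$dt))
  if (i2 <= i1) stop("window outside the trace")
  y <- trace$current[i1:i2]
  breaks <- seq(floor(min(y) / bin_width) * bin_width,
                ceiling(max(y) / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- graphics::hist(y, breaks = breaks, plot = FALSE)
  d <- data.frame(mid = h$mids, cnt = h$counts)
  flagged_out <- function() {
    structure(list(window = window, baseline_pA = mean(y),
                   peak_pA = NA_real_, mean_current_pA = NA_real_,
                   flagged = TRUE, histogram = d, n_samples = length(y)),
              class = "current_window")
  }
  km <- tryCatch(kmeans(y, centers = range(y)), error = function(e) NULL)
  if (is.null(km)) return(flagged_out())
  mus <- sort(km$centers[, 1])
  sds <- pmax(tapply(y, km$cluster, sd)[order(km$centers[, 1])],
              bin_width / 2, na.rm = TRUE)
  sds[is.na(sds)] <- bin_width
  pis <- tabulate(km$cluster, 2)[order(km$centers[, 1])] / length(y)
  start <- lapply(list(a1 = max(d$cnt) * pis[1] / max(pis), mu1 = mus[1],
                       s1 = sds[1],
                       a2 = max(d$cnt) * pis[2] / max(pis), mu2 = mus[2],
                       s2 = sds[2]), unname)
  fit <- try(minpack.lm::nlsLM(
    cnt ~ a1 * exp(-(mid - mu1)^2 / (2 * s1^2)) +
      a2 * exp(-(mid - mu2)^2 / (2 * s2^2)),
    data = d, start = start,
    lower = c(0, min(y), bin_width / 10, 0, min(y), bin_width / 10),
    control = minpack.lm::nls.lm.control(maxiter = 300)), silent = TRUE)
  if (inherits(fit, "try-error")) return(flagged_out())
  cf <- coef(fit)
  if (any(!is.finite(cf))) return(flagged_out())
  comps <- rbind(c(cf["a1"], cf["mu1"], cf["s1"]),
                 c(cf["a2"], cf["mu2"], cf["s2"]))
  # collapse checks: vanishing component or unresolved means; the mixture
  # weight of a Gaussian component is proportional to its area a * s, so a
  # narrow spike fitted to histogram noise counts as vanishing
  areas <- comps[, 1] * comps[, 3]
  sep <- abs(comps[1, 2] - comps[2, 2])
  if (min(areas) / max(areas) < 0.02 || sep < max(comps[, 3]))
    return(flagged_out())
  base_i <- which.min(abs(comps[, 2]))
  baseline <- comps[base_i, 2]
  peak <- comps[-base_i, 2][1]
  structure(list(window = window, baseline_pA = unname(baseline),
                 peak_pA = unname(peak),
                 mean_current_pA = unname(abs(peak - baseline)),
                 flagged = FALSE, histogram = d, fit = cf,
                 n_samples = length(y)),
            class = "current_window")
}

#' @export
print.current_window <- function(x, ...) {
  if (x$flagged) {
    cat("<current_window> flagged: single component (no opening)\n")
  } else {
    cat(sprintf(
      "<current_window> baseline %.2f pA, peak %.2f pA, mean current %.2f pA\n",
      x$baseline_pA, x$peak_pA, x$mean_current_pA))
  }
  invisible(x)
}

#' Group similar window mean currents
#'
#' One-dimensional grouping of window mean currents with a maximum
#' within-group spread: means are sorted and swept greedily, starting a new
#' group whenever including the next value would stretch the group's
#' max-min spread beyond `tolerance`. For 1D data this sweep yields the
#' minimum possible number of groups.
#'
#' @param windows List of [analyze_window()] results (flagged windows are
#'   skipped) or a numeric vector of mean currents in pA.
#' @param tolerance Maximum within-group spread in pA (default 1).
#' @return A list of groups, each with `members` (pA) and `mean_pA`.
#' @export
group_currents <- function(windows, tolerance = 1) {
  means <- if (is.numeric(windows)) windows else
    vapply(Filter(function(w) !w$flagged, windows),
           function(w) w$mean_current_pA, numeric(1))
  if (!length(means)) return(list())
  s <- sort(means)
  groups <- list()
  cur <- s[1]
  for (v in s[-1]) {
    if (v - cur[1] <= tolerance) cur <- c(cur, v)
    else {
      groups[[length(groups) + 1L]] <- cur
      cur <- v
    }
  }
  groups[[length(groups) + 1L]] <- cur
  lapply(groups, function(g) list(members = g, mean_pA = mean(g)))
}

#' Propose candidate analysis windows by variance-burst detection
#'
#' Convenience helper (window selection is otherwise manual): slides a
#' window along the filtered trace and proposes spans whose sample SD
#' exceeds a multiple of the trace's baseline noise, indicating channel
#' activity.
#'
#' @param trace A (filtered) [current_trace()].
#' @param width Window width in seconds (default 0.5; keep below 1 s).
#' @param sd_factor Burst threshold as a multiple of the 20th-percentile
#'   rolling SD.
#' @return A matrix with columns `start`, `end` (seconds); possibly empty.
#' @export
propose_windows <- function(trace, width = 0.5, sd_factor = 2) {
  stopifnot(inherits(trace, "current_trace"))
  n <- length(trace$current)
  w <- max(10L, round(width / trace$dt))
  starts <- seq(1L, max(1L, n - w + 1L), by = max(1L, w %/% 2L))
  sds <- vapply(starts, function(i)
    sd(trace$current[i:(i + w - 1L)]), numeric(1))
  base <- quantile(sds, 0.2, na.rm = TRUE)
  hit <- which(sds > sd_factor * base)
  if (!length(hit)) return(matrix(numeric(0), 0, 2,
                                  dimnames = list(NULL, c("start", "end"))))
  cbind(start = (starts[hit] - 1L) * trace$dt,
        end = pmin(n, starts[hit] + w - 1L) * trace$dt)
}
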