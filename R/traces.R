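#' Single-spot intensity trace
#'
#' Ordered per-frame intensity samples for one diffraction-limited spot,
#' typically the 3 x 3 pixel sum about the spot center, used for
#' photobleaching step counting.
#'
#' @param values Numeric vector of intensities, one per frame.
#' @param frame_interval Frame interval in seconds.
#' @param center Optional `(row, col)` spot center.
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(values, frame_interval, center = c(NA, NA)) {
  stopifnot(length(values) >= 1L, all(is.finite(values)),
            is.numeric(frame_interval), frame_interval > 0)
  structure(list(values = as.numeric(values),
                 frame_interval = frame_interval,
                 center = center),
            class = "intensity_trace")
}

#' Patch-clamp current trace
#'
#' @param current Numeric vector of currents in pA.
#' @param dt Sampling interval in seconds.
#' @param holding_potential Holding potential in mV (metadata only).
#' @return An object of class `current_trace`.
#' @export
current_trace <- function(current, dt, holding_potential = NA_real_) {
  stopifnot(all(is.finite(current)), is.numeric(dt), dt > 0)
  structure(list(current = as.numeric(current), dt = dt,
                 holding_potential = holding_potential),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples at %g kHz (%.3g s)\n",
              length(x$current), 1e-3 / x$dt, length(x$current) * x$dt))
  invisible(x)
}

#' Read a current trace from CSV
#'
#' Accepts a single-column file (values; `dt` must be given) or a two-column
#' `(time, value)` file from which the sampling interval is inferred.
#'
#' @param path CSV file path.
#' @param dt Sampling interval in seconds (single-column files).
#' @param holding_potential Holding potential in mV.
#' @return A [current_trace()].
#' @export
read_current_trace <- function(path, dt = NULL, holding_potential = NA_real_) {
  df <- read.csv(path)
  if (ncol(df) >= 2L) {
    tt <- df[[1]]
    if (is.null(dt)) dt <- median(diff(tt))
    current_trace(df[[2]], dt, holding_potential)
  } else {
    if (is.null(dt)) stop("single-column trace files require 'dt'")
    current_trace(df[[1]], dt, holding_potential)
  }
}

#' Write a current trace to CSV
#' @param trace A [current_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_current_trace <- function(trace, path) {
  df <- data.frame(time_s = (seq_along(trace$current) - 1) * trace$dt,
                   current_pA = trace$current)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
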