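#' Detect diffraction-limited spots for subunit counting
#'
#' Finds local maxima in the average of the first frames whose contrast over
#' the local background, \eqn{\delta F / F}, exceeds `snr_threshold`. Each
#' candidate claims a 5 x 5 pixel window; candidates with intersecting
#' windows are partially overlapping and all of them are discarded.
#' Intensity traces are extracted as 3 x 3 pixel sums about each accepted
#' center across all frames.
#'
#' @param series A camera [image_series()].
#' @param snr_threshold Minimum `(peak - background) / background` contrast
#'   (default 0.20).
#' @param n_avg_frames Frames averaged for detection.
#' @param window Detection window size (odd; default 5).
#' @param channel Channel to analyze (single-molecule counting uses the
#'   photostable eGFP channel).
#' @return A list of spot records, each with `center`, `trace` (an
#'   [intensity_trace()] of 3 x 3 sums) and `contrast`; the overlap-discarded
#'   count is attached as attribute `"n_overlap_discarded"`.
#' @export
detect_spots <- function(series, snr_threshold = 0.20, n_avg_frames = 10L,
                         window = 5L, channel = 1L) {
  stopifnot(inherits(series, "image_series"))
  if (series$geometry$modality != "camera")
    stop("spot detection expects a camera series")
  a <- series$data[[channel]]
  nf <- dim(a)[1]
  n_avg_frames <- min(n_avg_frames, nf)
  avg <- apply(a[seq_len(n_avg_frames), , , drop = FALSE], c(2, 3), mean)
  nr <- nrow(avg); nc <- ncol(avg)
  half <- (window - 1L) %/% 2L
  cand <- list()
  for (r in (half + 1L):(nr - half)) {
    for (c in (half + 1L):(nc - half)) {
      v <- avg[r, c]
      nb <- avg[(r - 1L):(r + 1L), (c - 1L):(c + 1L)]
      if (v < max(nb)) next
      win <- avg[(r - half):(r + half), (c - half):(c + half)]
      ring <- c(win[1, ], win[window, ], win[2:(window - 1L), 1],
                win[2:(window - 1L), window])
      bg <- mean(ring)
      if (bg <= 0) next
      contrast <- (v - bg) / bg
      if (contrast >= snr_threshold)
        cand[[length(cand) + 1L]] <- list(center = c(r, c),
                                          contrast = contrast)
    }
  }
  if (!length(cand)) {
    out <- list()
    attr(out, "n_overlap_discarded") <- 0L
    return(out)
  }
  centers <- do.call(rbind, lapply(cand, `[[`, "center"))
  # windows intersect iff both center offsets are < window size
  overlap <- rep(FALSE, nrow(centers))
  if (nrow(centers) > 1L) {
    for (i in seq_len(nrow(centers) - 1L)) {
      for (j in (i + 1L):nrow(centers)) {
        if (all(abs(centers[i, ] - centers[j, ]) < window)) {
          overlap[i] <- TRUE; overlap[j] <- TRUE
        }
      }
    }
  }
  keep <- which(!overlap)
  dt <- series$geometry$frame_time %||% 1
  spots <- lapply(keep, function(i) {
    ctr <- centers[i, ]
    tr <- apply(a[, (ctr[1] - 1L):(ctr[1] + 1L),
                  (ctr[2] - 1L):(ctr[2] + 1L), drop = FALSE], 1, sum)
    list(center = ctr, contrast = cand[[i]]$contrast,
         trace = intensity_trace(tr, dt, ctr))
  })
  attr(spots, "n_overlap_discarded") <- sum(overlap)
  spots
}

# Change-point step idealization minimizing the Schwarz information
# criterion (Kalafut-Visscher): candidate change points are added greedily
# at the split giving the largest residual sum-of-squares reduction while
# the SIC decreases; after each insertion every change point is re-located
# to its locally optimal position, and finally change points whose removal
# lowers the SIC are dropped.
sic_steps <- function(y, max_steps = 30L) {
  T <- length(y)
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  seg_rss <- function(lo, hi) {
    # RSS of y[lo:hi] about its mean, via the global cumulative sums
    n <- hi - lo + 1L
    s <- cs[hi] - if (lo > 1L) cs[lo - 1L] else 0
    s2 <- cs2[hi] - if (lo > 1L) cs2[lo - 1L] else 0
    max(s2 - s^2 / n, 0)
  }
  best_split <- function(lo, hi) {
    # best single change point inside [lo, hi]
    n <- hi - lo + 1L
    if (n < 2L) return(NULL)
    v <- y[lo:hi]
    vs <- cumsum(v); vs2 <- cumsum(v^2)
    k <- seq_len(n - 1L)
    rss_l <- vs2[k] - vs[k]^2 / k
    rss_r <- (vs2[n] - vs2[k]) - (vs[n] - vs[k])^2 / (n - k)
    i <- which.min(rss_l + rss_r)
    list(cp = lo + i - 1L, rss = rss_l[i] + rss_r[i])
  }
  total_rss <- function(cps) {
    bounds <- c(0L, cps, T)
    sum(vapply(seq_len(length(bounds) - 1L), function(s)
      seg_rss(bounds[s] + 1L, bounds[s + 1L]), numeric(1)))
  }
  refine <- function(cps) {
    # coordinate descent: move each change point to the optimal split of
    # the span between its neighbors
    repeat {
      moved <- FALSE
      for (i in seq_along(cps)) {
        lo <- if (i == 1L) 1L else cps[i - 1L] + 1L
        hi <- if (i == length(cps)) T else cps[i + 1L]
        sp <- best_split(lo, hi)
        if (!is.null(sp) && sp$cp != cps[i]) {
          old <- seg_rss(lo, cps[i]) + seg_rss(cps[i] + 1L, hi)
          if (sp$rss < old) {
            cps[i] <- sp$cp
            moved <- TRUE
          }
        }
      }
      if (!moved) return(cps)
    }
  }
  sic <- function(k, rss) (k + 2) * log(T) + T * log(max(rss / T, 1e-300))
  cps <- integer(0)   # cp = last index of a segment
  cur_sic <- sic(0L, total_rss(cps))
  repeat {
    bounds <- c(0L, cps, T)
    best <- NULL
    for (s in seq_len(length(bounds) - 1L)) {
      lo <- bounds[s] + 1L; hi <- bounds[s + 1L]
      sp <- best_split(lo, hi)
      if (is.null(sp)) next
      gain <- seg_rss(lo, hi) - sp$rss
      if (is.null(best) || gain > best$gain)
        best <- list(cp = sp$cp, gain = gain)
    }
    if (is.null(best) || length(cps) >= max_steps) break
    cand <- refine(sort(c(cps, best$cp)))
    new_sic <- sic(length(cand), total_rss(cand))
    if (new_sic >= cur_sic) break
    cps <- cand
    cur_sic <- new_sic
  }
  # removal pass: drop any change point whose removal lowers the SIC
  repeat {
    if (!length(cps)) break
    sics <- vapply(seq_along(cps), function(i)
      sic(length(cps) - 1L, total_rss(cps[-i])), numeric(1))
    i <- which.min(sics)
    if (sics[i] >= cur_sic) break
    cps <- cps[-i]
    cur_sic <- sics[i]
    if (length(cps)) cps <- refine(cps)
  }
  cps
}

#' Count photobleaching steps in a single-spot intensity trace
#'
#' Locates intensity change points by iterative information-criterion step
#' fitting, then applies the acceptance filters of single-molecule subunit
#' counting: every dwell must last at least `min_dwell` frames, every step
#' must be downward with the final level the lowest, no step amplitude may
#' deviate from the median step amplitude by more than `amp_tolerance`
#' (relative), and every step must exceed `step_snr_min` times the pooled
#' noise SD of its two adjacent dwells.
#'
#' @param trace An [intensity_trace()] or numeric vector.
#' @param min_dwell Minimum dwell length in frames (default 3).
#' @param amp_tolerance Maximum relative deviation of a step amplitude from
#'   the median step amplitude (default 0.60).
#' @param step_snr_min Minimum step amplitude over local noise SD
#'   (default 2).
#' @return A list with `accepted` (logical), `n_steps` (count, or `NA` when
#'   rejected), `reason` (rejection reason code or `NA`), `changepoints`
#'   and `levels`.
#' @examples
#' y <- rep(c(300, 200, 100, 0), each = 10)
#' find_steps(y)$n_steps  # 3
#' @export
find_steps <- function(trace, min_dwell = 3L, amp_tolerance = 0.60,
                       step_snr_min = 2) {
  y <- if (inherits(trace, "intensity_trace")) trace$values else trace
  reject <- function(reason)
    list(accepted = FALSE, n_steps = NA_integer_, reason = reason,
         changepoints = integer(0), levels = numeric(0))
  cps <- sic_steps(y)
  if (!length(cps)) return(reject("no_steps"))
  bounds <- c(0L, cps, length(y))
  dwells <- diff(bounds)
  levels <- vapply(seq_len(length(bounds) - 1L), function(s)
    mean(y[(bounds[s] + 1L):bounds[s + 1L]]), numeric(1))
  sds <- vapply(seq_len(length(bounds) - 1L), function(s)
    sd(y[(bounds[s] + 1L):bounds[s + 1L]]), numeric(1))
  sds[is.na(sds)] <- 0
  amps <- -diff(levels)               # positive for downward steps
  if (any(dwells < min_dwell)) return(reject("short_dwell"))
  if (any(amps <= 0)) return(reject("upward_step"))
  if (which.min(levels) != length(levels)) return(reject("final_not_lowest"))
  med <- median(amps)
  if (med > 0 && any(abs(amps - med) / med > amp_tolerance))
    return(reject("amplitude_outlier"))
  pooled <- sqrt((sds[-length(sds)]^2 + sds[-1]^2) / 2)
  if (any(pooled > 0 & amps < step_snr_min * pooled))
    return(reject("low_step_snr"))
  list(accepted = TRUE, n_steps = length(amps), reason = NA_character_,
       changepoints = cps, levels = levels)
}

#' Count steps for a set of detected spots
#'
#' Convenience wrapper applying [find_steps()] to every spot from
#' [detect_spots()] (or every trace of a [simulate_bleach_traces()] result).
#'
#' @param spots List of spot records with a `trace` element, or a list of
#'   [intensity_trace()] objects.
#' @param ... Passed to [find_steps()].
#' @return Data frame with `n_steps` (`NA` when rejected) and `reason`.
#' @export
count_spot_steps <- function(spots, ...) {
  res <- lapply(spots, function(s) {
    tr <- if (!is.null(s$trace)) s$trace else s
    find_steps(tr, ...)
  })
  data.frame(n_steps = vapply(res, function(r)
    if (r$accepted) r$n_steps else NA_integer_, integer(1)),
    reason = vapply(res, function(r) r$reason %||% NA_character_,
                    character(1)))
}
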