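#' Boolean inclusion masks aligned to an image series
#'
#' A `mask_stack` is either one static inclusion grid shared by all frames or
#' one grid per frame, plus a provenance record of how it was built. A mask
#' without any included pixel is flagged `empty`.
#'
#' @param mask Logical matrix (static) or 3-d logical array `[frame, row,
#'   col]` (per-frame).
#' @param provenance Named list recording mode, threshold factor,
#'   neighborhood and smoothing.
#' @return An object of class `mask_stack`.
#' @export
mask_stack <- function(mask, provenance = list()) {
  static <- is.matrix(mask)
  stopifnot(is.logical(mask), static || length(dim(mask)) == 3L)
  structure(list(mask = mask, static = static, provenance = provenance,
                 empty = !any(mask)),
            class = "mask_stack")
}

#' @export
print.mask_stack <- function(x, ...) {
  cat(sprintf("<mask_stack> %s, %.1f%% included%s\n",
              if (x$static) "static" else
                sprintf("per-frame (%d)", dim(x$mask)[1]),
              100 * mean(x$mask), if (x$empty) " [EMPTY]" else ""))
  invisible(x)
}

# Collapse a mask_stack to a single static grid (intersection over frames).
static_grid <- function(mask) {
  if (mask$static) mask$mask else apply(mask$mask, c(2, 3), all)
}

# Summed-area-table box mean with shrinking windows at the borders (no
# zero-padding artifacts).
box_mean <- function(mat, half) {
  nr <- nrow(mat); nc <- ncol(mat)
  sat <- function(m) {
    m <- apply(m, 2, cumsum)
    t(apply(m, 1, cumsum))
  }
  S <- sat(mat)
  C <- sat(matrix(1, nr, nc))
  r1 <- pmax(seq_len(nr) - half, 1L); r2 <- pmin(seq_len(nr) + half, nr)
  c1 <- pmax(seq_len(nc) - half, 1L); c2 <- pmin(seq_len(nc) + half, nc)
  block <- function(S) {
    A <- S[r2, c2, drop = FALSE]
    B <- matrix(0, nr, nc); D <- matrix(0, nr, nc); E <- matrix(0, nr, nc)
    B[r1 > 1, ] <- S[r1[r1 > 1] - 1L, c2, drop = FALSE]
    D[, c1 > 1] <- S[r2, c1[c1 > 1] - 1L, drop = FALSE]
    E[r1 > 1, c1 > 1] <- S[r1[r1 > 1] - 1L, c1[c1 > 1] - 1L, drop = FALSE]
    A - B - D + E
  }
  block(S) / block(C)
}

# 3x3 majority filter on a logical grid (boolean analogue of the 3x3 median
# filter; windows shrink at the borders).
median_smooth <- function(mask) {
  cnt <- box_mean(mask * 1, 1L)
  cnt > 0.5
}

#' Static polygon region of interest
#'
#' Builds a static mask that is true for pixels whose centers fall inside the
#' closed polygon (even-odd rule), emulating freehand cell-membrane
#' selection. Vertices are in pixel coordinates `(row, col)`.
#'
#' @param series An [image_series()].
#' @param vertices Numeric matrix with columns `(row, col)`, at least 3
#'   vertices.
#' @return A [mask_stack()] (static).
#' @export
polygon_roi <- function(series, vertices) {
  stopifnot(inherits(series, "image_series"), is.matrix(vertices),
            ncol(vertices) == 2L)
  if (nrow(vertices) < 3L) stop("a polygon needs at least 3 vertices")
  r <- vertices[, 1]; c <- vertices[, 2]
  area <- abs(sum(r * c[c(2:length(c), 1)] - c * r[c(2:length(r), 1)])) / 2
  if (area == 0) stop("degenerate polygon (zero area)")
  d <- dim(series$data[[1]])[2:3]
  centers <- cbind(rep(seq_len(d[1]), d[2]),
                   rep(seq_len(d[2]), each = d[1]))
  inside <- mgcv::in.out(rbind(vertices, vertices[1, ]), centers)
  m <- matrix(inside, d[1], d[2])
  ms <- mask_stack(m, provenance = list(mode = "polygon",
                                        n_vertices = nrow(vertices)))
  if (ms$empty) warning("polygon mask is empty")
  ms
}

#' Cluster-exclusion intensity threshold mask
#'
#' Excludes pixels belonging to high-intensity clusters: a pixel is excluded
#' when the boxcar mean over itself and its `neighborhood x neighborhood`
#' surroundings is at least `k` times the mean intensity of all currently
#' included pixels of the series. Because bright clusters inflate that
#' reference mean, exclusion and reference are iterated to convergence. In
#' dynamic mode the rule is applied per frame; in static mode once to the
#' time-averaged image. Each resulting grid is smoothed with a 3 x 3
#' majority (median) filter.
#'
#' @param series An [image_series()] (detrended upstream if desired).
#' @param mode `"dynamic"` (per frame) or `"static"` (time average).
#' @param k Threshold factor (> 1); default 3.
#' @param neighborhood Odd boxcar size in pixels; default 5.
#' @param roi Optional initial [mask_stack()] (e.g. a [polygon_roi()]) that
#'   is intersected with the result.
#' @param channel Channel used for thresholding.
#' @param max_iter Maximum exclusion/recompute iterations.
#' @return A [mask_stack()] (per-frame for dynamic mode, static otherwise).
#' @export
cluster_mask <- function(series, mode = c("dynamic", "static"), k = 3,
                         neighborhood = 5L, roi = NULL, channel = 1L,
                         max_iter = 10L) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "image_series"))
  if (k <= 1) stop("'k' must exceed 1 (threshold at or below the mean ",
                   "would exclude everything)")
  if (neighborhood %% 2 != 1) stop("'neighborhood' must be odd")
  half <- (neighborhood - 1L) %/% 2L
  a <- series$data[[channel]]
  nf <- dim(a)[1]
  base <- if (!is.null(roi)) static_grid(roi) else
    matrix(TRUE, dim(a)[2], dim(a)[3])
  imgs <- if (mode == "static") {
    list(apply(a, c(2, 3), mean))
  } else {
    lapply(seq_len(nf), function(f) a[f, , ])
  }
  boxed <- lapply(imgs, box_mean, half = half)
  masks <- lapply(imgs, function(x) base)
  for (iter in seq_len(max_iter)) {
    # reference: mean of the series over currently included pixels
    if (mode == "static") {
      mu <- mean(imgs[[1]][masks[[1]]])
    } else {
      tot <- 0; cnt <- 0
      for (f in seq_along(imgs)) {
        tot <- tot + sum(imgs[[f]][masks[[f]]])
        cnt <- cnt + sum(masks[[f]])
      }
      mu <- tot / cnt
    }
    new_masks <- lapply(seq_along(imgs), function(f)
      base & (boxed[[f]] < k * mu))
    if (identical(new_masks, masks)) break
    masks <- new_masks
  }
  masks <- lapply(masks, median_smooth)
  masks <- lapply(masks, function(m) m & base)
  prov <- list(mode = mode, k = k, neighborhood = neighborhood,
               smoothing = "3x3 majority", iterations = iter)
  out <- if (mode == "static") {
    mask_stack(masks[[1]], prov)
  } else {
    arr <- array(FALSE, dim(a))
    for (f in seq_len(nf)) arr[f, , ] <- masks[[f]]
    mask_stack(arr, prov)
  }
  if (out$empty) warning("cluster mask is empty")
  out
}

#' Intersection of per-frame masks
#'
#' Reduces a per-frame mask stack to the single static grid of pixels
#' included in every frame's mask.
#'
#' @param mask A [mask_stack()].
#' @return A static [mask_stack()].
#' @export
intersect_masks <- function(mask) {
  stopifnot(inherits(mask, "mask_stack"))
  g <- static_grid(mask)
  out <- mask_stack(g, modifyList(mask$provenance,
                                  list(intersected = TRUE)))
  if (out$empty) warning("intersected mask is empty")
  out
}
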