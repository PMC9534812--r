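#' Time-ordered fluorescence image series
#'
#' An `image_series` holds one intensity stack per detection channel, indexed
#' `[frame, row, column]` (0-diffusion convention: row 1 is the image top and
#' the first raster line), together with its [acquisition_geometry()].
#' Intensities are stored as non-negative reals: photon-counting inputs are
#' integers, but detrending corrections produce non-integer values that must
#' not be truncated.
#'
#' @param data A 3-d numeric array `[frame, row, col]` (single channel) or a
#'   named list of such arrays, one per channel.
#' @param geometry An [acquisition_geometry()].
#' @param channels Optional character vector of channel names; defaults to
#'   `"ch1"`, `"ch2"`.
#' @param allow_negative Permit negative values. Acquired intensities must be
#'   non-negative; detrended fluctuation series (whose corrections can dip
#'   below zero) set this internally.
#'
#' @return An object of class `image_series` with elements `data` (named list
#'   of arrays), `geometry` and `channels`.
#' @examples
#' g <- camera_geometry()
#' s <- image_series(array(1, c(4, 8, 8)), g)
#' dim(s$data[[1]])
#' @export
image_series <- function(data, geometry, channels = NULL,
                         allow_negative = FALSE) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  if (is.array(data) && !is.list(data)) data <- list(data)
  stopifnot(is.list(data), length(data) >= 1L)
  dims <- lapply(data, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    stop("each channel must be a 3-d array [frame, row, col]")
  if (length(unique(lapply(dims, identity))) != 1L)
    stop("all channels must have the same dimensions")
  if (dims[[1]][1] < 1L) stop("an image series needs at least one frame")
  for (ch in data) {
    if (anyNA(ch) || (!allow_negative && any(ch < 0)))
      stop("intensities must be non-negative and finite")
  }
  if (is.null(channels))
    channels <- names(data) %||% paste0("ch", seq_along(data))
  names(data) <- channels
  structure(list(data = data, geometry = geometry, channels = channels),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat(sprintf("<image_series> %d frame(s), %d x %d px, channels: %s\n",
              d[1], d[2], d[3], paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Number of frames in an image series
#' @param series An [image_series()].
#' @return Integer frame count.
#' @export
n_frames <- function(series) dim(series$data[[1]])[1]

#' Extract one frame of one channel as a matrix
#' @param series An [image_series()].
#' @param frame Frame index (1-based).
#' @param channel Channel index or name.
#' @return A numeric matrix `[row, col]`.
#' @export
get_frame <- function(series, frame, channel = 1L) {
  series$data[[channel]][frame, , , drop = TRUE]
}

# ---- TIFF serialization -----------------------------------------------------
#
# Multi-page TIFF, channel-interleaved (page 0 -> channel 1 frame 1, page 1 ->
# channel 2 frame 1, ...).  The 'tiff' package writes 32-bit samples scaled to
# [0, 1]; intensities are divided by a power-of-two scale factor chosen from
# the data maximum and the scale is recorded in a JSON sidecar together with
# the geometry.  Integer-valued stacks (raw photon counts) round-trip exactly;
# general real stacks round-trip to 32-bit quantization (relative error
# ~2^-32 of the scale).

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image series to a multi-page TIFF
#'
#' Pages are channel-interleaved in acquisition order. Acquisition geometry
#' and the intensity scale factor are written to a JSON sidecar
#' (`<path>.json`) because baseline TIFF tags cannot carry them portably.
#'
#' @param series An [image_series()].
#' @param path Output file path (`.tif`).
#' @return `path`, invisibly.
#' @seealso [read_image_series()]
#' @export
write_image_series <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  n_ch <- length(series$data)
  nf <- n_frames(series)
  mx <- max(vapply(series$data, max, 0), 1)
  scale <- 2^ceiling(log2(mx + 1))
  pages <- vector("list", nf * n_ch)
  for (f in seq_len(nf)) {
    for (c in seq_len(n_ch)) {
      pages[[(f - 1L) * n_ch + c]] <- series$data[[c]][f, , ] / scale
    }
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                            compression = "none", reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("could not write TIFF to '", path, "': ", attr(ok, "condition")$message)
  integer_counts <- all(vapply(series$data,
                               function(a) all(a == round(a)), TRUE))
  meta <- list(scale = scale, channels = series$channels,
               integer_counts = integer_counts,
               geometry = series$geometry[!vapply(series$geometry, is.null, TRUE)])
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image series from a multi-page TIFF
#'
#' Pages are de-interleaved across channels (page 1 is channel 1, frame 1).
#' When a sidecar JSON written by [write_image_series()] is present, its
#' intensity scale restores the original values; geometry conflicts between
#' the sidecar and the supplied `geometry` are reported, and `geometry` wins.
#'
#' @param path Path to a single- or multi-page TIFF.
#' @param geometry An [acquisition_geometry()]; its channel count determines
#'   the de-interleaving.
#' @return An [image_series()].
#' @export
read_image_series <- function(path, geometry) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  pages <- try(tiff::readTIFF(path, all = TRUE, as.is = TRUE), silent = TRUE)
  if (inherits(pages, "try-error"))
    stop("unreadable or truncated TIFF '", path, "'")
  n_ch <- geometry$channels
  if (length(pages) %% n_ch != 0L)
    stop(sprintf("page count (%d) not divisible by channel count (%d)",
                 length(pages), n_ch))
  shp <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), shp))
      stop(sprintf("format error: page %d shape differs from page 1", i))
  }
  scale <- 1
  integer_counts <- FALSE
  sp <- sidecar_path(path)
  if (file.exists(sp)) {
    meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
    scale <- meta$scale %||% 1
    integer_counts <- isTRUE(meta$integer_counts)
    for (fld in c("pixel_size", "pixel_dwell", "line_time", "frame_time",
                  "focal_waist")) {
      gv <- geometry[[fld]]
      mv <- meta$geometry[[fld]]
      if (!is.null(gv) && !is.null(mv) && !isTRUE(all.equal(gv, mv)))
        message(sprintf(
          "geometry conflict for '%s': file says %g, using supplied %g",
          fld, mv, gv))
    }
  }
  nf <- length(pages) %/% n_ch
  data <- vector("list", n_ch)
  for (c in seq_len(n_ch)) {
    a <- array(0, c(nf, shp[1], shp[2]))
    for (f in seq_len(nf)) {
      raw <- pages[[(f - 1L) * n_ch + c]]
      u <- ifelse(raw < 0, as.numeric(raw) + 2^32, as.numeric(raw))
      v <- u / (2^32 - 1) * scale
      if (integer_counts) v <- round(v)
      a[f, , ] <- v
    }
    # raw photon counts regain integer storage so write/read round-trips
    # are bit-exact
    if (integer_counts && max(a) < .Machine$integer.max)
      storage.mode(a) <- "integer"
    data[[c]] <- a
  }
  image_series(data, geometry)
}
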