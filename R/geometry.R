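#' Acquisition geometry of an imaging system
#'
#' Bundles the spatial and temporal sampling parameters that every
#' correlation model needs: the pixel size, the raster-scan pixel dwell and
#' line times (confocal) or the frame time (camera), and the lateral 1/e^2
#' radius of the effective Gaussian detection profile (focal waist).
#'
#' @param pixel_size Pixel size \eqn{\delta r} in micrometres per pixel.
#' @param focal_waist Lateral 1/e^2 radius \eqn{\omega_r} of the Gaussian
#'   focal spot, in micrometres.
#' @param modality `"raster"` for a scanned confocal beam, `"camera"` for a
#'   widefield/TIRF camera.
#' @param pixel_dwell Pixel dwell time \eqn{\tau_p} in seconds (raster only).
#' @param line_time Line repetition time \eqn{\tau_l} in seconds (raster
#'   only); must exceed `pixel_dwell`.
#' @param frame_time Frame repetition time in seconds (required for camera,
#'   optional for raster).
#' @param channels Number of detection channels (1 or 2).
#'
#' @return An object of class `acquisition_geometry`.
#' @examples
#' confocal_geometry()
#' camera_geometry()
#' @export
acquisition_geometry <- function(pixel_size, focal_waist,
                                 modality = c("raster", "camera"),
                                 pixel_dwell = NULL, line_time = NULL,
                                 frame_time = NULL, channels = 1L) {
  modality <- match.arg(modality)
  stopifnot(is.numeric(pixel_size), pixel_size > 0,
            is.numeric(focal_waist), focal_waist > 0,
            channels %in% c(1L, 2L))
  if (modality == "raster") {
    if (is.null(pixel_dwell) || is.null(line_time))
      stop("raster geometry requires 'pixel_dwell' and 'line_time'")
    stopifnot(pixel_dwell > 0, line_time > 0)
    if (pixel_dwell >= line_time)
      stop("'pixel_dwell' must be smaller than 'line_time'")
  } else {
    if (is.null(frame_time))
      stop("camera geometry requires 'frame_time'")
    stopifnot(frame_time > 0)
  }
  if (!is.null(frame_time)) stopifnot(frame_time > 0)
  structure(list(pixel_size = pixel_size, focal_waist = focal_waist,
                 modality = modality, pixel_dwell = pixel_dwell,
                 line_time = line_time, frame_time = frame_time,
                 channels = as.integer(channels)),
            class = "acquisition_geometry")
}

#' @describeIn acquisition_geometry Default confocal raster geometry:
#'   256 x 256 px at 50 nm/px, 8.19 us pixel dwell, 4.92 ms line time,
#'   1.26 s frame time.
#' @export
confocal_geometry <- function(pixel_size = 0.05, pixel_dwell = 8.19e-6,
                              line_time = 4.92e-3, frame_time = 1.26,
                              focal_waist = 0.2, channels = 1L) {
  acquisition_geometry(pixel_size, focal_waist, "raster",
                       pixel_dwell = pixel_dwell, line_time = line_time,
                       frame_time = frame_time, channels = channels)
}

#' @describeIn acquisition_geometry Default TIRF camera geometry:
#'   150 nm/px, 80 ms/frame.
#' @export
camera_geometry <- function(pixel_size = 0.15, frame_time = 0.08,
                            focal_waist = 0.3, channels = 1L) {
  acquisition_geometry(pixel_size, focal_waist, "camera",
                       frame_time = frame_time, channels = channels)
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat("<acquisition_geometry> ", x$modality,
      sprintf(", %d channel(s)\n", x$channels), sep = "")
  cat(sprintf("  pixel size : %g um, focal waist: %g um\n",
              x$pixel_size, x$focal_waist))
  if (x$modality == "raster")
    cat(sprintf("  pixel dwell: %g s, line time: %g s\n",
                x$pixel_dwell, x$line_time))
  if (!is.null(x$frame_time))
    cat(sprintf("  frame time : %g s\n", x$frame_time))
  invisible(x)
}
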