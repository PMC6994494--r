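#' Acquisition calibration for a confocal time series
#'
#' Bundles the physical calibration of a raster-scanned confocal acquisition:
#' number of frames, frame geometry, frame time and pixel size. Defaults
#' reproduce a rapid small-field acquisition used for fluctuation imaging of
#' nuclear bodies: 1000 frames of 64 x 64 pixels over a 13.5 um field
#' (pixel size 13.5/64 um) at 121 ms per frame.
#'
#' @param n_frames Number of frames (>= 1).
#' @param frame_shape Integer vector `c(rows, cols)`.
#' @param frame_time Seconds per frame (> 0).
#' @param pixel_size Pixel size in um/pixel (> 0).
#' @param field_of_view Optional field of view in um along the row axis;
#'   must equal `frame_shape[1] * pixel_size` to within 1e-9. Computed when
#'   omitted.
#' @return An object of class `nb_acquisition`.
#' @examples
#' acq <- acquisition_config()
#' acq$field_of_view  # 13.5 um
#' @export
acquisition_config <- function(n_frames = 1000L,
                               frame_shape = c(64L, 64L),
                               frame_time = 0.121,
                               pixel_size = 13.5 / 64,
                               field_of_view = NULL) {
  if (!is_count(n_frames) || n_frames < 1) {
    nb_stop("invalid_config", "n_frames must be a count >= 1")
  }
  if (length(frame_shape) != 2L || !all(vapply(frame_shape, is_count, TRUE)) ||
      any(frame_shape < 1)) {
    nb_stop("invalid_config", "frame_shape must be two positive integers")
  }
  if (!is_scalar_num(frame_time) || frame_time <= 0) {
    nb_stop("invalid_config", "frame_time must be > 0")
  }
  if (!is_scalar_num(pixel_size) || pixel_size <= 0) {
    nb_stop("invalid_config", "pixel_size must be > 0")
  }
  fov <- frame_shape[1] * pixel_size
  if (!is.null(field_of_view)) {
    if (abs(field_of_view - fov) > 1e-9) {
      nb_stop("invalid_config",
              sprintf("field_of_view %.9f inconsistent with rows * pixel_size = %.9f",
                      field_of_view, fov))
    }
    fov <- field_of_view
  }
  structure(
    list(n_frames = as.integer(n_frames),
         frame_shape = as.integer(frame_shape),
         frame_time = frame_time,
         pixel_size = pixel_size,
         field_of_view = fov),
    class = "nb_acquisition"
  )
}

#' Frame time implied by a line-scanned acquisition
#'
#' A raster-scanned confocal frame takes `n_lines * line_time` seconds; scan
#' software reports this rounded to the millisecond (e.g. 64 lines at
#' 1.89 ms/line gives 120.96 ms, reported as 121 ms).
#'
#' @param n_lines Number of scan lines per frame.
#' @param line_time Line time in seconds.
#' @param digits Rounding applied to the returned value, in decimal digits of
#'   seconds (default 3: millisecond precision, as acquisition software
#'   reports it). Use `NULL` for the exact product.
#' @return Frame time in seconds.
#' @examples
#' frame_time_from_lines(64, 0.00189)        # 0.121
#' frame_time_from_lines(64, 0.00189, NULL)  # 0.12096
#' @export
frame_time_from_lines <- function(n_lines, line_time, digits = 3) {
  if (!is_count(n_lines) || n_lines < 1) {
    nb_stop("invalid_config", "n_lines must be a count >= 1")
  }
  if (!is_scalar_num(line_time) || line_time <= 0) {
    nb_stop("invalid_config", "line_time must be > 0")
  }
  ft <- n_lines * line_time
  if (!is.null(digits)) ft <- round(ft, digits)
  ft
}

#' @export
print.nb_acquisition <- function(x, ...) {
  cat(sprintf("<nb_acquisition> %d frames, %dx%d px, %.4g s/frame, %.4g um/px (%.3g um field)\n",
              x$n_frames, x$frame_shape[1], x$frame_shape[2],
              x$frame_time, x$pixel_size, x$field_of_view))
  invisible(x)
}
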