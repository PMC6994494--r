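#' Construct a movie object
#'
#' A movie is an `H x W x T` array of non-negative intensity counts plus its
#' acquisition calibration and per-frame timestamps. With a Poisson detector
#' all values are integers. Timestamps default to a uniform grid at
#' `acquisition$frame_time` but may be non-uniform (e.g. a photobleaching
#' protocol with dense pre-bleach frames followed by sparse recovery frames).
#'
#' @param frames Numeric array `H x W x T`, all values >= 0.
#' @param acquisition An [acquisition_config()] with `n_frames == T`.
#' @param timestamps Optional numeric vector of length `T`, strictly
#'   increasing, in seconds.
#' @return An object of class `nb_movie`.
#' @export
nb_movie <- function(frames, acquisition, timestamps = NULL) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    nb_stop("invalid_config", "frames must be an H x W x T array")
  }
  if (any(frames < 0)) nb_stop("invalid_config", "frames must be non-negative")
  d <- dim(frames)
  if (!identical(d[1:2], as.integer(acquisition$frame_shape)) ||
      d[3] != acquisition$n_frames) {
    nb_stop("invalid_config", "frames dimensions disagree with acquisition")
  }
  if (is.null(timestamps)) {
    timestamps <- (seq_len(d[3]) - 1) * acquisition$frame_time
  }
  if (length(timestamps) != d[3] || any(diff(timestamps) <= 0)) {
    nb_stop("metadata_mismatch",
            "timestamps must be strictly increasing and one per frame")
  }
  structure(
    list(frames = frames, acquisition = acquisition, timestamps = timestamps),
    class = "nb_movie"
  )
}

#' @export
print.nb_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<nb_movie> %d frames of %dx%d px, t = [%.3g, %.3g] s, counts in [%g, %g]\n",
              d[3], d[1], d[2], min(x$timestamps), max(x$timestamps),
              min(x$frames), max(x$frames)))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie An `nb_movie`.
#' @return Integer frame count.
#' @export
n_frames <- function(movie) dim(movie$frames)[3]

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".yml")

#' Write a movie as multi-page TIFF plus sidecar metadata
#'
#' Frames are stored as 16-bit unsigned grayscale, one page per frame (counts
#' above 65535 are clipped with a warning). A sidecar YAML file next to the
#' TIFF records timestamps, calibration, the random seed and a full echo of
#' the generating configuration, so a written movie can be re-read (and a
#' simulation re-run) without loss.
#'
#' @param movie An [nb_movie()].
#' @param path Output TIFF path (`.tif`); the sidecar is written at the same
#'   path with extension `.yml`.
#' @param seed Optional seed to record.
#' @param config_echo Optional list echoed verbatim into the sidecar.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, seed = NULL, config_echo = NULL) {
  fr <- movie$frames
  if (any(fr > 65535)) {
    warning("counts above 65535 clipped for 16-bit storage")
    fr[fr > 65535] <- 65535
  }
  pages <- lapply(seq_len(dim(fr)[3]), function(t) round(fr[, , t]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    schema_version = 1L,
    n_frames = dim(fr)[3],
    frame_shape = as.integer(dim(fr)[1:2]),
    frame_time = movie$acquisition$frame_time,
    pixel_size = movie$acquisition$pixel_size,
    timestamps = as.numeric(movie$timestamps),
    seed = seed,
    config_echo = config_echo
  )
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a movie from multi-page TIFF (with optional sidecar)
#'
#' Inverse of [write_movie()]: the round trip reproduces counts bit-exactly.
#' Without a sidecar, a uniform default frame time is assumed with a warning.
#'
#' @param path TIFF path.
#' @param default_frame_time Frame time assumed when no sidecar is found.
#' @return An [nb_movie()]; any sidecar seed/config echo is attached as
#'   attribute `"sidecar"`.
#' @export
read_movie <- function(path, default_frame_time = 0.121) {
  if (!file.exists(path)) nb_stop("not_found", paste("no such file:", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, TRUE))) {
    nb_stop("unsupported_tiff", "only single-channel grayscale pages are supported")
  }
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    nb_stop("unsupported_tiff", "pages have irregular sizes")
  }
  frames <- array(0, c(dims[1, 1], dims[2, 1], length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- round(pages[[t]] * 65535)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- yaml::read_yaml(sc)
    if (length(meta$timestamps) != length(pages)) {
      nb_stop("metadata_mismatch",
              sprintf("sidecar has %d timestamps for %d pages",
                      length(meta$timestamps), length(pages)))
    }
    acq <- acquisition_config(length(pages), dim(frames)[1:2],
                              meta$frame_time, meta$pixel_size)
    mv <- nb_movie(frames, acq, as.numeric(meta$timestamps))
    attr(mv, "sidecar") <- meta[c("seed", "config_echo", "schema_version")]
  } else {
    warning("no sidecar metadata found; assuming uniform frame time ",
            default_frame_time, " s and pixel size 1 um")
    acq <- acquisition_config(length(pages), dim(frames)[1:2],
                              default_frame_time, 1)
    mv <- nb_movie(frames, acq)
  }
  mv
}
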