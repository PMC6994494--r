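#' Per-pixel moment (variance/mean) map of a frame segment
#'
#' Computes, for every pixel of a sub-stack, the temporal mean (first
#' moment), the population variance (second central moment, denominator N)
#' and their ratio, the per-pixel index of dispersion. For pure Poisson shot
#' noise the ratio is 1; coordinated movement of multiple fluorophores
#' through a pixel inflates it. Accumulation is single-pass and numerically
#' stable (Welford), vectorized over pixels. Pixels with mean at or below
#' `mean_floor` are marked invalid (their ratio is undefined noise).
#'
#' @param frames Numeric array `H x W x T` (`T >= 2`), or an [nb_movie()].
#' @param mean_floor Counts threshold below which a pixel is invalid
#'   (default 1).
#' @param pixel_size Optional pixel size in um carried into the map (taken
#'   from the movie when one is given).
#' @param segment_range Optional `c(first, last)` frame indices recorded in
#'   the map (bookkeeping only).
#' @return An object of class `nb_moment_map` with fields `mean_img`,
#'   `var_img`, `ratio_img` (NA where invalid), `valid_mask`,
#'   `segment_range`, `pixel_size`.
#' @examples
#' fr <- array(c(1, 3), c(1, 1, 2))
#' m <- moment_map(fr, mean_floor = 0)
#' m$ratio_img  # population variance 1 over mean 2 = 0.5
#' @export
moment_map <- function(frames, mean_floor = 1, pixel_size = NULL,
                       segment_range = NULL) {
  if (inherits(frames, "nb_movie")) {
    pixel_size <- pixel_size %||% frames$acquisition$pixel_size
    frames <- frames$frames
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    nb_stop("invalid_config", "frames must be an H x W x T array")
  }
  nt <- dim(frames)[3]
  if (nt < 2) nb_stop("insufficient_frames", "need at least 2 frames")
  h <- dim(frames)[1]; w <- dim(frames)[2]
  mean_img <- matrix(0, h, w)
  m2 <- matrix(0, h, w)
  for (t in seq_len(nt)) {          # Welford, one frame at a time
    x <- frames[, , t]
    delta <- x - mean_img
    mean_img <- mean_img + delta / t
    m2 <- m2 + delta * (x - mean_img)
  }
  var_img <- m2 / nt                # population variance (denominator N)
  valid <- mean_img > mean_floor
  ratio <- matrix(NA_real_, h, w)
  ratio[valid] <- var_img[valid] / mean_img[valid]
  structure(
    list(mean_img = mean_img, var_img = var_img, ratio_img = ratio,
         valid_mask = valid,
         segment_range = segment_range %||% c(1L, nt + 1L),
         pixel_size = pixel_size),
    class = "nb_moment_map"
  )
}

#' @export
print.nb_moment_map <- function(x, ...) {
  cat(sprintf("<nb_moment_map> %dx%d px, frames [%d, %d), %d valid px, ratio range [%.3g, %.3g]\n",
              nrow(x$mean_img), ncol(x$mean_img),
              x$segment_range[1], x$segment_range[2], sum(x$valid_mask),
              min(x$ratio_img, na.rm = TRUE), max(x$ratio_img, na.rm = TRUE)))
  invisible(x)
}

# Per-pixel boxcar detrend: subtract the centred running mean over `window`
# frames and add the pixel's global mean back, so slow drifts (pool
# depletion, slow exchange) are removed while fluctuations faster than the
# window survive.
detrend_frames <- function(frames, window) {
  d <- dim(frames)
  flat <- matrix(frames, d[1] * d[2], d[3])
  half <- floor(window / 2)
  cs <- cbind(0, t(apply(flat, 1, cumsum)))
  lo <- pmax(seq_len(d[3]) - half, 1L)
  hi <- pmin(seq_len(d[3]) + half, d[3])
  run <- (cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]) /
    rep(hi - lo + 1L, each = nrow(flat))
  out <- flat - run + rowMeans(flat)
  array(out, d)
}

#' Segmented moment analysis of a movie
#'
#' Tiles the acquisition into consecutive, non-overlapping segments of
#' `segment_len` frames (default 80 frames, about 10 s at 121 ms/frame) and
#' computes one moment map per segment; trailing remainder frames are
#' dropped. The segment series traces how coordinated-mobility maps evolve
#' during the acquisition (e.g. through a fusion event).
#'
#' @param movie An [nb_movie()] (or `H x W x T` array).
#' @param segment_len Frames per segment (>= 2, default 80).
#' @param mean_floor Passed to [moment_map()].
#' @param detrend Subtract a per-pixel boxcar running mean
#'   (`window = segment_len` frames) before computing moments, preserving
#'   each pixel's mean. Off by default (raw moments); useful when slow
#'   drifts (pool depletion, slow exchange) should not count as
#'   fluctuation, leaving only components faster than the segment.
#' @return An object of class `nb_moment_series`: list of maps plus
#'   `segment_len` and the acquisition.
#' @export
segmented_moments <- function(movie, segment_len = 80L, mean_floor = 1,
                              detrend = FALSE) {
  if (segment_len < 2) nb_stop("invalid_segment_len", "segment_len must be >= 2")
  acq <- NULL; ps <- NULL
  frames <- movie
  if (inherits(movie, "nb_movie")) {
    acq <- movie$acquisition
    ps <- acq$pixel_size
    frames <- movie$frames
  }
  nt <- dim(frames)[3]
  if (nt < segment_len) {
    nb_stop("invalid_segment_len", "movie shorter than one segment")
  }
  if (detrend) frames <- detrend_frames(frames, segment_len)
  n_seg <- nt %/% segment_len
  maps <- vector("list", n_seg)
  for (s in seq_len(n_seg)) {
    first <- (s - 1L) * segment_len + 1L
    maps[[s]] <- moment_map(frames[, , first:(first + segment_len - 1L),
                                   drop = FALSE],
                            mean_floor = mean_floor, pixel_size = ps,
                            segment_range = c(first, first + segment_len))
  }
  structure(list(maps = maps, segment_len = as.integer(segment_len),
                 acquisition = acq),
            class = "nb_moment_series")
}

#' @export
print.nb_moment_series <- function(x, ...) {
  cat(sprintf("<nb_moment_series> %d segments of %d frames\n",
              length(x$maps), x$segment_len))
  invisible(x)
}

ratio_values_in <- function(map, mask) {
  v <- map$ratio_img[mask & map$valid_mask]
  v[!is.na(v)]
}

#' Frequency of high variance/mean pixels in a region
#'
#' The fraction of valid pixels inside `analysis_mask` whose variance/mean
#' ratio exceeds a threshold. With `threshold = "auto"` the cutoff is the
#' 95th percentile of ratio values inside a disjoint `reference_mask`
#' (droplet interior or nucleoplasm), making "high" adaptive to brightness
#' while reproducible. For a segment series, the threshold is computed once
#' from the pooled reference values, each segment's fraction is reported,
#' and the overall fraction pools high and valid pixel counts across
#' segments.
#'
#' @param x An `nb_moment_map` or `nb_moment_series`.
#' @param analysis_mask ROI or logical mask selecting analysed pixels.
#' @param threshold Numeric cutoff, or `"auto"`.
#' @param reference_mask ROI/mask for the auto threshold (required then;
#'   must be disjoint from `analysis_mask`).
#' @param probs Reference percentile used by `"auto"` (default 0.95).
#' @return For a map: the fraction, with attributes `threshold`, `n_high`,
#'   `n_valid`. For a series: a list with `overall`, `per_segment`
#'   (data.frame `segment`, `fraction`, `n_high`, `n_valid`) and `threshold`.
#' @export
high_ratio_frequency <- function(x, analysis_mask, threshold = "auto",
                                 reference_mask = NULL, probs = 0.95) {
  maps <- if (inherits(x, "nb_moment_series")) x$maps else list(x)
  dimhw <- dim(maps[[1]]$mean_img)
  amask <- roi_pixels(analysis_mask, dimhw)
  rmask <- NULL
  if (identical(threshold, "auto")) {
    if (is.null(reference_mask)) {
      nb_stop("missing_reference", "auto threshold requires a reference_mask")
    }
    rmask <- roi_pixels(reference_mask, dimhw)
    if (any(rmask & amask)) {
      nb_stop("invalid_config", "reference_mask must be disjoint from analysis_mask")
    }
    ref_vals <- unlist(lapply(maps, ratio_values_in, rmask))
    if (!length(ref_vals)) nb_stop("empty_roi", "no valid reference pixels")
    threshold <- as.numeric(quantile(ref_vals, probs, names = FALSE))
  }
  per <- lapply(seq_along(maps), function(s) {
    v <- ratio_values_in(maps[[s]], amask)
    data.frame(segment = s, fraction = if (length(v)) mean(v > threshold) else NA,
               n_high = sum(v > threshold), n_valid = length(v))
  })
  per <- do.call(rbind, per)
  if (sum(per$n_valid) == 0) {
    nb_stop("empty_roi", "no valid pixels in the analysis mask")
  }
  if (inherits(x, "nb_moment_series")) {
    list(overall = sum(per$n_high) / sum(per$n_valid),
         per_segment = per, threshold = threshold)
  } else {
    structure(per$fraction[1], threshold = threshold,
              n_high = per$n_high[1], n_valid = per$n_valid[1])
  }
}

# NA-aware bilinear interpolation of a matrix at points (x, y) in pixel
# units (pixel centre of [i, j] at x = j - 0.5, y = i - 0.5). Weights of NA
# neighbours are renormalized away; all-NA neighbourhoods give NA.
bilinear_at <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  gx <- x - 0.5; gy <- y - 0.5          # 0-based continuous pixel index
  j0 <- floor(gx); i0 <- floor(gy)
  fx <- gx - j0; fy <- gy - i0
  out <- numeric(length(x))
  acc <- numeric(length(x))
  wsum <- numeric(length(x))
  for (k in 1:4) {
    di <- (k - 1) %/% 2; dj <- (k - 1) %% 2
    ii <- i0 + di + 1L; jj <- j0 + dj + 1L
    wgt <- (if (di == 0) 1 - fy else fy) * (if (dj == 0) 1 - fx else fx)
    ok <- ii >= 1L & ii <= h & jj >= 1L & jj <= w
    val <- rep(NA_real_, length(x))
    val[ok] <- img[cbind(ii[ok], jj[ok])]
    use <- ok & !is.na(val) & wgt > 0
    acc[use] <- acc[use] + wgt[use] * val[use]
    wsum[use] <- wsum[use] + wgt[use]
  }
  out <- ifelse(wsum > 0, acc / wsum, NA_real_)
  out
}

#' Profile of the moment ratio along an axis through a droplet
#'
#' Samples the variance/mean ratio at 1-pixel steps along a user-defined
#' axis, averaging over a perpendicular band of `+/- band_halfwidth` pixels
#' (bilinear interpolation, NA-aware). Plotting this profile across a
#' nuclear body makes the two boundary peaks of coordinated mobility
#' directly visible. Positions are reported in um from the first endpoint.
#'
#' @param map An `nb_moment_map`.
#' @param endpoints 2 x 2 matrix (rows = the two endpoints, columns x, y)
#'   in um.
#' @param band_halfwidth Half-width of the perpendicular averaging band in
#'   pixels (default 2).
#' @param statistic `"mean_ratio"` (band mean of the ratio) or
#'   `"high_ratio_frequency"` (band fraction above `threshold`).
#' @param threshold Cutoff, required for `"high_ratio_frequency"`.
#' @param pixel_size Pixel size in um; defaults to the size stored in the map.
#' @return An object of class `nb_boundary_profile`: data.frame-like list
#'   with `positions` (um) and `values`.
#' @export
boundary_axis_profile <- function(map, endpoints, band_halfwidth = 2,
                                  statistic = c("mean_ratio",
                                                "high_ratio_frequency"),
                                  threshold = NULL, pixel_size = NULL) {
  statistic <- match.arg(statistic)
  pixel_size <- pixel_size %||% map$pixel_size
  if (is.null(pixel_size)) nb_stop("invalid_config", "pixel_size unknown")
  if (statistic == "high_ratio_frequency" && is.null(threshold)) {
    nb_stop("invalid_config", "threshold required for high_ratio_frequency")
  }
  ep <- matrix(as.numeric(endpoints), 2, 2)
  p1 <- ep[1, ] / pixel_size; p2 <- ep[2, ] / pixel_size  # pixel units
  h <- nrow(map$ratio_img); w <- ncol(map$ratio_img)
  if (any(c(p1, p2) < 0) || p1[1] > w || p2[1] > w || p1[2] > h || p2[2] > h) {
    nb_stop("axis_out_of_bounds", "endpoints must lie inside the image")
  }
  len <- sqrt(sum((p2 - p1)^2))
  if (len < 1e-9) nb_stop("axis_out_of_bounds", "endpoints must be distinct")
  u <- (p2 - p1) / len
  v <- c(-u[2], u[1])
  s <- seq(0, len, by = 1)
  offs <- seq(-band_halfwidth, band_halfwidth, by = 1)
  vals <- vapply(s, function(si) {
    xs <- p1[1] + si * u[1] + offs * v[1]
    ys <- p1[2] + si * u[2] + offs * v[2]
    smp <- bilinear_at(map$ratio_img, xs, ys)
    smp <- smp[!is.na(smp)]
    if (!length(smp)) return(NA_real_)
    if (statistic == "mean_ratio") mean(smp) else mean(smp > threshold)
  }, 0)
  structure(list(positions = s * pixel_size, values = vals,
                 band_halfwidth = band_halfwidth, statistic = statistic),
            class = "nb_boundary_profile")
}

#' @export
print.nb_boundary_profile <- function(x, ...) {
  cat(sprintf("<nb_boundary_profile> %s over %d positions spanning %.3g um\n",
              x$statistic, length(x$positions), max(x$positions)))
  invisible(x)
}
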