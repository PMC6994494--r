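#' Extract a normalized FRAP recovery curve from a movie
#'
#' Measures the mean intensity of the bleached ROI in every frame,
#' subtracts the background ROI mean, optionally divides by a
#' background-subtracted reference ROI (double normalization, which removes
#' acquisition photobleaching and whole-pool depletion), and converts the
#' post-bleach frames to percentage recovery:
#' `R(t) = 100 * (F(t) - F_post) / (F_pre - F_post)` with `F_pre` the mean
#' of the pre-bleach frames and `F_post` the first post-bleach frame. Time
#' zero is the first post-bleach frame; the bleach frame itself is excluded.
#'
#' @param movie An [nb_movie()] with timestamps.
#' @param bleach_roi ROI of the bleached region.
#' @param bleach_frame 1-based index of the bleach frame (>= 2, with at
#'   least two frames after it).
#' @param background_roi Optional ROI measuring camera/electronic offset;
#'   must not overlap the bleach ROI. Zero background assumed when absent.
#' @param reference_roi Optional ROI of an unbleached region for double
#'   normalization; skipped with a warning when absent.
#' @return An object of class `nb_frap_curve`: `times` (s post-bleach),
#'   `recovery_pct`, plus the raw ROI traces and normalization levels.
#' @export
extract_recovery_curve <- function(movie, bleach_roi, bleach_frame,
                                   background_roi = NULL,
                                   reference_roi = NULL) {
  nt <- n_frames(movie)
  if (bleach_frame < 2 || bleach_frame > nt - 2) {
    nb_stop("invalid_bleach_frame",
            "need at least one pre-bleach and two post-bleach frames")
  }
  raw_roi <- roi_means(movie, bleach_roi)
  dimhw <- dim(movie$frames)[1:2]
  raw_bg <- rep(0, nt)
  if (!is.null(background_roi)) {
    if (any(roi_pixels(bleach_roi, dimhw) & roi_pixels(background_roi, dimhw))) {
      nb_stop("roi_overlap", "bleach and background ROIs overlap")
    }
    raw_bg <- roi_means(movie, background_roi)
  }
  f <- raw_roi - raw_bg
  raw_ref <- NULL
  if (!is.null(reference_roi)) {
    raw_ref <- roi_means(movie, reference_roi)
    f <- f / (raw_ref - raw_bg)
  } else {
    warning("no reference ROI: acquisition-bleaching correction skipped")
  }
  pre_idx <- seq_len(bleach_frame - 1L)
  post_idx <- (bleach_frame + 1L):nt
  f_pre <- mean(f[pre_idx])
  f_post <- f[post_idx[1]]
  if (f_pre <= f_post) {
    nb_stop("no_bleach_detected", "pre-bleach level does not exceed post-bleach")
  }
  times <- movie$timestamps[post_idx] - movie$timestamps[post_idx[1]]
  recovery <- 100 * (f[post_idx] - f_post) / (f_pre - f_post)
  structure(
    list(times = times, recovery_pct = recovery,
         raw_roi = raw_roi, raw_reference = raw_ref, raw_background = raw_bg,
         prebleach_level = f_pre, postbleach_level = f_post,
         bleach_frame = bleach_frame),
    class = "nb_frap_curve"
  )
}

#' @export
print.nb_frap_curve <- function(x, ...) {
  cat(sprintf("<nb_frap_curve> %d post-bleach points over %.3g s, last recovery %.1f%%\n",
              length(x$times), max(x$times),
              mean(tail(x$recovery_pct, 3))))
  invisible(x)
}

#' Fit an exponential recovery model to a FRAP curve
#'
#' Least-squares fit of the saturating single-exponential model
#' `R(t) = A * (1 - exp(-k * t))` (one effective exchange component); the
#' fitted plateau `A` is the maximum recovery percentage (100 = full
#' recovery). A two-component model (`"double_exp"`) is available for
#' curves with distinct fast and slow pools; its maximum recovery is the
#' sum of the two plateaus. When the optimizer fails, the fit falls back to
#' the mean of the last three observed points with `converged = FALSE`.
#'
#' @param curve An [extract_recovery_curve()] result (>= 4 post-bleach
#'   points).
#' @param model `"single_exp"` (default) or `"double_exp"`.
#' @return An object of class `nb_frap_fit`: `max_recovery_pct`, `rate_k`
#'   (1/s), `initial_rate` (%/s, from [initial_rate()]), `fit_rss`,
#'   `converged`, and `capped` (TRUE when the plateau exceeds the 110
#'   soft cap).
#' @examples
#' tt <- seq(5, 250, 5)
#' curve <- structure(list(times = tt, recovery_pct = 80 * (1 - exp(-0.1 * tt))),
#'                    class = "nb_frap_curve")
#' fit_recovery(curve)
#' @export
fit_recovery <- function(curve, model = c("single_exp", "double_exp")) {
  model <- match.arg(model)
  t <- curve$times; r <- curve$recovery_pct
  keep <- t > 0
  t <- t[keep]; r <- r[keep]
  if (length(t) < 4) nb_stop("insufficient_points", "need >= 4 post-bleach points")
  ir <- tryCatch(initial_rate(curve), error = function(e) NA_real_)
  mk_fit <- function(a, k, rss, conv) {
    structure(list(max_recovery_pct = a, rate_k = k, initial_rate = ir,
                   fit_rss = rss, converged = conv, capped = a > 110,
                   model = model),
              class = "nb_frap_fit")
  }
  if (all(abs(r) < 1e-8)) return(mk_fit(0, 0, 0, TRUE))
  a0 <- max(mean(tail(r, 3)), 1e-3)
  k0 <- {
    early <- r[t <= max(15, t[2])]
    slope <- max(early[length(early)] / max(t[t <= max(15, t[2])]), 1e-4)
    min(max(slope / a0, 1e-4), 2)
  }
  dat <- data.frame(t = t, r = r)
  fit <- tryCatch({
    if (model == "single_exp") {
      fm <- minpack.lm::nlsLM(r ~ A * (1 - exp(-k * t)), data = dat,
                              start = list(A = a0, k = k0),
                              lower = c(A = 0, k = 1e-6),
                              control = minpack.lm::nls.lm.control(maxiter = 200))
      cf <- coef(fm)
      mk_fit(unname(cf["A"]), unname(cf["k"]), sum(resid(fm)^2), TRUE)
    } else {
      fm <- minpack.lm::nlsLM(
        r ~ A1 * (1 - exp(-k1 * t)) + A2 * (1 - exp(-k2 * t)), data = dat,
        start = list(A1 = a0 / 2, k1 = min(k0 * 5, 2), A2 = a0 / 2, k2 = k0 / 5),
        lower = c(A1 = 0, k1 = 1e-6, A2 = 0, k2 = 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 400))
      cf <- coef(fm)
      mk_fit(unname(cf["A1"] + cf["A2"]),
             unname(max(cf["k1"], cf["k2"])), sum(resid(fm)^2), TRUE)
    }
  }, error = function(e) NULL)
  if (is.null(fit)) fit <- mk_fit(mean(tail(r, 3)), NA_real_, NA_real_, FALSE)
  fit
}

#' @export
print.nb_frap_fit <- function(x, ...) {
  cat(sprintf("<nb_frap_fit> max recovery %.1f%%, k = %.4g /s, initial rate %.3g %%/s%s%s\n",
              x$max_recovery_pct, x$rate_k, x$initial_rate,
              if (x$converged) "" else " (fallback, not converged)",
              if (isTRUE(x$capped)) " [plateau above 110 soft cap]" else ""))
  invisible(x)
}

#' Initial recovery rate over the first 15 s post-bleach
#'
#' The average percentage-recovery rate for the first 15 seconds after the
#' bleach, in %/s. The default is the slope of an origin-anchored
#' least-squares line through the recovery values at t = 5, 10 and 15 s
#' (`sum(t_i * R_i) / sum(t_i^2)`), which equals `R(15)/15` for linear data
#' and is more noise-robust; `method = "endpoint"` returns `R(15)/15`
#' directly. Curves sampled off the 5-s grid are linearly interpolated onto
#' it.
#'
#' @param curve An [extract_recovery_curve()] result whose times span 15 s.
#' @param method `"regression"` (default) or `"endpoint"`.
#' @return Initial rate in %/s.
#' @examples
#' curve <- structure(list(times = c(0, 5, 10, 15),
#'                         recovery_pct = c(0, 20, 40, 60)),
#'                    class = "nb_frap_curve")
#' initial_rate(curve)  # 4 %/s
#' @export
initial_rate <- function(curve, method = c("regression", "endpoint")) {
  method <- match.arg(method)
  t <- curve$times; r <- curve$recovery_pct
  grid <- c(5, 10, 15)
  if (max(t) < 15 || sum(t > 0 & t <= 15 + 1e-9) < 2) {
    nb_stop("insufficient_early_points",
            "curve must span t = 5, 10, 15 s post-bleach")
  }
  rg <- stats::approx(t, r, xout = grid)$y
  if (anyNA(rg)) {
    nb_stop("insufficient_early_points", "cannot interpolate to the 5 s grid")
  }
  if (method == "regression") sum(grid * rg) / sum(grid^2) else rg[3] / 15
}
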