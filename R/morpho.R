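# 8-connected component labeling (two-pass union-find). EBImage's bwlabel
# is 4-connected, which splits diagonally touching objects.
label_components8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nxt <- 0L
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      if (!mask[i, j]) next
      nb <- integer(0)
      if (i > 1 && lab[i - 1L, j]) nb <- c(nb, lab[i - 1L, j])
      if (j > 1) {
        if (lab[i, j - 1L]) nb <- c(nb, lab[i, j - 1L])
        if (i > 1 && lab[i - 1L, j - 1L]) nb <- c(nb, lab[i - 1L, j - 1L])
        if (i < h && lab[i + 1L, j - 1L]) nb <- c(nb, lab[i + 1L, j - 1L])
      }
      if (!length(nb)) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[i, j] <- nxt
      } else {
        roots <- vapply(unique(nb), find, 0L)
        r0 <- min(roots)
        lab[i, j] <- r0
        for (r in roots) parent[r] <- r0
      }
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, 0L)
  remap <- integer(nxt)
  remap[sort(unique(roots))] <- seq_along(unique(roots))
  pos <- which(lab > 0L)
  lab[pos] <- remap[roots[lab[pos]]]
  lab
}

#' Segment nuclear bodies in a protein channel
#'
#' Thresholds the protein channel inside the nucleus mask (Otsu's method on
#' the within-nucleus intensities by default, or a fixed value), fills
#' holes, labels 8-connected components, discards objects below `min_area`,
#' and measures each object: area (um^2), equivalent diameter
#' (`2 * sqrt(area / pi)`, um), size class and centroid. A featureless
#' (zero-contrast) image yields zero objects, not an error.
#'
#' @param protein_channel Numeric intensity matrix.
#' @param nucleus_mask Logical matrix (non-empty) restricting the search.
#' @param pixel_size Pixel size in um (> 0).
#' @param min_area Minimum object area in um^2 (default 0.05, about one
#'   pixel at 0.21 um pixels) to suppress noise specks.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param threshold Absolute intensity cutoff for `"fixed"`.
#' @return A list with `labels` (integer matrix) and `nbs` (data.frame:
#'   `label`, `area_um2`, `eq_diameter_um`, `size_class`, `centroid_x_um`,
#'   `centroid_y_um`).
#' @export
segment_nbs <- function(protein_channel, nucleus_mask, pixel_size,
                        min_area = 0.05,
                        threshold_method = c("otsu", "fixed"),
                        threshold = NULL) {
  threshold_method <- match.arg(threshold_method)
  if (!any(nucleus_mask)) nb_stop("empty_nucleus", "nucleus mask is empty")
  if (!is_scalar_num(pixel_size) || pixel_size <= 0) {
    nb_stop("invalid_config", "pixel_size must be > 0")
  }
  vals <- protein_channel[nucleus_mask]
  empty <- list(labels = matrix(0L, nrow(protein_channel), ncol(protein_channel)),
                nbs = data.frame(label = integer(0), area_um2 = numeric(0),
                                 eq_diameter_um = numeric(0),
                                 size_class = character(0),
                                 centroid_x_um = numeric(0),
                                 centroid_y_um = numeric(0)))
  if (threshold_method == "otsu") {
    rng <- range(vals)
    if (diff(rng) < 1e-12) return(empty)   # no contrast
    # Otsu on the within-nucleus histogram only: the image outside the
    # nucleus would otherwise drag the threshold
    th_scaled <- otsu_threshold((vals - rng[1]) / diff(rng))
    threshold <- rng[1] + th_scaled * diff(rng)
  } else if (is.null(threshold)) {
    nb_stop("invalid_config", "fixed threshold_method needs a threshold")
  }
  mask <- protein_channel > threshold & nucleus_mask
  if (!any(mask)) return(empty)
  mask <- fill_holes(mask)
  lab <- label_components8(mask)
  n_obj <- max(lab)
  px_area <- pixel_size^2
  rows <- lapply(seq_len(n_obj), function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    area <- nrow(idx) * px_area
    data.frame(label = l, area_um2 = area,
               eq_diameter_um = 2 * sqrt(area / pi),
               size_class = NA_character_,
               centroid_x_um = mean(idx[, 2] - 0.5) * pixel_size,
               centroid_y_um = mean(idx[, 1] - 0.5) * pixel_size)
  })
  nbs <- do.call(rbind, rows)
  nbs <- nbs[nbs$area_um2 >= min_area, , drop = FALSE]
  keep <- nbs$label
  lab[!(lab %in% keep)] <- 0L
  if (nrow(nbs)) {
    nbs$label <- seq_len(nrow(nbs))
    relab <- matrix(0L, nrow(lab), ncol(lab))
    for (i in seq_along(keep)) relab[lab == keep[i]] <- i
    lab <- relab
    nbs$size_class <- size_class(nbs$eq_diameter_um)
    rownames(nbs) <- NULL
  }
  list(labels = lab, nbs = nbs)
}

# Otsu threshold on a numeric vector scaled to [0, 1] (256-bin histogram).
otsu_threshold <- function(v, n_bins = 256L) {
  h <- tabulate(pmin(pmax(floor(v * n_bins) + 1L, 1L), n_bins), n_bins)
  p <- h / sum(h)
  mids <- (seq_len(n_bins) - 0.5) / n_bins
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

fill_holes <- function(mask) {
  img <- EBImage::fillHull(EBImage::Image(t(mask * 1)))
  t(EBImage::imageData(img)) > 0
}

#' Size class of a nuclear body from its equivalent diameter
#'
#' Class I: diameter <= 0.75 um; class II: 0.75 < diameter <= 2 um;
#' class III: diameter > 2 um. The printed class ranges share their
#' endpoints; closed upper bounds are the documented tie-break, so 0.75 is
#' class I and 2.0 is class II.
#'
#' @param eq_diameter Equivalent diameter(s) in um (> 0); vectorized.
#' @return Character vector of `"I"`, `"II"`, `"III"`.
#' @examples
#' size_class(c(0.5, 0.75, 1.2, 2, 3))
#' @export
size_class <- function(eq_diameter) {
  if (any(!is.finite(eq_diameter)) || any(eq_diameter <= 0)) {
    nb_stop("invalid_diameter", "diameters must be positive")
  }
  ifelse(eq_diameter <= 0.75, "I", ifelse(eq_diameter <= 2, "II", "III"))
}

#' Nucleus-to-cytoplasm fluorescence intensity ratio (Fn/c)
#'
#' `(mean_nucleus - background) / (mean_cytoplasm - background)`, with the
#' cytoplasm defined by subtracting the nucleus mask from the cell mask.
#'
#' @param image Intensity matrix.
#' @param nucleus_mask,cell_mask Logical matrices; the cell mask must
#'   strictly contain the nucleus mask.
#' @param background Scalar background counts (default 0).
#' @return Dimensionless ratio.
#' @examples
#' img <- matrix(10, 4, 4); img[2:3, 2:3] <- 20
#' nuc <- matrix(FALSE, 4, 4); nuc[2:3, 2:3] <- TRUE
#' fn_c_ratio(img, nuc, matrix(TRUE, 4, 4))  # 2
#' @export
fn_c_ratio <- function(image, nucleus_mask, cell_mask, background = 0) {
  cyto <- cell_mask & !nucleus_mask
  if (!any(nucleus_mask) || !any(cyto)) {
    nb_stop("empty_nucleus", "need non-empty nucleus and cytoplasm regions")
  }
  denom <- mean(image[cyto]) - background
  if (denom <= 0) nb_stop("degenerate_cytoplasm", "cytoplasm mean <= background")
  (mean(image[nucleus_mask]) - background) / denom
}

#' RNA intensity ratio between nuclear bodies and nucleoplasm
#'
#' `(F_NB - F_background) / (F_non-NB - F_background)` where each `F` is the
#' mean RNA-channel intensity over the respective region: the NB area, the
#' non-NB nucleoplasm (nucleus minus NBs) and a background region outside
#' the cell. Ratios below 1 indicate RNA depletion inside the bodies.
#'
#' @param rna_channel Intensity matrix.
#' @param nb_mask Logical NB mask, a subset of `nucleus_mask`.
#' @param nucleus_mask Logical nucleus mask.
#' @param background_region Logical mask outside the cell.
#' @return Dimensionless ratio.
#' @export
rna_ratio <- function(rna_channel, nb_mask, nucleus_mask, background_region) {
  non_nb <- nucleus_mask & !nb_mask
  if (!any(nb_mask) || !any(non_nb) || !any(background_region)) {
    nb_stop("empty_roi", "need non-empty NB, non-NB and background regions")
  }
  f_bg <- mean(rna_channel[background_region])
  denom <- mean(rna_channel[non_nb]) - f_bg
  if (denom <= 0) nb_stop("degenerate_nucleoplasm", "non-NB mean <= background")
  (mean(rna_channel[nb_mask]) - f_bg) / denom
}

#' Correct a slowly varying illumination field
#'
#' Divides the image by a heavily smoothed estimate of the illumination
#' field (Gaussian-weighted local-linear smoothing, sigma = `width / 8`
#' pixels, exact on linear shading including at the image edges) and
#' rescales so the global mean is preserved exactly. A flat image is
#' returned unchanged.
#'
#' @param image Intensity matrix.
#' @param sigma Smoothing sigma in pixels (default `ncol(image) / 8`).
#' @return Corrected matrix with the same global mean.
#' @export
illumination_correct <- function(image, sigma = ncol(image) / 8) {
  if (diff(range(image)) < 1e-12) return(image)
  field <- llin_smooth(llin_smooth(image, sigma), sigma, by_row = TRUE)
  field <- field / mean(field)
  field[field < 1e-6] <- 1e-6
  corrected <- image / field
  corrected * (mean(image) / mean(corrected))
}

# Gaussian-weighted local-linear smoothing along one dimension. Unlike a
# plain Gaussian blur it reproduces linear shading exactly at the image
# edges (the truncated window would otherwise bias a ramp), which is what
# an illumination-field estimator needs.
llin_smooth <- function(m, sigma, by_row = FALSE) {
  if (by_row) return(t(llin_smooth(t(m), sigma)))
  n <- nrow(m)
  k <- min(ceiling(3 * sigma), n - 1L)
  u_all <- -k:k
  w_all <- exp(-u_all^2 / (2 * sigma^2))
  out <- matrix(0, n, ncol(m))
  for (i in seq_len(n)) {
    ok <- i + u_all >= 1L & i + u_all <= n
    u <- u_all[ok]; w <- w_all[ok]
    s0 <- sum(w); s1 <- sum(w * u); s2 <- sum(w * u^2)
    cf <- w * (s2 - s1 * u) / (s0 * s2 - s1^2)
    out[i, ] <- cf %*% m[i + u, , drop = FALSE]
  }
  out
}

#' Per-nucleus morphometry summary
#'
#' Bundles NB segmentation with the per-nucleus summary statistics: total
#' NB area (sum over bodies), mean NB area, and optionally the Fn/c and RNA
#' ratios when the corresponding channels and masks are supplied.
#'
#' @param protein_channel Intensity matrix.
#' @param nucleus_mask Logical nucleus mask.
#' @param pixel_size Pixel size in um.
#' @param nucleus_id Identifier copied into the result.
#' @param cell_mask,fn_c_channel Optional inputs for [fn_c_ratio()]
#'   (defaults to the protein channel).
#' @param rna_channel,background_region Optional inputs for [rna_ratio()]
#'   (the NB mask is the segmentation result).
#' @param ... Passed to [segment_nbs()].
#' @return An object of class `nb_morpho_result`.
#' @export
quantify_nucleus <- function(protein_channel, nucleus_mask, pixel_size,
                             nucleus_id = 1L,
                             cell_mask = NULL, fn_c_channel = protein_channel,
                             rna_channel = NULL, background_region = NULL,
                             ...) {
  seg <- segment_nbs(protein_channel, nucleus_mask, pixel_size, ...)
  n_obj <- nrow(seg$nbs)
  fnc <- if (!is.null(cell_mask)) {
    fn_c_ratio(fn_c_channel, nucleus_mask, cell_mask)
  } else NA_real_
  rr <- if (!is.null(rna_channel) && !is.null(background_region) && n_obj > 0) {
    rna_ratio(rna_channel, seg$labels > 0, nucleus_mask, background_region)
  } else NA_real_
  structure(
    list(nucleus_id = nucleus_id, nbs = seg$nbs, labels = seg$labels,
         total_nb_area = sum(seg$nbs$area_um2),
         mean_nb_area = if (n_obj > 0) mean(seg$nbs$area_um2) else NA_real_,
         n_nbs = n_obj, fn_c = fnc, rna_ratio = rr),
    class = "nb_morpho_result"
  )
}

#' @export
print.nb_morpho_result <- function(x, ...) {
  cat(sprintf("<nb_morpho_result> nucleus %s: %d NBs, total area %.3g um^2%s\n",
              x$nucleus_id, x$n_nbs, x$total_nb_area,
              if (is.na(x$fn_c)) "" else sprintf(", Fn/c %.3g", x$fn_c)))
  invisible(x)
}
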