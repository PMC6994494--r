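#' Region-of-interest specifications
#'
#' ROIs are defined in pixel coordinates: the centre of the pixel in row `i`,
#' column `j` (1-based) sits at `x = j - 0.5`, `y = i - 0.5` pixel units, and
#' physical positions are pixel units times the pixel size. A pixel belongs
#' to a geometric ROI when its centre lies inside the shape.
#'
#' @param x,y Top-left corner of the rectangle (pixel units).
#' @param width,height Rectangle extent in pixels.
#' @param cx,cy Circle/annulus centre (pixel units).
#' @param r Circle radius (pixels).
#' @param r_inner,r_outer Annulus radii (pixels), `0 <= r_inner < r_outer`.
#' @param mask Logical (or 0/1) matrix; `TRUE` marks member pixels.
#' @return An object of class `nb_roi`.
#' @examples
#' roi <- roi_circle(32, 32, 5)
#' sum(roi_pixels(roi, c(64, 64)))
#' @name roi
NULL

new_roi <- function(shape, ...) {
  structure(c(list(shape = shape), list(...)), class = "nb_roi")
}

#' @rdname roi
#' @export
roi_rect <- function(x, y, width, height) {
  if (width <= 0 || height <= 0) nb_stop("empty_roi", "rectangle has no area")
  new_roi("rectangle", x = x, y = y, width = width, height = height)
}

#' @rdname roi
#' @export
roi_circle <- function(cx, cy, r) {
  if (r <= 0) nb_stop("empty_roi", "circle has no area")
  new_roi("circle", cx = cx, cy = cy, r = r)
}

#' @rdname roi
#' @export
roi_annulus <- function(cx, cy, r_inner, r_outer) {
  if (r_outer <= r_inner || r_inner < 0) {
    nb_stop("empty_roi", "need 0 <= r_inner < r_outer")
  }
  new_roi("annulus", cx = cx, cy = cy, r_inner = r_inner, r_outer = r_outer)
}

#' @rdname roi
#' @export
roi_mask <- function(mask) {
  m <- mask != 0
  if (!any(m)) nb_stop("empty_roi", "mask has no member pixels")
  new_roi("mask", mask = m)
}

#' Rasterize an ROI to a logical pixel mask
#'
#' @param roi An `nb_roi` (a logical matrix is accepted as-is).
#' @param dim Image dimensions `c(rows, cols)`.
#' @return Logical `rows x cols` matrix.
#' @export
roi_pixels <- function(roi, dim) {
  if (is.matrix(roi)) roi <- roi_mask(roi)
  if (!inherits(roi, "nb_roi")) nb_stop("invalid_config", "not an ROI")
  h <- dim[1]; w <- dim[2]
  cx_pix <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)   # x = col centre
  cy_pix <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)  # y = row centre
  m <- switch(roi$shape,
    rectangle = cx_pix >= roi$x & cx_pix < roi$x + roi$width &
                cy_pix >= roi$y & cy_pix < roi$y + roi$height,
    circle = (cx_pix - roi$cx)^2 + (cy_pix - roi$cy)^2 <= roi$r^2,
    annulus = {
      d2 <- (cx_pix - roi$cx)^2 + (cy_pix - roi$cy)^2
      d2 >= roi$r_inner^2 & d2 <= roi$r_outer^2
    },
    mask = {
      if (!identical(dim(roi$mask), as.integer(dim))) {
        nb_stop("invalid_config", "mask dimensions disagree with image")
      }
      roi$mask
    }
  )
  if (!any(m)) nb_stop("empty_roi", "ROI rasterizes to zero pixels")
  m
}

# Test whether points (x, y in pixel units) fall inside an ROI; used for
# particle-level operations such as photobleaching.
roi_contains <- function(roi, x, y, dim = NULL) {
  if (is.matrix(roi)) roi <- roi_mask(roi)
  switch(roi$shape,
    rectangle = x >= roi$x & x < roi$x + roi$width &
                y >= roi$y & y < roi$y + roi$height,
    circle = (x - roi$cx)^2 + (y - roi$cy)^2 <= roi$r^2,
    annulus = {
      d2 <- (x - roi$cx)^2 + (y - roi$cy)^2
      d2 >= roi$r_inner^2 & d2 <= roi$r_outer^2
    },
    mask = {
      i <- pmin(pmax(floor(y) + 1L, 1L), nrow(roi$mask))
      j <- pmin(pmax(floor(x) + 1L, 1L), ncol(roi$mask))
      roi$mask[cbind(i, j)]
    }
  )
}

# Mean intensity within an ROI for every frame of a movie.
roi_means <- function(movie, roi) {
  m <- roi_pixels(roi, dim(movie$frames)[1:2])
  idx <- which(m)
  hw <- prod(dim(movie$frames)[1:2])
  flat <- matrix(movie$frames, hw, dim(movie$frames)[3])
  colMeans(flat[idx, , drop = FALSE])
}
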