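test_that("moment map matches hand-computed moments", {
  # pixel trace {1, 3}: mean 2, population variance 1, ratio 0.5
  fr <- array(c(1, 3), c(1, 1, 2))
  m <- moment_map(fr, mean_floor = 0)
  expect_equal(m$mean_img[1, 1], 2)
  expect_equal(m$var_img[1, 1], 1)
  expect_equal(m$ratio_img[1, 1], 0.5)

  # constant trace: zero variance, zero ratio
  mc <- moment_map(array(7, c(2, 2, 10)), mean_floor = 1)
  expect_true(all(mc$var_img == 0))
  expect_true(all(mc$ratio_img == 0))

  # dark pixels are invalid
  md <- moment_map(array(0.5, c(2, 2, 5)), mean_floor = 1)
  expect_false(any(md$valid_mask))
  expect_true(all(is.na(md$ratio_img)))

  expect_error(moment_map(array(1, c(2, 2, 1))),
               class = "insufficient_frames")
})

test_that("streaming accumulation equals the two-pass oracle", {
  # independent two-pass oracle on random small stacks
  two_pass <- function(fr) {
    nt <- dim(fr)[3]
    mu <- apply(fr, c(1, 2), mean)
    v <- apply(fr, c(1, 2), function(x) sum((x - mean(x))^2)) / nt
    list(mean = mu, var = v)
  }
  set.seed(42)
  for (i in 1:100) {
    fr <- array(runif(8 * 8 * 50, 0, 1000), c(8, 8, 50))
    m <- moment_map(fr, mean_floor = 0)
    o <- two_pass(fr)
    expect_lt(max(abs(m$mean_img - o$mean) / o$mean), 1e-9)
    expect_lt(max(abs(m$var_img - o$var) / pmax(o$var, 1e-12)), 1e-9)
  }
})

test_that("the dispersion index of Poisson data sits at 1", {
  # asymptotic SE of the index of dispersion is sqrt(2/N)
  mv <- poisson_movie(rate = 10, n_frames = 1000, seed = 2)
  m <- moment_map(mv)
  se <- sqrt(2 / 1000)
  expect_true(all(abs(m$ratio_img - 1) < 6 * se))
  expect_lt(abs(mean(m$ratio_img) - 1), 3 * se / sqrt(16))
})

test_that("segmentation tiles the movie with floor semantics", {
  mv <- poisson_movie(rate = 10, n_frames = 170, shape = c(4L, 4L))
  s <- segmented_moments(mv, segment_len = 80)
  expect_length(s$maps, 2)
  expect_equal(s$maps[[1]]$segment_range, c(1L, 81L))
  expect_equal(s$maps[[2]]$segment_range, c(81L, 161L))
  # frames 161:170 dropped; each map equals moment_map on its segment
  direct <- moment_map(mv$frames[, , 81:160])
  expect_equal(s$maps[[2]]$ratio_img, direct$ratio_img)

  one <- segmented_moments(poisson_movie(n_frames = 80, shape = c(4L, 4L)),
                           segment_len = 80)
  expect_length(one$maps, 1)
  expect_error(segmented_moments(mv, segment_len = 1),
               class = "invalid_segment_len")
  expect_error(segmented_moments(poisson_movie(n_frames = 50,
                                               shape = c(4L, 4L)), 80),
               class = "invalid_segment_len")
})

test_that("high-ratio frequency counts valid pixels against the threshold", {
  ratio <- matrix(1, 10, 10)
  ratio[1:5, 1:5] <- 3            # 25 high pixels
  map <- manual_map(ratio)
  f <- high_ratio_frequency(map, roi_rect(0, 0, 10, 10), threshold = 2)
  expect_equal(as.numeric(f), 0.25)
  expect_equal(attr(f, "n_high"), 25)

  # auto threshold: 95th percentile of the reference region
  ratio2 <- matrix(seq(0, 1, length.out = 100), 10, 10)
  map2 <- manual_map(ratio2)
  fa <- high_ratio_frequency(map2, roi_rect(0, 0, 10, 5),
                             threshold = "auto",
                             reference_mask = roi_rect(0, 5, 10, 5))
  ref_vals <- ratio2[roi_pixels(roi_rect(0, 5, 10, 5), c(10, 10))]
  expect_equal(attr(fa, "threshold"),
               as.numeric(quantile(ref_vals, 0.95, names = FALSE)))

  expect_error(high_ratio_frequency(map, roi_rect(0, 0, 10, 10), "auto"),
               class = "missing_reference")
  expect_error(high_ratio_frequency(map, roi_rect(0, 0, 10, 10), "auto",
                                    reference_mask = roi_rect(0, 0, 5, 5)),
               class = "invalid_config")

  # all pixels invalid -> degenerate-case contract: empty_roi
  map_inv <- manual_map(matrix(NA_real_, 10, 10),
                        valid = matrix(FALSE, 10, 10))
  expect_error(high_ratio_frequency(map_inv, roi_rect(0, 0, 10, 10), 2),
               class = "empty_roi")
})

test_that("axis profiles sample the ratio image with band averaging", {
  # constant image: profile constant at that value for any axis
  map <- manual_map(matrix(2.5, 40, 40), pixel_size = 0.1)
  p <- boundary_axis_profile(map, rbind(c(0.3, 0.3), c(3.5, 3.2)),
                             band_halfwidth = 2)
  expect_true(all(abs(p$values - 2.5) < 1e-9))
  expect_equal(p$positions[1], 0)
  expect_true(all(diff(p$positions) > 0))

  # annulus of value 3 at radius 1.5 um on background 1, axis through the
  # centre: exactly two local maxima at the two rim crossings
  n <- 80; ps <- 0.1
  cx <- matrix(rep((1:n) - 0.5, each = n), n, n) * ps
  cy <- matrix(rep((1:n) - 0.5, times = n), n, n) * ps
  r <- sqrt((cx - 4)^2 + (cy - 4)^2)
  ratio <- ifelse(abs(r - 1.5) < 0.15, 3, 1)
  map2 <- manual_map(ratio, pixel_size = ps)
  p2 <- boundary_axis_profile(map2, rbind(c(1.0, 4), c(7.0, 4)),
                              band_halfwidth = 1)
  # two disjoint clusters of elevated values, centred on the rim crossings
  # (x = 2.5 and 5.5, i.e. 1.5 and 4.5 um along the axis)
  high <- p2$values > 2
  runs <- rle(high)
  expect_equal(sum(runs$values), 2)
  bounds <- cumsum(runs$lengths)
  starts <- c(1, head(bounds, -1) + 1)[runs$values]
  ends <- bounds[runs$values]
  centres <- p2$positions[floor((starts + ends) / 2)]
  expect_lt(abs(centres[1] - 1.5), 0.25)
  expect_lt(abs(centres[2] - 4.5), 0.25)

  expect_error(boundary_axis_profile(map, rbind(c(-5, 0), c(2, 2))),
               class = "axis_out_of_bounds")
  expect_error(boundary_axis_profile(map, rbind(c(1, 1), c(1, 1))),
               class = "axis_out_of_bounds")
})
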