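test_that("size classes partition every positive diameter", {
  expect_equal(size_class(0.5), "I")
  expect_equal(size_class(0.75), "I")    # closed upper bound
  expect_equal(size_class(0.7500001), "II")
  expect_equal(size_class(1.2), "II")
  expect_equal(size_class(2.0), "II")    # closed upper bound
  expect_equal(size_class(2.0000001), "III")
  expect_equal(size_class(3.0), "III")
  expect_equal(size_class(c(0.5, 1, 3)), c("I", "II", "III"))
  expect_error(size_class(0), class = "invalid_diameter")
  expect_error(size_class(-1), class = "invalid_diameter")
})

test_that("a rendered disc is recovered with its true diameter and class", {
  img <- render_static_nucleus(
    shape = c(120L, 120L), pixel_size = 0.1, nucleus_center = c(6, 6),
    nucleus_radius = 4, cell_radius = 5.5,
    nbs = data.frame(x = 6, y = 6, diameter = 2, intensity = 80))
  seg <- segment_nbs(img$channels$protein, img$masks$nucleus, 0.1)
  expect_equal(nrow(seg$nbs), 1)
  expect_lt(abs(seg$nbs$eq_diameter_um - 2), 0.1)
  # class is consistent with the measured diameter (rasterization can move
  # a diameter sitting exactly on the class boundary by under a pixel)
  expect_equal(seg$nbs$size_class, size_class(seg$nbs$eq_diameter_um))
  expect_lt(abs(seg$nbs$centroid_x_um - 6), 0.1)

  img2 <- render_static_nucleus(
    shape = c(120L, 120L), pixel_size = 0.1, nucleus_center = c(6, 6),
    nucleus_radius = 4, cell_radius = 5.5,
    nbs = data.frame(x = 6, y = 6, diameter = 1.4, intensity = 80))
  seg2 <- segment_nbs(img2$channels$protein, img2$masks$nucleus, 0.1)
  expect_equal(seg2$nbs$size_class, "II")
})

test_that("separated objects are counted and summed independently", {
  img <- render_static_nucleus(
    shape = c(120L, 120L), pixel_size = 0.1, nucleus_center = c(6, 6),
    nucleus_radius = 4.5, cell_radius = 5.8,
    nbs = data.frame(x = c(4.5, 8), y = c(6, 6), diameter = c(1, 1.6),
                     intensity = 80))
  res <- quantify_nucleus(img$channels$protein, img$masks$nucleus, 0.1)
  expect_equal(res$n_nbs, 2)
  expect_equal(res$total_nb_area, sum(res$nbs$area_um2))
  expect_equal(res$mean_nb_area, mean(res$nbs$area_um2))
})

test_that("featureless and degenerate inputs are handled", {
  flat <- matrix(10, 50, 50)
  nuc <- roi_pixels(roi_circle(25, 25, 20), c(50, 50))
  seg <- segment_nbs(flat, nuc, 0.1)
  expect_equal(nrow(seg$nbs), 0)
  expect_error(segment_nbs(flat, matrix(FALSE, 50, 50), 0.1),
               class = "empty_nucleus")
  expect_error(segment_nbs(flat, nuc, -1), class = "invalid_config")
  expect_error(segment_nbs(flat, nuc, 0.1, threshold_method = "fixed"),
               class = "invalid_config")
})

test_that("labeling is 8-connected and respects min_area", {
  img <- matrix(0, 20, 20)
  # two squares touching only diagonally: one object under 8-connectivity
  img[3:6, 3:6] <- 100
  img[7:10, 7:10] <- 100
  nuc <- matrix(TRUE, 20, 20)
  seg <- segment_nbs(img, nuc, pixel_size = 0.1, threshold_method = "fixed",
                     threshold = 50)
  expect_equal(nrow(seg$nbs), 1)
  # a single speck below min_area is suppressed
  img2 <- matrix(0, 20, 20)
  img2[5, 5] <- 100
  img2[12:15, 12:15] <- 100
  seg2 <- segment_nbs(img2, nuc, pixel_size = 0.1, min_area = 0.05,
                      threshold_method = "fixed", threshold = 50)
  expect_equal(nrow(seg2$nbs), 1)
  expect_equal(seg2$nbs$area_um2, 16 * 0.01)
})

test_that("holes are filled before measuring", {
  img <- matrix(0, 30, 30)
  img[10:20, 10:20] <- 100
  img[14:16, 14:16] <- 0           # interior hole
  seg <- segment_nbs(img, matrix(TRUE, 30, 30), pixel_size = 0.1,
                     threshold_method = "fixed", threshold = 50)
  expect_equal(nrow(seg$nbs), 1)
  expect_equal(seg$nbs$area_um2, 121 * 0.01)  # 11x11 incl. filled hole
})

test_that("intensity ratios follow their defining formulas", {
  img <- matrix(10, 20, 20)
  nuc <- matrix(FALSE, 20, 20); nuc[6:15, 6:15] <- TRUE
  img[nuc] <- 20
  expect_equal(fn_c_ratio(img, nuc, matrix(TRUE, 20, 20)), 2)
  img_eq <- matrix(7, 20, 20)
  expect_equal(fn_c_ratio(img_eq, nuc, matrix(TRUE, 20, 20)), 1)
  expect_error(fn_c_ratio(img, nuc, matrix(TRUE, 20, 20), background = 15),
               class = "degenerate_cytoplasm")
  expect_error(fn_c_ratio(img, matrix(TRUE, 20, 20), matrix(TRUE, 20, 20)),
               class = "empty_nucleus")

  # (F_NB - F_bg) / (F_nonNB - F_bg) = (50 - 10)/(110 - 10) = 0.4
  rna <- matrix(10, 20, 20)
  nb <- matrix(FALSE, 20, 20); nb[8:11, 8:11] <- TRUE
  rna[nuc] <- 110
  rna[nb] <- 50
  expect_equal(rna_ratio(rna, nb, nuc, !nuc & rna == 10), 0.4)
  rna[nb] <- 110
  expect_equal(rna_ratio(rna, nb, nuc, rna == 10), 1)
  rna[nuc] <- 5
  expect_error(rna_ratio(rna, nb, nuc, rna == 10),
               class = "degenerate_nucleoplasm")
})

test_that("illumination correction flattens gradients, preserving the mean", {
  flat <- matrix(50, 64, 64)
  expect_lt(max(abs(illumination_correct(flat) - flat)), 1e-6)

  grad <- matrix(rep(seq(0.5, 1.5, length.out = 64), each = 64), 64, 64)
  img <- 100 * grad
  corr <- illumination_correct(img)
  cv <- function(x) sd(x) / mean(x)
  expect_gt(cv(img) / cv(corr), 5)
  expect_lt(abs(mean(corr) - mean(img)) / mean(img), 0.001)
})

test_that("fixture render rejects out-of-bounds bodies", {
  expect_error(render_static_nucleus(
    nucleus_radius = 3, cell_radius = 5,
    nbs = data.frame(x = 12, y = 12, diameter = 8, intensity = 80)),
    class = "nb_out_of_bounds")
  empty <- render_static_nucleus()
  expect_equal(nrow(empty$ground_truth), 0)
  seg <- segment_nbs(empty$channels$protein, empty$masks$nucleus, 0.1)
  expect_equal(nrow(seg$nbs), 0)
})
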