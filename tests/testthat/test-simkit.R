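test_that("identical configuration and seed give a bit-identical movie", {
  args <- list(acq = quick_acq(30), n_particles = 300, seed = 17,
               burn_in = 20)
  a <- do.call(simulate_droplet_movie, args)
  b <- do.call(simulate_droplet_movie, args)
  expect_identical(a$movie$frames, b$movie$frames)
  expect_identical(a$ground_truth$trajectories, b$ground_truth$trajectories)
  d <- simulate_droplet_movie(acq = quick_acq(30), n_particles = 300,
                              seed = 18, burn_in = 20)
  expect_false(identical(a$movie$frames, d$movie$frames))
})

test_that("particle count is conserved and flags account for bleaching", {
  sim <- simulate_frap_movie(seed = 2, n_particles = 1500,
                             frame_shape = c(64L, 64L), pixel_size = 0.21,
                             nucleus_radius = 6,
                             droplets = list(droplet_spec(c(6.72, 6.72), 1,
                                                          p_exit = 0.04,
                                                          p_enter = 0.8)),
                             total_postbleach = 50)
  gt <- sim$ground_truth
  # every particle is tracked in every frame: fluorescent + bleached = n
  expect_true(all(colSums(gt$fluorescent) +
                    colSums(!gt$fluorescent) == gt$n_particles))
  expect_true(all(is.finite(gt$trajectories$x)))
  # the bleach drops the fluorescent count at the bleach frame
  expect_lt(sum(gt$fluorescent[, gt$bleach_frame + 1]),
            sum(gt$fluorescent[, gt$bleach_frame]))
  expect_equal(nrow(gt$bleach_events), 1)
})

test_that("zero-particle Poisson movies are pure shot noise", {
  sim <- simulate_droplet_movie(acq = quick_acq(400),
                                detector = detector_model(background = 5),
                                n_particles = 0, seed = 4, burn_in = 0)
  expect_true(all(sim$movie$frames == floor(sim$movie$frames)))
  m <- moment_map(sim$movie)
  expect_lt(abs(mean(m$ratio_img, na.rm = TRUE) - 1), 0.05)
})

test_that("a kinetically transparent droplet leaves no trace", {
  # D_in = D_out, p_exit = p_enter = 1: the boundary is a no-op
  acq <- quick_acq(200, c(48L, 48L))
  d <- droplet_spec(center = c(5, 5), radius = 1.5, D_in = 0.5, D_out = 0.5,
                    p_exit = 1, p_enter = 1)
  sim <- simulate_droplet_movie(acq, droplets = list(d),
                                n_particles = 1500, seed = 5, burn_in = 50)
  tr <- sim$ground_truth$trajectories
  r2 <- (tr$x - 5)^2 + (tr$y - 5)^2
  in_frac <- mean(r2 < 1.5^2)
  area_frac <- pi * 1.5^2 / (acq$field_of_view^2)
  expect_lt(abs(in_frac - area_frac) / area_frac, 0.15)
  # mean intensity inside vs outside indistinguishable (few percent)
  mimg <- moment_map(sim$movie)$mean_img
  inside <- roi_pixels(roi_circle(5 / acq$pixel_size, 5 / acq$pixel_size,
                                  1 / acq$pixel_size), c(48, 48))
  expect_lt(abs(mean(mimg[inside]) - mean(mimg[!inside])) /
              mean(mimg[!inside]), 0.1)
})

test_that("partitioning is stationary after burn-in", {
  sim <- simulate_droplet_movie(acq = quick_acq(500, c(64L, 64L)),
                                n_particles = 1500, seed = 6, burn_in = 200)
  tr <- sim$ground_truth$trajectories
  fov <- 13.5
  r2 <- (tr$x - fov / 2)^2 + (tr$y - fov / 2)^2
  inside <- r2 < 1.5^2
  dens_ratio <- function(cols) {
    fin <- mean(inside[, cols]); a_in <- pi * 1.5^2 / fov^2
    (fin / a_in) / ((1 - fin) / (1 - a_in))
  }
  first <- dens_ratio(1:250)
  second <- dens_ratio(251:500)
  # with p_enter > p_exit the droplet is denser than the nucleoplasm,
  # and the ratio is stable between the two halves
  expect_gt(first, 5)
  expect_lt(abs(first - second) / first, 0.1)
})

test_that("simulation inputs are validated", {
  expect_error(simulate_droplet_movie(
    acq = quick_acq(5),
    droplets = list(droplet_spec(center = c(0.5, 0.5), radius = 1.5)),
    seed = 1), class = "droplet_out_of_bounds")
  expect_error(simulate_droplet_movie(acq = quick_acq(5),
                                      n_particles = -5, seed = 1),
               class = "invalid_config")
  expect_error(simulate_droplet_movie(acq = quick_acq(5),
                                      n_particles = 10,
                                      immobile_fraction = 1.5, seed = 1),
               class = "invalid_config")
  expect_error(droplet_spec(c(1, 1), radius = -2), class = "invalid_config")
  expect_error(droplet_spec(c(1, 1), 1, p_exit = 2), class = "invalid_config")
  expect_error(detector_model(psf_sigma = 0), class = "invalid_config")
})

test_that("fusion conserves area and particles and records contact", {
  acq <- quick_acq(120, c(64L, 64L))
  da <- droplet_spec(c(4.75, 6.75), 1)
  db <- droplet_spec(c(8.75, 6.75), 1)
  sim <- simulate_fusion_movie(acq, da, db, approach_speed = 0.1,
                               n_particles = 400, seed = 8, burn_in = 10)
  gt <- sim$ground_truth
  expect_equal(gt$merged_radius, sqrt(2))
  # contact when the 2 um gap closes at 0.1 um/s -> t = 20 s, frame ~166
  expect_equal(gt$contact_time, 20)
  drops_last <- gt$droplets[gt$droplets$frame == 120, ]
  expect_equal(nrow(drops_last), 2)  # contact after this short clip

  sim2 <- simulate_fusion_movie(quick_acq(60, c(64L, 64L)), da, db, approach_speed = 0.5,
                                n_particles = 400, seed = 8, burn_in = 10)
  gt2 <- sim2$ground_truth
  expect_equal(gt2$contact_time, 4)
  expect_equal(gt2$contact_frame, 35L)  # first frame at t >= 4 s
  last <- gt2$droplets[gt2$droplets$frame == 60, ]
  expect_equal(nrow(last), 1)
  expect_equal(last$radius, sqrt(2))

  # no approach: geometry identical in first and last frame
  sim0 <- simulate_fusion_movie(quick_acq(20, c(64L, 64L)), da, db, approach_speed = 0,
                                n_particles = 100, seed = 9, burn_in = 5)
  g0 <- sim0$ground_truth$droplets
  expect_equal(g0[g0$frame == 1, -1], g0[g0$frame == 20, -1],
               ignore_attr = TRUE)

  expect_error(simulate_fusion_movie(
    quick_acq(10, c(64L, 64L)), droplet_spec(c(6, 6.75), 1.2),
    droplet_spec(c(7.5, 6.75), 1.2), seed = 1),
    class = "droplets_overlap")
})

test_that("the FRAP protocol produces the documented timeline", {
  sim <- simulate_frap_movie(seed = 3, n_particles = 800,
                             frame_shape = c(64L, 64L), pixel_size = 0.21,
                             nucleus_radius = 6,
                             droplets = list(droplet_spec(c(6.72, 6.72), 1)),
                             total_postbleach = 60)
  ts <- sim$movie$timestamps
  # 3 pre-bleach frames 1.3 s apart, one bleach frame, then 5 s spacing
  expect_equal(ts[1:4], c(0, 1.3, 2.6, 3.9))
  expect_equal(diff(ts[5:length(ts)]), rep(5, length(ts) - 5))
  expect_equal(length(ts), 3 + 1 + 13)
  expect_equal(sim$ground_truth$bleach_frame, 4L)

  # nothing bleached when the probability is zero
  sim0 <- simulate_frap_movie(seed = 3, n_particles = 800,
                              frame_shape = c(64L, 64L), pixel_size = 0.21,
                              nucleus_radius = 6,
                              detector = detector_model(),
                              droplets = list(droplet_spec(c(6.72, 6.72), 1)),
                              bleach_probability = 0, total_postbleach = 30)
  expect_true(all(sim0$ground_truth$fluorescent))
})

test_that("an immobile fully bleached body never recovers", {
  sim <- simulate_frap_movie(seed = 11, n_particles = 4000,
                             immobile_fraction = 1, total_postbleach = 100)
  a <- analyse_frap_sim(sim, reference = TRUE)
  expect_lt(mean(tail(a$curve$recovery_pct, 5)), 5)
})

test_that("static nucleus renders carry exact ground truth", {
  img <- render_static_nucleus(
    nbs = data.frame(x = c(10, 14), y = c(12, 12), diameter = c(1, 2.4),
                     intensity = 80),
    nucleus_center = c(12, 12))
  expect_equal(img$ground_truth$size_class, c("II", "III"))
  expect_equal(img$ground_truth$area, pi * c(0.5, 1.2)^2)
  # channel means over the true masks equal the configured levels
  expect_equal(mean(img$channels$rna[img$masks$nb]), 50)
  expect_equal(mean(img$channels$rna[img$masks$nucleus & !img$masks$nb]), 110)
  expect_equal(mean(img$channels$rna[!img$masks$cell]), 10)
  expect_equal(rna_ratio(img$channels$rna, img$masks$nb, img$masks$nucleus,
                         !img$masks$cell), 0.4)
  # noise requires a seed and is reproducible
  expect_error(render_static_nucleus(noise_sd = 3), class = "invalid_config")
  n1 <- render_static_nucleus(noise_sd = 3, seed = 2)
  n2 <- render_static_nucleus(noise_sd = 3, seed = 2)
  expect_identical(n1$channels$protein, n2$channels$protein)
})

test_that("coordinated mobility concentrates at the droplet rim", {
  sim <- simulate_droplet_movie(acq = quick_acq(400, c(64L, 64L)),
                                seed = 13, record_trajectories = FALSE)
  acq <- sim$movie$acquisition
  ps <- acq$pixel_size
  series <- segmented_moments(sim$movie, 80)
  masks <- nbdyn:::boundary_masks(
    droplet_spec(c(6.75, 6.75), 1.5), sim$detector, acq)
  ann <- roi_pixels(masks$annulus, c(64, 64))
  skirt <- roi_pixels(masks$outer_skirt, c(64, 64))
  band <- ann | skirt
  interior <- roi_pixels(masks$interior, c(64, 64))
  th <- quantile(unlist(lapply(series$maps, function(m)
    m$ratio_img[interior & m$valid_mask])), 0.95, na.rm = TRUE)
  # localization is judged in the body's vicinity (within two radii):
  # farther out, sparse single-pixel estimator noise over the large dim
  # field is not a statement about the boundary
  cxm <- matrix(rep((1:64) - 0.5, each = 64), 64, 64) * ps
  cym <- matrix(rep((1:64) - 0.5, times = 64), 64, 64) * ps
  vicinity <- sqrt((cxm - 6.75)^2 + (cym - 6.75)^2) < 3
  n_band <- 0; n_elsewhere <- 0
  for (m in series$maps) {
    high <- !is.na(m$ratio_img) & m$ratio_img > th
    high_out <- high & !interior & vicinity  # interior defines the threshold
    n_band <- n_band + sum(high_out & band)
    n_elsewhere <- n_elsewhere + sum(high_out & !band)
  }
  expect_gt(n_band / (n_band + n_elsewhere), 0.6)

  # radial argmax of the mean-ratio profile sits at the true rim radius
  mfull <- moment_map(sim$movie$frames[, , 1:400])
  cx <- matrix(rep((1:64) - 0.5, each = 64), 64, 64) * ps
  cy <- matrix(rep((1:64) - 0.5, times = 64), 64, 64) * ps
  r <- sqrt((cx - 6.75)^2 + (cy - 6.75)^2)
  bins <- cut(r, seq(0, 5, 0.25))
  prof <- tapply(as.vector(mfull$ratio_img), bins, mean, na.rm = TRUE)
  peak_r <- seq(0.125, 4.875, 0.25)[which.max(prof)]
  expect_lt(abs(peak_r - 1.5), 0.5)
})

test_that("mean ratio grows with molecular brightness", {
  # uniform freely-diffusing field: dispersion excess scales with the
  # counts contributed per fluorophore
  ratios <- vapply(c(1, 5, 10), function(br) {
    sim <- simulate_droplet_movie(
      acq = quick_acq(160, c(32L, 32L)),
      droplets = list(droplet_spec(c(3.375, 3.375), 1, D_in = 0.5,
                                   D_out = 0.5, p_exit = 1, p_enter = 1)),
      detector = detector_model(brightness = br),
      n_particles = 800, seed = 21, burn_in = 20)
    mean(moment_map(sim$movie)$ratio_img, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(ratios) > 0))
})

test_that("reducing boundary mobility never raises the rim frequency", {
  # stress events are a thinned subset of the seed-matched control events
  f1 <- boundary_frequency(simulate_droplet_movie(
    acq = quick_acq(400, c(64L, 64L)), seed = 31,
    record_trajectories = FALSE))
  f0 <- boundary_frequency(simulate_droplet_movie(
    acq = quick_acq(400, c(64L, 64L)), seed = 31,
    preset = sim_preset("stress"), record_trajectories = FALSE))
  expect_lte(f0$overall, f1$overall)
})
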