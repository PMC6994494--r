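#' End-to-end analysis scenarios on synthetic ground truth
#'
#' Each scenario generates its synthetic inputs, runs the relevant analysis
#' modules, and returns a machine-readable summary (optionally writing CSV
#' tables and a JSON summary to `out_dir`). Given the same `(name, seed)`
#' the summary is identical across runs.
#'
#' \describe{
#'   \item{`fig2_boundary`}{Seed-matched control vs stress droplet movies
#'     (five replicate seed pairs), detrended segmented moment analysis,
#'     and the fold-change of the rim-skirt high-ratio pixel frequency. The
#'     stress preset's five-fold boundary-mobility reduction should be
#'     recovered as a fold-change of about 5.}
#'   \item{`fig2_fusion`}{Two droplets drifting together and fusing; the
#'     high-ratio frequency in a disc at the contact zone is compared
#'     between pre- and post-contact segments (coordinated mobility is lost
#'     where the shared boundary dissolves).}
#'   \item{`fig4_stress_frap`}{Seed-matched FRAP simulations under control
#'     and stress presets; whole-body bleach, recovery extraction, and the
#'     fitted maximum recovery and initial rate for each condition.}
#'   \item{`fig1_sizes`}{A noiseless fixed-cell render with nuclear bodies
#'     of known diameters in every size class; segmentation must recover
#'     the per-class counts exactly, plus the RNA and Fn/c ratio fixtures.}
#' }
#'
#' @param name Scenario name.
#' @param seed Integer seed; replicate seeds are derived from it.
#' @param out_dir Optional output directory for CSV/JSON reports.
#' @return A named list of summary quantities, invisibly when `out_dir` is
#'   given.
#' @export
run_scenario <- function(name = c("fig2_boundary", "fig2_fusion",
                                  "fig4_stress_frap", "fig1_sizes"),
                         seed = 1, out_dir = NULL) {
  name <- tryCatch(match.arg(name),
                   error = function(e) nb_stop("unknown_scenario",
                                               paste("unknown scenario:", name)))
  summary <- switch(name,
    fig2_boundary = scenario_boundary(seed, out_dir),
    fig2_fusion = scenario_fusion(seed, out_dir),
    fig4_stress_frap = scenario_stress_frap(seed, out_dir),
    fig1_sizes = scenario_sizes(seed, out_dir)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(summary)
  } else {
    summary
  }
}

# Masks around a droplet rim, in pixel units: the full boundary annulus
# (true radius +/- 2 psf sigma, used for localization checks), the outer
# rim skirt [R + sigma/2, R + 3 sigma] (used for the frequency fold
# measurement: the dim outer skirt has the tightest dispersion-estimator
# noise floor, while the bright inner skirt inherits the interior's
# estimator spread), and a disjoint interior reference disc for the auto
# threshold.
boundary_masks <- function(droplet, detector, acq) {
  ps <- acq$pixel_size
  cx <- droplet$center[1] / ps; cy <- droplet$center[2] / ps
  half <- 2 * detector$psf_sigma / ps
  r_px <- droplet$radius / ps
  list(
    annulus = roi_annulus(cx, cy, max(r_px - half, 0.5), r_px + half),
    outer_skirt = roi_annulus(cx, cy, r_px + half / 4, r_px + 1.5 * half),
    interior = roi_circle(cx, cy, max(r_px - half - 1, 1))
  )
}

#' Boundary high-ratio frequency of one droplet movie
#'
#' Convenience wrapper used by the boundary scenario: simulates (or takes)
#' a droplet movie, runs segmented moments, and measures the high-ratio
#' frequency in the boundary annulus with the auto threshold taken from the
#' droplet interior.
#'
#' @param sim Result of [simulate_droplet_movie()].
#' @param segment_len Frames per segment.
#' @param detrend Remove slow per-pixel drifts before the moments (on by
#'   default here: the boundary statistic targets fast coordinated
#'   fluctuations, and slow pool/exchange drift otherwise adds
#'   dispersion-estimator noise to both the band and the reference).
#' @return The [high_ratio_frequency()] series result.
#' @export
boundary_frequency <- function(sim, segment_len = 80L, detrend = TRUE) {
  acq <- sim$movie$acquisition
  drop1 <- sim$ground_truth$droplets[1, ]
  dd <- droplet_spec(center = c(drop1$x, drop1$y), radius = drop1$radius)
  masks <- boundary_masks(dd, sim$detector, acq)
  series <- segmented_moments(sim$movie, segment_len = segment_len,
                              detrend = detrend)
  high_ratio_frequency(series, masks$outer_skirt, threshold = "auto",
                       reference_mask = masks$interior)
}

scenario_boundary <- function(seed, out_dir = NULL, n_replicates = 5) {
  seeds <- seed + seq_len(n_replicates) - 1
  rows <- lapply(seeds, function(s) {
    res <- lapply(c("control", "stress"), function(p) {
      sim <- simulate_droplet_movie(seed = s, preset = sim_preset(p),
                                    record_trajectories = FALSE)
      boundary_frequency(sim)
    })
    data.frame(seed = s,
               freq_control = res[[1]]$overall,
               freq_stress = res[[2]]$overall,
               fold = res[[1]]$overall / res[[2]]$overall)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(out_dir, "boundary_frequency.csv"),
              row.names = FALSE)
  }
  list(scenario = "fig2_boundary",
       per_seed = tab,
       freq_control = mean(tab$freq_control),
       freq_stress = mean(tab$freq_stress),
       fold_change = mean(tab$freq_control) / mean(tab$freq_stress))
}

scenario_fusion <- function(seed, out_dir = NULL) {
  acq <- acquisition_config()
  fov <- acq$field_of_view
  da <- droplet_spec(center = c(fov / 2 - 2, fov / 2), radius = 1.0)
  db <- droplet_spec(center = c(fov / 2 + 2, fov / 2), radius = 1.0)
  sim <- simulate_fusion_movie(acq, da, db, approach_speed = 0.04,
                               seed = seed, record_trajectories = FALSE)
  gt <- sim$ground_truth
  series <- segmented_moments(sim$movie, segment_len = 80L)
  ps <- acq$pixel_size
  # contact point: where the two rims meet (symmetric pair -> field centre)
  contact_xy <- c(fov / 2, fov / 2) / ps
  contact_disc <- roi_circle(contact_xy[1], contact_xy[2], 0.6 / ps)
  # the interior reference tracks droplet a's ground-truth centre segment
  # by segment (post-merge it tracks the merged droplet), so its pixels are
  # interior throughout; the 95th percentile of the pooled values is then
  # applied as an absolute threshold
  seg_of_frame <- function(f) ceiling(f / 80)
  interior_at <- function(s) {
    mid <- (s - 1) * 80 + 40
    d1 <- gt$droplets[gt$droplets$frame == mid & gt$droplets$id == 1, ]
    roi_circle(d1$x / ps, d1$y / ps, 0.5 / ps)
  }
  ref_vals <- unlist(lapply(seq_along(series$maps), function(s) {
    m <- series$maps[[s]]
    msk <- roi_pixels(interior_at(s), dim(m$ratio_img))
    m$ratio_img[msk & m$valid_mask]
  }))
  th <- as.numeric(quantile(ref_vals, 0.95, na.rm = TRUE, names = FALSE))
  freq <- high_ratio_frequency(series, contact_disc, threshold = th)
  contact_seg <- seg_of_frame(gt$contact_frame)
  per <- freq$per_segment
  # the approach window: the segment spanning contact and the one before
  # it are when the rims traverse the contact zone; afterwards the zone is
  # merged-droplet interior
  pre <- per$fraction[per$segment %in% c(contact_seg - 1, contact_seg)]
  post <- per$fraction[per$segment > contact_seg]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(per, file.path(out_dir, "contact_zone_frequency.csv"),
              row.names = FALSE)
  }
  list(scenario = "fig2_fusion",
       contact_frame = gt$contact_frame,
       contact_segment = contact_seg,
       merged_radius = gt$merged_radius,
       measured_final_radius = gt$droplets$radius[nrow(gt$droplets)],
       freq_pre_contact = mean(pre, na.rm = TRUE),
       freq_post_contact = mean(post, na.rm = TRUE))
}

scenario_stress_frap <- function(seed, out_dir = NULL) {
  res <- lapply(c("control", "stress"), function(p) {
    sim <- simulate_frap_movie(seed = seed, preset = sim_preset(p))
    analyse_frap_sim(sim, reference = FALSE)
  })
  names(res) <- c("control", "stress")
  tab <- data.frame(
    condition = names(res),
    max_recovery_pct = vapply(res, function(r) r$fit$max_recovery_pct, 0),
    initial_rate = vapply(res, function(r) r$fit$initial_rate, 0),
    rate_k = vapply(res, function(r) r$fit$rate_k, 0)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(out_dir, "frap_summary.csv"), row.names = FALSE)
    for (p in names(res)) {
      write.csv(data.frame(time_s = res[[p]]$curve$times,
                           recovery_pct = res[[p]]$curve$recovery_pct),
                file.path(out_dir, paste0("frap_curve_", p, ".csv")),
                row.names = FALSE)
    }
  }
  list(scenario = "fig4_stress_frap",
       max_recovery_control = tab$max_recovery_pct[1],
       max_recovery_stress = tab$max_recovery_pct[2],
       initial_rate_control = tab$initial_rate[1],
       initial_rate_stress = tab$initial_rate[2],
       control_exceeds_stress =
         tab$max_recovery_pct[1] > tab$max_recovery_pct[2] &&
         tab$initial_rate[1] > tab$initial_rate[2])
}

#' Extract and fit the recovery curve of a simulated FRAP experiment
#'
#' Builds the standard ROI set for a [simulate_frap_movie()] result (the
#' bleached droplet disc, a background rectangle in a field corner, and an
#' optional far-field reference annulus for double normalization), then
#' extracts and fits the recovery curve.
#'
#' @param sim Result of [simulate_frap_movie()].
#' @param reference Use a far-field reference ROI (double normalization)?
#' @return List with `curve` and `fit`.
#' @export
analyse_frap_sim <- function(sim, reference = TRUE) {
  acq <- sim$movie$acquisition
  gt <- sim$ground_truth
  ps <- acq$pixel_size
  drop1 <- gt$droplets[gt$droplets$frame == 1, ][1, ]
  cx <- drop1$x / ps; cy <- drop1$y / ps
  r_px <- drop1$radius / ps
  bleach <- roi_circle(cx, cy, r_px + 0.2 / ps)
  bg <- roi_rect(1, 1, 16, 16)   # field corner, outside the nucleus
  ref <- if (reference) {
    roi_annulus(cx, cy, r_px + 3 / ps, r_px + 8 / ps)
  } else NULL
  curve <- suppressWarnings(
    extract_recovery_curve(sim$movie, bleach, gt$bleach_frame,
                           background_roi = bg, reference_roi = ref)
  )
  list(curve = curve, fit = fit_recovery(curve))
}

scenario_sizes <- function(seed, out_dir = NULL) {
  set.seed(seed)
  nbs <- data.frame(
    x = c(8, 15, 12, 16.5, 9, 13.5),
    y = c(9, 9, 12.5, 13.5, 15, 16),
    diameter = c(0.6, 0.7, 1.2, 1.8, 2.4, 3.0),
    intensity = 80
  )
  img <- render_static_nucleus(nucleus_center = c(12, 12), nucleus_radius = 8,
                               cell_radius = 11, nbs = nbs)
  res <- quantify_nucleus(img$channels$protein, img$masks$nucleus,
                          pixel_size = img$params$pixel_size,
                          cell_mask = img$masks$cell,
                          rna_channel = img$channels$rna,
                          background_region = !img$masks$cell)
  truth_classes <- table(factor(img$ground_truth$size_class,
                                levels = c("I", "II", "III")))
  meas_classes <- table(factor(res$nbs$size_class,
                               levels = c("I", "II", "III")))
  # match measured objects to truth by centroid proximity
  match_idx <- vapply(seq_len(nrow(res$nbs)), function(i) {
    which.min((img$ground_truth$x - res$nbs$centroid_x_um[i])^2 +
                (img$ground_truth$y - res$nbs$centroid_y_um[i])^2)
  }, 0L)
  diam_err <- res$nbs$eq_diameter_um - img$ground_truth$diameter[match_idx]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(res$nbs, file.path(out_dir, "nb_objects.csv"), row.names = FALSE)
  }
  list(scenario = "fig1_sizes",
       n_true = nrow(nbs), n_measured = res$n_nbs,
       class_counts_true = as.list(truth_classes),
       class_counts_measured = as.list(meas_classes),
       class_counts_match = all(truth_classes == meas_classes),
       max_abs_diameter_error_um = max(abs(diam_err)),
       total_nb_area_um2 = res$total_nb_area,
       fn_c = res$fn_c,
       rna_ratio = res$rna_ratio)
}
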