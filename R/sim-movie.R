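#' Simulate a confocal time series of droplet-partitioned particles
#'
#' Generates a movie of Brownian particles partitioning into one or more
#' liquid droplets with tunable boundary exchange, rendered through a
#' Gaussian-PSF Poisson detector, together with full ground truth. Particles
#' are initialized at the stationary partitioning implied by
#' `p_enter / p_exit` and equilibrated for `burn_in` frames before recording,
#' so moment maps are free of initialization transients. Identical inputs
#' (including `seed`) give a bit-identical movie.
#'
#' @param acq An [acquisition_config()]; the default emulates a rapid
#'   1000-frame 64 x 64 px acquisition.
#' @param droplets List of [droplet_spec()]s, all fully inside the field.
#' @param detector A [detector_model()].
#' @param n_particles Number of particles (constant over the simulation).
#' @param immobile_fraction Fraction of particles that never move.
#' @param preset A [sim_preset()]; `"stress"` scales both boundary crossing
#'   probabilities by 0.2.
#' @param seed Integer seed (required).
#' @param burn_in Equilibration frames before recording (default 200).
#' @param record_trajectories Keep per-particle trajectories in the ground
#'   truth (memory permitting).
#' @return A list with elements `movie` ([nb_movie()]) and `ground_truth`.
#' @examples
#' sim <- simulate_droplet_movie(
#'   acq = acquisition_config(n_frames = 20),
#'   n_particles = 200, seed = 1, burn_in = 10)
#' sim$movie
#' @export
simulate_droplet_movie <- function(acq = acquisition_config(),
                                   droplets = list(droplet_spec(
                                     center = c(acq$field_of_view / 2,
                                                acq$field_of_view / 2),
                                     radius = 1.5)),
                                   detector = detector_model(),
                                   n_particles = 2000,
                                   immobile_fraction = 0,
                                   preset = sim_preset("control"),
                                   seed,
                                   burn_in = 200,
                                   record_trajectories = TRUE) {
  st <- sim_state(acq, droplets, detector, n_particles, immobile_fraction,
                  preset, seed)
  st$time <- -burn_in * st$dt
  timestamps <- (seq_len(acq$n_frames) - 1) * acq$frame_time
  rec <- sim_record(st, timestamps)
  frames <- render_frames(st, rec)
  movie <- nb_movie(frames, acq, timestamps)
  gt <- new_ground_truth(st, rec, timestamps,
                         record_trajectories = record_trajectories)
  list(movie = movie, ground_truth = gt, detector = detector)
}

frap_timestamps <- function(n_prebleach, prebleach_interval,
                            postbleach_interval, total_postbleach) {
  pre <- (seq_len(n_prebleach) - 1) * prebleach_interval
  t_bleach <- n_prebleach * prebleach_interval
  post0 <- t_bleach + prebleach_interval
  post <- post0 + seq(0, total_postbleach, by = postbleach_interval)
  list(times = c(pre, t_bleach, post), bleach_frame = n_prebleach + 1L)
}

#' Run a photobleaching protocol on a droplet simulation
#'
#' Applies the standard FRAP protocol to an in-progress droplet simulation:
#' `n_prebleach` frames at a minimal interval (1.3 s), a single bleach frame
#' during which every fluorescent particle inside the bleach ROI is switched
#' off with probability `bleach_probability`, then recovery frames every
#' `postbleach_interval` seconds for `total_postbleach` seconds. Frame
#' timestamps (non-uniform) are carried by the returned movie and recorded
#' in the ground truth. Particle dynamics always advance at the simulation
#' step `state$dt` regardless of the frame spacing.
#'
#' @param state A simulation state as built internally by
#'   [simulate_frap_movie()]; most users want that wrapper.
#' @param bleach_roi An ROI ([roi_circle()] etc.) in pixel coordinates.
#' @param bleach_frame 1-based index of the bleach frame; must equal
#'   `n_prebleach + 1` (the bleach occupies exactly one frame).
#' @param bleach_probability Probability that a fluorophore inside the ROI
#'   is bleached.
#' @param n_prebleach Number of pre-bleach frames (default 3).
#' @param prebleach_interval Pre-bleach frame spacing in seconds (default 1.3).
#' @param postbleach_interval Recovery frame spacing in seconds (default 5).
#' @param total_postbleach Recovery duration in seconds (default 250).
#' @return A list with `movie` and `ground_truth`.
#' @export
apply_frap_protocol <- function(state, bleach_roi,
                                bleach_frame = n_prebleach + 1L,
                                bleach_probability = 1,
                                n_prebleach = 3L,
                                prebleach_interval = 1.3,
                                postbleach_interval = 5,
                                total_postbleach = 250) {
  if (bleach_frame != n_prebleach + 1L) {
    nb_stop("invalid_bleach_frame",
            "bleach_frame must immediately follow the pre-bleach frames")
  }
  # rasterization errors out on empty ROIs
  roi_pixels(bleach_roi, state$acq$frame_shape)
  tt <- frap_timestamps(n_prebleach, prebleach_interval,
                        postbleach_interval, total_postbleach)
  nt <- length(tt$times)
  rec_pre <- sim_record(state, tt$times[seq_len(tt$bleach_frame)])
  sim_bleach(state, bleach_roi, bleach_probability)
  state$bleach_events <- c(state$bleach_events, list(data.frame(
    frame_index = tt$bleach_frame,
    roi = bleach_roi$shape,
    bleach_probability = bleach_probability
  )))
  rec_post <- sim_record(state, tt$times[(tt$bleach_frame + 1L):nt])
  rec <- list(
    x = cbind(rec_pre$x, rec_post$x),
    y = cbind(rec_pre$y, rec_post$y),
    fluor = cbind(rec_pre$fluor, rec_post$fluor),
    droplets = rbind(rec_pre$droplets,
                     within(rec_post$droplets,
                            frame <- frame + tt$bleach_frame))
  )
  acq <- acquisition_config(nt, state$acq$frame_shape, state$acq$frame_time,
                            state$acq$pixel_size)
  frames <- render_frames(state, rec)
  movie <- nb_movie(frames, acq, tt$times)
  gt <- new_ground_truth(state, rec, tt$times,
                         extra = list(bleach_frame = tt$bleach_frame,
                                      n_prebleach = n_prebleach))
  list(movie = movie, ground_truth = gt, detector = state$detector)
}

#' Simulate a complete FRAP experiment on one droplet
#'
#' Convenience wrapper: builds a droplet simulation sized for photobleaching
#' work and runs [apply_frap_protocol()] on it. The defaults put one 1-um
#' droplet in a 30-um-diameter nucleus so that the droplet holds only a
#' small share (about 8 percent) of the fluorescent pool, with the standard
#' droplet kinetics (`p_enter = 1`, `p_exit = 0.05`): recovery after
#' bleaching the whole droplet is boundary-limited with a control rate
#' constant near 0.03/s, so the control curve saturates within the 250-s
#' protocol while the five-fold slower stress preset does not.
#'
#' @inheritParams simulate_droplet_movie
#' @inheritParams apply_frap_protocol
#' @param bleach_roi Defaults to a circle covering the droplet plus a small
#'   margin, i.e. the whole body is bleached and recovery reports boundary
#'   exchange.
#' @param nucleus_radius Radius (um) of the nuclear disc confining the
#'   particles, centred in the field; the image corners are then true
#'   background (detector counts only), as outside a real cell.
#' @return A list with `movie` and `ground_truth`.
#' @export
simulate_frap_movie <- function(droplets = NULL,
                                detector = detector_model(acq_bleach = 0.006),
                                n_particles = 20000,
                                immobile_fraction = 0,
                                preset = sim_preset("control"),
                                seed,
                                bleach_roi = NULL,
                                bleach_probability = 1,
                                n_prebleach = 3L,
                                prebleach_interval = 1.3,
                                postbleach_interval = 5,
                                total_postbleach = 250,
                                frame_shape = c(80L, 80L),
                                pixel_size = 0.42,
                                nucleus_radius = 15,
                                sim_dt = 0.121,
                                burn_in = 200) {
  tt <- frap_timestamps(n_prebleach, prebleach_interval,
                        postbleach_interval, total_postbleach)
  acq <- acquisition_config(length(tt$times), frame_shape,
                            frame_time = sim_dt, pixel_size = pixel_size)
  fov <- acq$field_of_view
  if (is.null(droplets)) {
    droplets <- list(droplet_spec(center = c(fov / 2, fov / 2), radius = 1,
                                  p_exit = 0.05, p_enter = 1))
  }
  if (is.null(bleach_roi)) {
    d <- droplets[[1]]
    bleach_roi <- roi_circle(d$center[1] / pixel_size,
                             d$center[2] / pixel_size,
                             (d$radius + 0.2) / pixel_size)
  }
  st <- sim_state(acq, droplets, detector, n_particles, immobile_fraction,
                  preset, seed, dt = sim_dt, nucleus_radius = nucleus_radius)
  st$time <- -burn_in * sim_dt
  apply_frap_protocol(st, bleach_roi,
                      bleach_frame = n_prebleach + 1L,
                      bleach_probability = bleach_probability,
                      n_prebleach = n_prebleach,
                      prebleach_interval = prebleach_interval,
                      postbleach_interval = postbleach_interval,
                      total_postbleach = total_postbleach)
}

#' Simulate two droplets drifting together and fusing
#'
#' The droplet centres approach each other along their connecting line at
#' `approach_speed` (closing speed); at first rim contact the two discs are
#' replaced by a single droplet whose area is the sum of the two (2-D area
#' conservation, merged radius `sqrt(ra^2 + rb^2)`) centred at the
#' area-weighted centroid. Fusion is instantaneous; particle count is
#' conserved throughout, and the contact frame and time are recorded in the
#' ground truth. `approach_speed = 0` reproduces two static droplets.
#'
#' @inheritParams simulate_droplet_movie
#' @param droplet_a,droplet_b Initially disjoint [droplet_spec()]s; the
#'   merged droplet inherits the kinetic parameters of `droplet_a`.
#' @param approach_speed Closing speed of the two centres in um/s (>= 0).
#' @return A list with `movie` and `ground_truth` (fields `contact_time`,
#'   `contact_frame`).
#' @export
simulate_fusion_movie <- function(acq = acquisition_config(),
                                  droplet_a, droplet_b,
                                  approach_speed = 0.05,
                                  detector = detector_model(),
                                  n_particles = 2000,
                                  immobile_fraction = 0,
                                  preset = sim_preset("control"),
                                  seed,
                                  burn_in = 200,
                                  record_trajectories = TRUE) {
  if (approach_speed < 0) nb_stop("invalid_config", "approach_speed must be >= 0")
  ca <- droplet_a$center; cb <- droplet_b$center
  dist0 <- sqrt(sum((ca - cb)^2))
  gap <- dist0 - (droplet_a$radius + droplet_b$radius)
  if (gap <= 0) nb_stop("droplets_overlap", "initial droplets must be disjoint")
  t_contact <- if (approach_speed > 0) gap / approach_speed else Inf
  u <- (cb - ca) / dist0
  aa <- droplet_a$radius^2; ab <- droplet_b$radius^2
  merged_radius <- sqrt(aa + ab)

  droplet_fn <- function(t) {
    t <- max(t, 0)
    if (t < t_contact) {
      da <- droplet_a; db <- droplet_b
      da$center <- ca + u * (approach_speed / 2) * t
      db$center <- cb - u * (approach_speed / 2) * t
      da$drift_velocity <- u * approach_speed / 2
      db$drift_velocity <- -u * approach_speed / 2
      list(da, db)
    } else {
      pa <- ca + u * (approach_speed / 2) * t_contact
      pb <- cb - u * (approach_speed / 2) * t_contact
      dm <- droplet_a
      dm$center <- (pa * aa + pb * ab) / (aa + ab)
      dm$radius <- merged_radius
      dm$drift_velocity <- c(0, 0)
      list(dm)
    }
  }

  st <- sim_state(acq, list(droplet_a, droplet_b), detector, n_particles,
                  immobile_fraction, preset, seed, droplet_fn = droplet_fn)
  st$time <- -burn_in * st$dt
  timestamps <- (seq_len(acq$n_frames) - 1) * acq$frame_time
  rec <- sim_record(st, timestamps)
  frames <- render_frames(st, rec)
  movie <- nb_movie(frames, acq, timestamps)
  contact_frame <- if (is.finite(t_contact)) {
    idx <- which(timestamps >= t_contact)
    if (length(idx)) idx[1] else NA_integer_
  } else NA_integer_
  gt <- new_ground_truth(st, rec, timestamps,
                         extra = list(contact_time = t_contact,
                                      contact_frame = contact_frame,
                                      merged_radius = merged_radius),
                         record_trajectories = record_trajectories)
  list(movie = movie, ground_truth = gt, detector = detector)
}
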