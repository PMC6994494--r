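#' Droplet ground-truth specification
#'
#' Describes one liquid droplet (nuclear body) for the simulator: its disc
#' geometry, the diffusion coefficients inside and outside, and the boundary
#' permeabilities. A Brownian step whose segment crosses the droplet rim is
#' accepted with probability `p_exit` (inside to outside) or `p_enter`
#' (outside to inside), otherwise the particle is specularly reflected at the
#' rim. With `p_enter > p_exit` the stationary particle density inside the
#' droplet exceeds the outside density by roughly `p_enter / p_exit`
#' (detailed-balance heuristic), which is how partitioning into the dense
#' phase is encoded.
#'
#' @param center Droplet centre `c(x, y)` in um.
#' @param radius Droplet radius in um (> 0).
#' @param D_in,D_out Diffusion coefficients inside/outside the droplet
#'   (um^2/s, >= 0). All droplets in one simulation share `D_out` (the
#'   nucleoplasm is one medium).
#' @param p_exit,p_enter Boundary crossing probabilities per encounter, in
#'   `[0, 1]`.
#' @param drift_velocity Deterministic drift `c(vx, vy)` of the droplet
#'   centre in um/s; particles inside are advected along.
#' @param boundary_event_rate Rate of interfacial remodeling events, per um
#'   of rim perimeter per second, before preset scaling (see Details).
#' @param boundary_event_amp Peak radial displacement of a remodeling event
#'   in um.
#' @param boundary_event_duration Duration of one event in seconds.
#' @param boundary_event_width Angular half-width (Gaussian sigma, um of
#'   arc) of one event.
#'
#' @details
#' A liquid interface is not static: rim molecules undergo transient,
#' collective remodeling (capillary-wave-like protrusions) that shows up in
#' fluctuation imaging as coordinated movement confined to the boundary.
#' The simulator models this as discrete events: Poisson-distributed in
#' time along the rim at `boundary_event_rate` per um of perimeter per
#' second, each a transient outward bulge (half-sine in time over
#' `boundary_event_duration`) that displaces rim-proximal particles
#' radially by up to `boundary_event_amp`, tapered as a Gaussian along the
#' arc (`boundary_event_width`) and radially. The preset's
#' `boundary_mobility_factor` thins the event sequence (a stress rim is
#' rigid: it remodels five-fold less often, exactly as it exchanges
#' five-fold slower), and event amplitude is scaled by the phase contrast
#' `1 - p_exit / p_enter`, so a droplet that is a no-op
#' (`p_exit = p_enter`) has no visible interface at all. The default rate
#' keeps events sparse (about two per 80-frame segment on the default rim),
#' which makes the frequency of high-ratio boundary pixels an approximately
#' linear reporter of boundary mobility.
#' @return An object of class `nb_droplet`.
#' @export
droplet_spec <- function(center, radius, D_in = 0.05, D_out = 0.5,
                         p_exit = 0.05, p_enter = 1, drift_velocity = c(0, 0),
                         boundary_event_rate = 0.05,
                         boundary_event_amp = 0.4,
                         boundary_event_duration = 1.5,
                         boundary_event_width = 0.6) {
  if (!is_scalar_num(radius) || radius <= 0) {
    nb_stop("invalid_config", "radius must be > 0")
  }
  if (p_exit < 0 || p_exit > 1 || p_enter < 0 || p_enter > 1) {
    nb_stop("invalid_config", "p_exit and p_enter must lie in [0, 1]")
  }
  if (D_in < 0 || D_out < 0) nb_stop("invalid_config", "D must be >= 0")
  if (boundary_event_rate < 0 || boundary_event_amp < 0 ||
      boundary_event_duration <= 0 || boundary_event_width <= 0) {
    nb_stop("invalid_config", "boundary event parameters out of range")
  }
  structure(
    list(center = as.numeric(center), radius = radius,
         D_in = D_in, D_out = D_out,
         p_exit = p_exit, p_enter = p_enter,
         drift_velocity = as.numeric(drift_velocity),
         boundary_event_rate = boundary_event_rate,
         boundary_event_amp = boundary_event_amp,
         boundary_event_duration = boundary_event_duration,
         boundary_event_width = boundary_event_width),
    class = "nb_droplet"
  )
}

#' Confocal photon-detection model
#'
#' Emulates confocal detection of point emitters: each fluorescent particle
#' contributes an isotropic Gaussian point-spread function integrated over
#' the pixel grid, scaled by its molecular brightness; a uniform background
#' is added and, with `noise = "poisson"`, each pixel value is drawn from a
#' Poisson distribution with that expectation (photon shot noise). With
#' shot noise alone the per-pixel variance/mean ratio is 1, which is the
#' calibration floor of the moment analysis.
#'
#' @param brightness Expected counts per fluorophore per frame at the PSF
#'   centre (>= 0).
#' @param psf_sigma Gaussian PSF sigma in um (> 0); the default 0.21 um is
#'   about one pixel at the default calibration.
#' @param background Expected counts/pixel/frame (>= 0).
#' @param noise `"poisson"` or `"none"`.
#' @param acq_bleach Probability that a fluorophore is photobleached by the
#'   illumination of one recorded frame (acquisition photobleaching);
#'   default 0. Long protocols with many frames show a slow intensity decay
#'   when this is non-zero, as real confocal FRAP series do; a reference ROI
#'   (double normalization) divides it out.
#' @return An object of class `nb_detector`.
#' @export
detector_model <- function(brightness = 5, psf_sigma = 0.21, background = 2,
                           noise = c("poisson", "none"), acq_bleach = 0) {
  noise <- match.arg(noise)
  if (brightness < 0 || background < 0) {
    nb_stop("invalid_config", "brightness and background must be >= 0")
  }
  if (psf_sigma <= 0) nb_stop("invalid_config", "psf_sigma must be > 0")
  if (acq_bleach < 0 || acq_bleach > 1) {
    nb_stop("invalid_config", "acq_bleach must lie in [0, 1]")
  }
  structure(
    list(brightness = brightness, psf_sigma = psf_sigma,
         background = background, noise = noise, acq_bleach = acq_bleach),
    class = "nb_detector"
  )
}

#' Simulation condition presets
#'
#' Two ground-truth conditions: `"control"` leaves boundary permeabilities
#' untouched (factor 1), `"stress"` multiplies both `p_exit` and `p_enter`
#' by 0.2, encoding a five-fold reduction of protein mobility at the droplet
#' boundary (the oxidative-stress phenotype) as a single recoverable factor.
#' Diffusion coefficients are unchanged, so the equilibrium partitioning is
#' preserved while boundary exchange slows five-fold.
#'
#' @param name `"control"` or `"stress"`.
#' @return An object of class `nb_preset` with fields `name` and
#'   `boundary_mobility_factor`.
#' @export
sim_preset <- function(name = c("control", "stress")) {
  name <- match.arg(name)
  structure(
    list(name = name,
         boundary_mobility_factor = if (name == "control") 1.0 else 0.2),
    class = "nb_preset"
  )
}
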