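# Internal Brownian-dynamics engine.
#
# A simulation state is an environment holding particle positions (um),
# immobility and fluorescence flags, the droplet geometry as a function of
# time, and one RNG sub-stream per randomness layer (placement, diffusion,
# bleaching, detection). Sub-streams are derived deterministically from the
# user seed, so e.g. toggling acquisition photobleaching or the detector
# noise does not perturb the trajectories of a seed-matched run.

rng_capture <- function(seed) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  captured <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  captured
}

# Evaluate expr with the named RNG sub-stream active, then store its
# advanced state back and restore the caller's stream.
use_stream <- function(state, name, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", state$rng[[name]], globalenv())
  on.exit({
    state$rng[[name]] <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  eval.parent(substitute(expr))
}

validate_droplets <- function(droplets, acq) {
  if (length(droplets) == 0) nb_stop("invalid_config", "need at least one droplet")
  fov_x <- acq$frame_shape[2] * acq$pixel_size
  fov_y <- acq$frame_shape[1] * acq$pixel_size
  for (d in droplets) {
    if (d$center[1] - d$radius < 0 || d$center[1] + d$radius > fov_x ||
        d$center[2] - d$radius < 0 || d$center[2] + d$radius > fov_y) {
      nb_stop("droplet_out_of_bounds",
              "droplet does not lie fully inside the field of view")
    }
  }
  d_out <- vapply(droplets, function(d) d$D_out, 0)
  if (length(unique(d_out)) > 1L) {
    nb_stop("invalid_config", "all droplets must share D_out (one outside medium)")
  }
  invisible(TRUE)
}

# state constructor; droplet_fn(t) must return the droplet list with centres
# evaluated at simulation time t (t < 0 during burn-in maps to t = 0).
sim_state <- function(acq, droplets, detector, n_particles, immobile_fraction,
                      preset, seed, droplet_fn = NULL, dt = acq$frame_time,
                      nucleus_radius = NULL) {
  if (!is_count(n_particles)) nb_stop("invalid_config", "n_particles must be a count")
  if (immobile_fraction < 0 || immobile_fraction > 1) {
    nb_stop("invalid_config", "immobile_fraction must lie in [0, 1]")
  }
  if (is.null(seed) || !is_scalar_num(seed)) {
    nb_stop("invalid_config", "a numeric seed is required (reproducibility contract)")
  }
  validate_droplets(droplets, acq)
  st <- new.env(parent = emptyenv())
  st$acq <- acq
  st$detector <- detector
  st$fov_x <- acq$frame_shape[2] * acq$pixel_size
  st$fov_y <- acq$frame_shape[1] * acq$pixel_size
  st$n <- as.integer(n_particles)
  st$preset <- preset
  st$factor <- preset$boundary_mobility_factor
  st$seed <- seed
  st$dt <- dt
  st$time <- 0
  st$droplet_fn <- droplet_fn %||% static_droplet_fn(droplets)
  # optional confinement to a nuclear disc centred in the field; the region
  # outside then carries only detector background, as outside a real cell
  st$nucleus_radius <- nucleus_radius
  st$nucleus_center <- c(st$fov_x, st$fov_y) / 2
  if (!is.null(nucleus_radius)) {
    for (d in droplets) {
      if (sqrt(sum((d$center - st$nucleus_center)^2)) + d$radius >
          nucleus_radius) {
        nb_stop("droplet_out_of_bounds", "droplet outside the nucleus")
      }
    }
  }
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  subseeds <- sample.int(2147483646L, 5L)
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  st$rng <- list(placement = rng_capture(subseeds[1]),
                 diffusion = rng_capture(subseeds[2]),
                 bleach = rng_capture(subseeds[3]),
                 detection = rng_capture(subseeds[4]),
                 interface = rng_capture(subseeds[5]))
  place_particles(st)
  generate_boundary_events(st)
  st$fluor <- rep(TRUE, st$n)
  use_stream(st, "placement", {
    st$immobile <- rep(FALSE, st$n)
    n_imm <- round(immobile_fraction * st$n)
    if (n_imm > 0) st$immobile[sample.int(st$n, n_imm)] <- TRUE
  })
  st$immobile_fraction <- immobile_fraction
  st$bleach_events <- list()
  st
}

static_droplet_fn <- function(droplets) {
  force(droplets)
  function(t) {
    t <- max(t, 0)
    lapply(droplets, function(d) {
      d$center <- d$center + d$drift_velocity * t
      d
    })
  }
}

# Stationary initialization: particle counts per region are multinomial with
# weights area * (p_enter / p_exit) inside each droplet and area * 1 outside
# (detailed-balance heuristic); burn-in finishes equilibration.
place_particles <- function(st) {
  drops <- st$droplet_fn(0)
  areas <- vapply(drops, function(d) pi * d$radius^2, 0)
  ratios <- vapply(drops, function(d) {
    if (d$p_exit <= 0) 1e6 else min(d$p_enter / d$p_exit, 1e6)
  }, 0)
  a_total <- if (is.null(st$nucleus_radius)) st$fov_x * st$fov_y else
    pi * st$nucleus_radius^2
  a_out <- a_total - sum(areas)
  w <- c(areas * ratios, a_out)
  use_stream(st, "placement", {
    if (st$n == 0) {
      st$x <- numeric(0); st$y <- numeric(0)
    } else {
      counts <- as.vector(stats::rmultinom(1, st$n, w))
      xs <- numeric(0); ys <- numeric(0)
      for (i in seq_along(drops)) {
        if (counts[i] == 0) next
        r <- drops[[i]]$radius * sqrt(runif(counts[i]))
        th <- runif(counts[i], 0, 2 * pi)
        xs <- c(xs, drops[[i]]$center[1] + r * cos(th))
        ys <- c(ys, drops[[i]]$center[2] + r * sin(th))
      }
      n_out <- counts[length(counts)]
      got_x <- numeric(0); got_y <- numeric(0)
      while (length(got_x) < n_out) {
        m <- 2 * (n_out - length(got_x)) + 16
        if (is.null(st$nucleus_radius)) {
          cx <- runif(m, 0, st$fov_x); cy <- runif(m, 0, st$fov_y)
        } else {
          rr <- st$nucleus_radius * sqrt(runif(m))
          th <- runif(m, 0, 2 * pi)
          cx <- st$nucleus_center[1] + rr * cos(th)
          cy <- st$nucleus_center[2] + rr * sin(th)
        }
        inside <- rep(FALSE, m)
        for (d in drops) {
          inside <- inside |
            ((cx - d$center[1])^2 + (cy - d$center[2])^2 < d$radius^2)
        }
        got_x <- c(got_x, cx[!inside]); got_y <- c(got_y, cy[!inside])
      }
      st$x <- c(xs, got_x[seq_len(n_out)])
      st$y <- c(ys, got_y[seq_len(n_out)])
    }
  })
  invisible(st)
}

droplet_membership <- function(x, y, drops) {
  k <- length(drops)
  idx <- integer(length(x))  # 0 = outside, else droplet index
  for (i in rev(seq_len(k))) {
    d <- drops[[i]]
    idx[(x - d$center[1])^2 + (y - d$center[2])^2 < d$radius^2] <- i
  }
  idx
}

# One Brownian step of length dt for all mobile particles, with advection by
# droplet motion, boundary acceptance/reflection and reflecting field edges.
sim_step <- function(st) {
  t0 <- st$time
  t1 <- t0 + st$dt
  drops0 <- st$droplet_fn(t0)
  drops1 <- st$droplet_fn(t1)
  if (st$n == 0) { st$time <- t1; return(invisible(st)) }

  mem0 <- droplet_membership(st$x, st$y, drops0)
  # advect everything bound inside a moving droplet (immobile cargo included)
  for (i in seq_along(drops0)) {
    if (i > length(drops1)) next  # droplet vanished (fusion); no advection
    sel <- mem0 == i
    if (!any(sel)) next
    dxc <- drops1[[i]]$center - drops0[[i]]$center
    st$x[sel] <- st$x[sel] + dxc[1]
    st$y[sel] <- st$y[sel] + dxc[2]
  }

  mob <- which(!st$immobile)
  if (length(mob)) {
    mem <- droplet_membership(st$x[mob], st$y[mob], drops1)
    D <- rep(drops1[[1]]$D_out, length(mob))
    for (i in seq_along(drops1)) {
      sel <- mem == i
      if (any(sel)) D[sel] <- drops1[[i]]$D_in
    }
    sdv <- sqrt(2 * D * st$dt)
    use_stream(st, "diffusion", {
      x0 <- st$x[mob]; y0 <- st$y[mob]
      x1 <- x0 + rnorm(length(mob), 0, sdv)
      y1 <- y0 + rnorm(length(mob), 0, sdv)
      for (i in seq_along(drops1)) {
        d <- drops1[[i]]
        in0 <- (x0 - d$center[1])^2 + (y0 - d$center[2])^2 < d$radius^2
        in1 <- (x1 - d$center[1])^2 + (y1 - d$center[2])^2 < d$radius^2
        cross <- which(in0 != in1)
        if (!length(cross)) next
        # step-length (detailed-balance) correction: boundary encounter
        # rates scale with the step sd (~sqrt(D)), so raw acceptance
        # probabilities would equilibrate at (p_enter/p_exit) *
        # sqrt(D_out/D_in); damping the faster side makes the stationary
        # density ratio exactly p_enter/p_exit
        if (d$D_in > 0 && d$D_out > 0) {
          corr_enter <- min(1, sqrt(d$D_in / d$D_out))
          corr_exit <- min(1, sqrt(d$D_out / d$D_in))
        } else {
          corr_enter <- 1; corr_exit <- 1
        }
        p_acc <- ifelse(in0[cross], d$p_exit * corr_exit,
                        d$p_enter * corr_enter) * st$factor
        rej <- cross[runif(length(cross)) >= p_acc]
        if (!length(rej)) next
        refl <- reflect_at_circle(x0[rej], y0[rej], x1[rej], y1[rej],
                                  d$center, d$radius, in0[rej])
        x1[rej] <- refl$x; y1[rej] <- refl$y
      }
      if (!is.null(st$nucleus_radius)) {
        # radial reflection at the nuclear envelope
        dxn <- x1 - st$nucleus_center[1]; dyn <- y1 - st$nucleus_center[2]
        rr <- sqrt(dxn^2 + dyn^2)
        out <- rr > st$nucleus_radius
        if (any(out)) {
          rnew <- pmax(2 * st$nucleus_radius - rr[out], 0)
          scl <- rnew / rr[out]
          x1[out] <- st$nucleus_center[1] + dxn[out] * scl
          y1[out] <- st$nucleus_center[2] + dyn[out] * scl
        }
      }
      st$x[mob] <- reflect_into(x1, st$fov_x)
      st$y[mob] <- reflect_into(y1, st$fov_y)
    })
  }
  st$time <- t1
  invisible(st)
}

# Specular reflection of the segment p0 -> p1 at a circle. Falls back to
# staying at p0 when the reflected point still ends on the wrong side
# (grazing geometry).
reflect_at_circle <- function(x0, y0, x1, y1, center, r, in0) {
  dx <- x1 - x0; dy <- y1 - y0
  fx <- x0 - center[1]; fy <- y0 - center[2]
  a <- dx^2 + dy^2
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx^2 + fy^2 - r^2
  disc <- pmax(b^2 - 4 * a * cc, 0)
  sq <- sqrt(disc)
  ta <- (-b - sq) / (2 * a)
  tb <- (-b + sq) / (2 * a)
  tt <- ifelse(ta > 1e-12 & ta <= 1, ta, tb)
  tt <- pmin(pmax(tt, 1e-12), 1)
  pix <- x0 + tt * dx; piy <- y0 + tt * dy
  nx <- (pix - center[1]) / r; ny <- (piy - center[2]) / r
  vx <- (1 - tt) * dx; vy <- (1 - tt) * dy
  dot <- vx * nx + vy * ny
  rx <- pix + vx - 2 * dot * nx
  ry <- piy + vy - 2 * dot * ny
  in_new <- (rx - center[1])^2 + (ry - center[2])^2 < r^2
  bad <- in_new != in0
  rx[bad] <- x0[bad]; ry[bad] <- y0[bad]
  list(x = rx, y = ry)
}

# Interfacial remodeling events: Poisson candidate events along each rim
# over a fixed horizon, thinned by the preset's boundary mobility factor,
# so a stress run's events are a subset of the seed-matched control run's.
# Events displace rim-proximal particles at render time only; trajectories
# and partitioning statistics are untouched.
event_horizon_s <- 2000

generate_boundary_events <- function(st) {
  drops <- st$droplet_fn(0)
  rows <- list()
  use_stream(st, "interface", {
    for (i in seq_along(drops)) {
      d <- drops[[i]]
      lam <- d$boundary_event_rate * 2 * pi * d$radius * event_horizon_s
      n_ev <- rpois(1, lam)
      if (n_ev == 0) next
      rows[[i]] <- data.frame(
        droplet = i,
        t_start = runif(n_ev, 0, event_horizon_s),
        angle = runif(n_ev, 0, 2 * pi),
        keep = runif(n_ev) < st$factor
      )
    }
  })
  ev <- if (length(rows)) do.call(rbind, rows) else
    data.frame(droplet = integer(0), t_start = numeric(0),
               angle = numeric(0), keep = logical(0))
  ev <- ev[ev$keep, , drop = FALSE]
  st$boundary_events <- ev[order(ev$t_start), , drop = FALSE]
  invisible(st)
}

# Radial displacement of rendered positions by the remodeling events active
# at time t. Amplitude is scaled by the phase contrast 1 - p_exit/p_enter:
# a boundary that is a kinetic no-op has no interface to remodel.
apply_boundary_events <- function(st, x, y, t) {
  ev <- st$boundary_events
  if (is.null(ev) || nrow(ev) == 0 || length(x) == 0) return(list(x = x, y = y))
  drops <- st$droplet_fn(t)
  act <- ev[ev$t_start <= t & t < ev$t_start + vapply(
    ev$droplet, function(i) {
      if (i <= length(drops)) drops[[i]]$boundary_event_duration else 0
    }, 0), , drop = FALSE]
  if (nrow(act) == 0) return(list(x = x, y = y))
  for (k in seq_len(nrow(act))) {
    i <- act$droplet[k]
    if (i > length(drops)) next
    d <- drops[[i]]
    kappa <- if (d$p_enter > 0) max(1 - d$p_exit / d$p_enter, 0) else 1
    if (kappa <= 0) next
    dx <- x - d$center[1]; dy <- y - d$center[2]
    r <- sqrt(dx^2 + dy^2)
    near <- which(abs(r - d$radius) < 3 * 0.25 + d$boundary_event_amp)
    if (!length(near)) next
    phi <- atan2(dy[near], dx[near])
    arc <- (phi - act$angle[k] + pi) %% (2 * pi) - pi
    arc_um <- arc * d$radius
    g <- exp(-arc_um^2 / (2 * d$boundary_event_width^2)) *
      exp(-(r[near] - d$radius)^2 / (2 * 0.25^2))
    dt_ev <- t - act$t_start[k]
    amp <- d$boundary_event_amp * kappa *
      sin(pi * dt_ev / d$boundary_event_duration)
    push <- amp * g
    nz <- push > 1e-6 & r[near] > 1e-9
    idx <- near[nz]
    x[idx] <- x[idx] + push[nz] * dx[idx] / r[idx]
    y[idx] <- y[idx] + push[nz] * dy[idx] / r[idx]
  }
  list(x = x, y = y)
}

# Switch off fluorescent particles inside an ROI with given probability.
sim_bleach <- function(st, roi, probability) {
  ps <- st$acq$pixel_size
  inside <- roi_contains(roi, st$x / ps, st$y / ps)
  use_stream(st, "bleach", {
    hit <- inside & st$fluor & (runif(st$n) < probability)
    st$fluor[hit] <- FALSE
  })
  invisible(st)
}

sim_acq_bleach <- function(st) {
  p <- st$detector$acq_bleach
  if (p <= 0 || st$n == 0) return(invisible(st))
  use_stream(st, "bleach", {
    st$fluor <- st$fluor & (runif(st$n) >= p)
  })
  invisible(st)
}

# Advance to each absolute time in record_times (snapped to the dt grid) and
# record particle positions, fluorescence flags and droplet geometry.
sim_record <- function(st, record_times) {
  nt <- length(record_times)
  xs <- matrix(NA_real_, st$n, nt)
  ys <- matrix(NA_real_, st$n, nt)
  fl <- matrix(NA, st$n, nt)
  drows <- vector("list", nt)
  for (k in seq_len(nt)) {
    n_steps <- max(0L, round((record_times[k] - st$time) / st$dt))
    for (s in seq_len(n_steps)) sim_step(st)
    if (st$n > 0) {
      pos <- apply_boundary_events(st, st$x, st$y, st$time)
      xs[, k] <- pos$x; ys[, k] <- pos$y; fl[, k] <- st$fluor
    }
    drops <- st$droplet_fn(st$time)
    drows[[k]] <- data.frame(
      frame = k, id = seq_along(drops),
      x = vapply(drops, function(d) d$center[1], 0),
      y = vapply(drops, function(d) d$center[2], 0),
      radius = vapply(drops, function(d) d$radius, 0)
    )
    sim_acq_bleach(st)
  }
  list(x = xs, y = ys, fluor = fl, droplets = do.call(rbind, drows))
}

# Render recorded particle positions into photon-count frames: separable
# pixel-integrated Gaussian PSF per particle, uniform background, optional
# Poisson shot noise. Positions in um; output H x W x T counts.
render_frames <- function(st, rec) {
  acq <- st$acq; det <- st$detector
  h <- acq$frame_shape[1]; w <- acq$frame_shape[2]
  nt <- ncol(rec$x) %||% 0
  if (is.null(nt) || is.na(nt)) nt <- 0
  frames <- array(0, c(h, w, nt))
  sig <- det$psf_sigma / acq$pixel_size
  by <- 0:h; bx <- 0:w
  use_stream(st, "detection", {
    for (t in seq_len(nt)) {
      lam <- matrix(det$background, h, w)
      sel <- which(rec$fluor[, t])
      if (length(sel)) {
        px <- rec$x[sel, t] / acq$pixel_size
        py <- rec$y[sel, t] / acq$pixel_size
        pyb <- pnorm(outer(by, py, "-") / sig)   # (h+1) x n
        pxb <- pnorm(outer(bx, px, "-") / sig)   # (w+1) x n
        wy <- pyb[-1, , drop = FALSE] - pyb[-(h + 1), , drop = FALSE]
        wx <- pxb[-1, , drop = FALSE] - pxb[-(w + 1), , drop = FALSE]
        lam <- lam + det$brightness * (wy %*% t(wx))
      }
      if (det$noise == "poisson") {
        frames[, , t] <- matrix(rpois(h * w, lam), h, w)
      } else {
        frames[, , t] <- lam
      }
    }
  })
  frames
}

new_ground_truth <- function(st, rec, timestamps, extra = list(),
                             record_trajectories = TRUE) {
  gt <- c(list(
    droplets = rec$droplets,
    n_particles = st$n,
    immobile_fraction = st$immobile_fraction,
    immobile = st$immobile,
    fluorescent = rec$fluor,
    bleach_events = if (length(st$bleach_events)) {
      do.call(rbind, st$bleach_events)
    } else {
      data.frame(frame_index = integer(0), roi = character(0),
                 bleach_probability = numeric(0))
    },
    timestamps = timestamps,
    preset = st$preset$name,
    boundary_mobility_factor = st$factor,
    seed = st$seed
  ), extra)
  if (record_trajectories && st$n > 0) {
    gt$trajectories <- list(x = rec$x, y = rec$y)
  }
  structure(gt, class = "nb_ground_truth")
}

#' @export
print.nb_ground_truth <- function(x, ...) {
  cat(sprintf("<nb_ground_truth> %d particles (immobile fraction %.2f), %d frames, preset '%s'\n",
              x$n_particles, x$immobile_fraction, length(x$timestamps), x$preset))
  invisible(x)
}
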