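## Synthetic live-cell branch: cell geometry, nucleation events, and
## rendering of calibrated 4D stacks with ground truth.

#' Simulate cell geometry (mask outline, boundary, centroid per frame)
#'
#' The simulated cell is a disk of radius `cell_radius` centred in the field
#' of view, optionally drifting rigidly at `drift_velocity_um_s`.  The
#' boundary is returned as a dense point set (arc-length step ~0.25 px) in
#' micrometres, one per frame, together with the per-frame centroid.
#'
#' @param config A [simulation_config].
#' @return A `cell_geometry` object: `n_t`, `centroid` (t x 2 matrix, um),
#'   `boundary` (list of t matrices with columns x, y in um), `radius_um`,
#'   `pixel_size_xy`.
#' @export
simulate_cell <- function(config) {
  validate_simulation_config(config)
  c0 <- c(config$n_x, config$n_y) * config$pixel_size_xy / 2
  # start the cell so that the drift keeps it centred on average
  total_drift <- config$drift_velocity_um_s * (config$n_t - 1L) *
    config$frame_interval
  start <- c0 - total_drift / 2
  tt <- (seq_len(config$n_t) - 1L) * config$frame_interval
  centroid <- cbind(x = start[1L] + config$drift_velocity_um_s[1L] * tt,
                    y = start[2L] + config$drift_velocity_um_s[2L] * tt)
  n_pts <- max(64L, ceiling(2 * pi * config$cell_radius /
                              (0.25 * config$pixel_size_xy)))
  theta <- seq(0, 2 * pi, length.out = n_pts + 1L)[-(n_pts + 1L)]
  ring <- cbind(x = config$cell_radius * cos(theta),
                y = config$cell_radius * sin(theta))
  boundary <- lapply(seq_len(config$n_t), function(i)
    sweep(ring, 2L, centroid[i, ], "+"))
  structure(list(n_t = config$n_t, centroid = centroid, boundary = boundary,
                 radius_um = config$cell_radius,
                 pixel_size_xy = config$pixel_size_xy),
            class = "cell_geometry")
}

# sample n radii uniformly by area from the annulus [r_in, r_out]
.sample_annulus_radius <- function(n, r_in, r_out) {
  sqrt(runif(n, r_in^2, r_out^2))
}

#' Simulate punctum nucleation events with ground-truth labels
#'
#' After a stimulus-dependent `formation_delay`, puncta nucleate as a
#' homogeneous Poisson process at `nucleation_rate`.  A fraction
#' `membrane_fraction` of events is placed in the membrane band (distance to
#' the cell boundary at birth <= `membrane_threshold_um`), the rest in the
#' interior.  Lifetimes are drawn from the two-step degradation model via
#' [simulate_lifetimes()]'s construction.  Events co-move rigidly with the
#' cell; with `diffusion_coefficient > 0` they additionally perform a 2D
#' random walk.
#'
#' @param config A [simulation_config].
#' @param geometry A `cell_geometry` from [simulate_cell()].
#' @return A `ground_truth_events` object: `events` (data.frame with
#'   event_id, birth_s, death_s, lifetime_s, x_um, y_um, z_um, compartment)
#'   and `positions` (list of per-event data.frames: frame, t_s, x_um, y_um,
#'   z_um for every frame the event is alive).
#' @export
simulate_events <- function(config, geometry) {
  validate_simulation_config(config)
  stopifnot(inherits(geometry, "cell_geometry"))
  t_end <- (config$n_t - 1L) * config$frame_interval
  dur <- max(0, t_end - config$formation_delay)
  z_extent <- config$n_z * config$z_spacing
  band <- min(config$membrane_threshold_um, config$cell_radius)

  withr::with_seed(config$rng_seed + 1L, {
    n_ev <- rpois(1L, config$nucleation_rate * dur)
    if (n_ev == 0L) {
      return(structure(list(events = data.frame(
        event_id = integer(), birth_s = numeric(), death_s = numeric(),
        lifetime_s = numeric(), x_um = numeric(), y_um = numeric(),
        z_um = numeric(), compartment = character()),
        positions = list()), class = "ground_truth_events"))
    }
    birth <- sort(config$formation_delay + runif(n_ev, 0, dur))
    tau <- rexp(n_ev, config$k1) + rexp(n_ev, config$k2)
    membrane <- runif(n_ev) < config$membrane_fraction
    r <- numeric(n_ev)
    r[membrane] <- .sample_annulus_radius(sum(membrane),
                                          config$cell_radius - band,
                                          config$cell_radius)
    r[!membrane] <- .sample_annulus_radius(sum(!membrane), 0,
                                           max(config$cell_radius - band, 0))
    phi <- runif(n_ev, 0, 2 * pi)
    off <- cbind(r * cos(phi), r * sin(phi))    # offset from cell centroid
    z <- runif(n_ev, 0.3 * z_extent, 0.7 * z_extent)

    frame_time <- (seq_len(config$n_t) - 1L) * config$frame_interval
    positions <- vector("list", n_ev)
    x0 <- y0 <- numeric(n_ev)
    for (i in seq_len(n_ev)) {
      alive <- which(frame_time >= birth[i] & frame_time < birth[i] + tau[i])
      ctr <- geometry$centroid[alive, , drop = FALSE]
      nf <- length(alive)
      dx <- dy <- rep(0, nf)
      if (config$diffusion_coefficient > 0 && nf > 1L) {
        step_sd <- sqrt(2 * config$diffusion_coefficient *
                          config$frame_interval)
        dx <- cumsum(c(0, rnorm(nf - 1L, 0, step_sd)))
        dy <- cumsum(c(0, rnorm(nf - 1L, 0, step_sd)))
      }
      positions[[i]] <- data.frame(
        frame = alive - 1L, t_s = frame_time[alive],
        x_um = ctr[, 1L] + off[i, 1L] + dx,
        y_um = ctr[, 2L] + off[i, 2L] + dy,
        z_um = rep(z[i], nf))
      # birth-time absolute position (centroid interpolated at birth)
      ctr_b <- geometry$centroid[min(which(frame_time >= birth[i]),
                                     config$n_t), , drop = TRUE]
      x0[i] <- ctr_b[1L] + off[i, 1L]
      y0[i] <- ctr_b[2L] + off[i, 2L]
    }
    events <- data.frame(event_id = seq_len(n_ev), birth_s = birth,
                         death_s = birth + tau, lifetime_s = tau,
                         x_um = x0, y_um = y0, z_um = z,
                         compartment = ifelse(membrane, "membrane",
                                              "cytoplasm"))
    structure(list(events = events, positions = positions),
              class = "ground_truth_events")
  })
}

#' Render a calibrated 4D stack from simulated events
#'
#' Each live punctum is rendered as a 3D Gaussian of widths
#' `psf_sigma_xy` / `psf_sigma_z` and peak expectation `photon_amplitude`
#' on top of a uniform `background_level` plus `cell_intensity` inside the
#' cell mask.  Pixel values are Poisson draws of the photon expectation plus
#' Gaussian read noise, rounded and clamped to the 16-bit range.
#'
#' @param events A `ground_truth_events` from [simulate_events()].
#' @param geometry A `cell_geometry` from [simulate_cell()].
#' @param config A [simulation_config].
#' @param noise Apply Poisson shot noise and read noise?  `FALSE` returns
#'   the noise-free photon expectation (rounded).
#' @return An [image_stack4d] with the rendered intensities.
#' @export
render_stack <- function(events, geometry, config, noise = TRUE) {
  validate_simulation_config(config)
  if (config$photon_amplitude <= 0) stop("photon_amplitude must be > 0")
  psz <- config$pixel_size_xy
  sx <- config$psf_sigma_xy / psz          # px
  sz <- config$psf_sigma_z / config$z_spacing  # slices
  wx <- ceiling(4 * sx); wz <- ceiling(4 * sz)
  # pixel/slice centre coordinates (um)
  xc <- (seq_len(config$n_x) - 0.5) * psz
  yc <- (seq_len(config$n_y) - 0.5) * psz
  zc <- (seq_len(config$n_z) - 0.5) * config$z_spacing

  # per-frame list of punctum positions
  per_frame <- vector("list", config$n_t)
  for (p in events$positions) {
    for (j in seq_len(nrow(p))) {
      f <- p$frame[j] + 1L
      per_frame[[f]] <- rbind(per_frame[[f]],
                              c(p$x_um[j], p$y_um[j], p$z_um[j]))
    }
  }

  stack <- array(0L, dim = c(config$n_y, config$n_x, config$n_z, config$n_t))
  withr::with_seed(config$rng_seed + 2L, {
    for (f in seq_len(config$n_t)) {
      lam <- array(config$background_level,
                   dim = c(config$n_y, config$n_x, config$n_z))
      # diffuse cell body fluorescence
      if (config$cell_intensity > 0) {
        ctr <- geometry$centroid[f, ]
        inside <- outer((yc - ctr[2L])^2, (xc - ctr[1L])^2, "+") <=
          geometry$radius_um^2
        lam <- lam + config$cell_intensity *
          array(inside, dim = dim(lam))
      }
      pts <- per_frame[[f]]
      if (!is.null(pts)) {
        for (j in seq_len(nrow(pts))) {
          cx <- pts[j, 1L] / psz + 0.5   # px index of centre
          cy <- pts[j, 2L] / psz + 0.5
          cz <- pts[j, 3L] / config$z_spacing + 0.5
          ix <- max(1L, floor(cx - wx)):min(config$n_x, ceiling(cx + wx))
          iy <- max(1L, floor(cy - wx)):min(config$n_y, ceiling(cy + wx))
          iz <- max(1L, floor(cz - wz)):min(config$n_z, ceiling(cz + wz))
          gx <- exp(-((ix - cx)^2) / (2 * sx^2))
          gy <- exp(-((iy - cy)^2) / (2 * sx^2))
          gz <- exp(-((iz - cz)^2) / (2 * sz^2))
          g <- config$photon_amplitude *
            (gy %o% gx %o% gz)
          lam[iy, ix, iz] <- lam[iy, ix, iz] + g
        }
      }
      if (noise) {
        v <- rpois(length(lam), lam) +
          rnorm(length(lam), 0, config$read_noise_sigma)
      } else {
        v <- lam
      }
      stack[, , , f] <- as.integer(pmin(pmax(round(v), 0), 65535))
    }
  })
  image_stack4d(stack, pixel_size_xy = psz, z_spacing = config$z_spacing,
                frame_interval = config$frame_interval)
}

#' Simulate a complete live-cell dataset
#'
#' Convenience wrapper chaining [simulate_cell()], [simulate_events()] and
#' [render_stack()].
#'
#' @param config A [simulation_config].
#' @param noise Passed to [render_stack()].
#' @return List with `stack` ([image_stack4d]), `events`
#'   (`ground_truth_events`), `geometry` (`cell_geometry`), `config`.
#' @export
simulate_dataset <- function(config, noise = TRUE) {
  geometry <- simulate_cell(config)
  events <- simulate_events(config, geometry)
  stack <- render_stack(events, geometry, config, noise = noise)
  list(stack = stack, events = events, geometry = geometry, config = config)
}

#' Write a simulated dataset to disk
#'
#' Writes the stack as a multi-page 16-bit TIFF (pages in t-major, z-minor
#' order), the ground truth as CSV (one row per event), and the
#' configuration as JSON.
#'
#' @param dataset From [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`stack`, `events`, `config`).
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(stack = file.path(dir, "stack.tif"),
                events = file.path(dir, "ground_truth.csv"),
                config = file.path(dir, "config.json"))
  write_stack(dataset$stack, paths$stack)
  ev <- dataset$events$events
  out <- data.frame(id = ev$event_id, birth_s = ev$birth_s,
                    death_s = ev$death_s, x_um = ev$x_um, y_um = ev$y_um,
                    z_um = ev$z_um, compartment = ev$compartment)
  write.csv(out, paths$events, row.names = FALSE)
  write_config(dataset$config, paths$config)
  invisible(paths)
}
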