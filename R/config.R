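## Simulation and pipeline configuration.
##
## Analysis-stage defaults follow the tracking protocol the package
## implements: rolling ball radius 80 px, 3D blur sigma 1 px, maxima
## prominence 20 counts, search range 8 px (0.85 um at 0.10625 um/px),
## memory 6 frames, minimum track length 2 frames, membrane threshold
## 1.4 um, frame interval 10 s, z spacing 0.2 um.

#' Analysis defaults for the live-cell tracking pipeline
#'
#' Returns the canonical parameter set of the tracking protocol as a named
#' list.  Every stage function takes these values as its defaults; this
#' accessor exists so that configurations and tests have one authoritative
#' source.
#'
#' @return Named list: `ball_radius_px` (80), `blur_sigma_px` (1),
#'   `prominence` (20), `search_range_px` (8), `memory_frames` (6),
#'   `min_track_frames` (2), `membrane_threshold_um` (1.4),
#'   `frame_interval_s` (10), `z_spacing_um` (0.2),
#'   `pixel_size_um` (0.10625).
#' @export
pipeline_defaults <- function() {
  list(ball_radius_px = 80,
       blur_sigma_px = 1,
       prominence = 20,
       search_range_px = 8,
       memory_frames = 6,
       min_track_frames = 2,
       membrane_threshold_um = 1.4,
       frame_interval_s = 10,
       z_spacing_um = 0.2,
       pixel_size_um = 0.10625)
}

#' Configuration for the synthetic 4D stack generator
#'
#' Bundles every parameter of the live-cell simulation.  Acquisition
#' defaults mirror the imaging protocol (10 s frame interval, 0.2 um z
#' spacing, 0.10625 um pixels); kinetic parameters default to rates of the
#' order reported for Myddosome turnover.  The field of view and duration
#' are free choices; the defaults give a compact stack that still resolves
#' the kinetics.
#'
#' @param n_t,n_z,n_y,n_x Stack dimensions (frames, z-slices, rows, cols).
#' @param pixel_size_xy Lateral pixel size, um/px.
#' @param z_spacing Axial slice spacing, um.
#' @param frame_interval Time between consecutive z-stacks, s.
#' @param cell_radius Radius of the simulated adherent cell, um.
#' @param nucleation_rate Punctum nucleation rate after the delay, events/s.
#' @param formation_delay Delay between stimulus (t = 0) and the onset of
#'   nucleation, s.
#' @param k1,k2 Two-step degradation rate constants, 1/s.
#' @param membrane_fraction Fraction of events nucleating within the
#'   membrane band (distance to boundary <= `membrane_threshold_um`).
#' @param membrane_threshold_um Width of the membrane band, um.
#' @param psf_sigma_xy,psf_sigma_z Gaussian PSF widths, um.
#' @param photon_amplitude Peak photon expectation of one punctum, counts.
#' @param background_level Uniform background photon expectation, counts.
#' @param cell_intensity Additional photon expectation inside the cell (the
#'   diffuse cytosolic fluorophore pool), counts; gives the segmentation
#'   stage a cell body to find.
#' @param read_noise_sigma Gaussian read noise s.d., counts.
#' @param drift_velocity_um_s Rigid cell drift velocity `c(vx, vy)`, um/s.
#' @param diffusion_coefficient Punctum diffusion coefficient, um^2/s
#'   (0 = static puncta).
#' @param rng_seed Integer seed; identical config implies bit-identical
#'   simulated output.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_t = 180, n_z = 100, n_y = 160, n_x = 160,
                              pixel_size_xy = 0.10625,
                              z_spacing = 0.2,
                              frame_interval = 10,
                              cell_radius = 7,
                              nucleation_rate = 0.02,
                              formation_delay = 100,
                              k1 = 0.005, k2 = 0.02,
                              membrane_fraction = 0.9,
                              membrane_threshold_um = 1.4,
                              psf_sigma_xy = 0.15,
                              psf_sigma_z = 0.4,
                              photon_amplitude = 50,
                              background_level = 100,
                              cell_intensity = 10,
                              read_noise_sigma = 2,
                              drift_velocity_um_s = c(0, 0),
                              diffusion_coefficient = 0,
                              rng_seed = 1) {
  cfg <- list(n_t = as.integer(n_t), n_z = as.integer(n_z),
              n_y = as.integer(n_y), n_x = as.integer(n_x),
              pixel_size_xy = pixel_size_xy, z_spacing = z_spacing,
              frame_interval = frame_interval, cell_radius = cell_radius,
              nucleation_rate = nucleation_rate,
              formation_delay = formation_delay,
              k1 = k1, k2 = k2,
              membrane_fraction = membrane_fraction,
              membrane_threshold_um = membrane_threshold_um,
              psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
              photon_amplitude = photon_amplitude,
              background_level = background_level,
              cell_intensity = cell_intensity,
              read_noise_sigma = read_noise_sigma,
              drift_velocity_um_s = as.numeric(drift_velocity_um_s),
              diffusion_coefficient = diffusion_coefficient,
              rng_seed = as.integer(rng_seed))
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (any(c(n_t, n_z, n_y, n_x) < 1)) stop("all stack dimensions must be >= 1")
    pos <- c(pixel_size_xy = pixel_size_xy, z_spacing = z_spacing,
             frame_interval = frame_interval, cell_radius = cell_radius,
             nucleation_rate = nucleation_rate, k1 = k1, k2 = k2,
             membrane_threshold_um = membrane_threshold_um,
             psf_sigma_xy = psf_sigma_xy, psf_sigma_z = psf_sigma_z,
             photon_amplitude = photon_amplitude)
    bad <- names(pos)[!is.finite(pos) | pos <= 0]
    if (length(bad)) stop("strictly positive values required for: ",
                          paste(bad, collapse = ", "))
    if (formation_delay < 0) stop("formation_delay must be >= 0")
    if (membrane_fraction < 0 || membrane_fraction > 1)
      stop("membrane_fraction must lie in [0, 1]")
    if (background_level < 0 || read_noise_sigma < 0 || cell_intensity < 0)
      stop("noise/background levels must be non-negative")
    if (length(drift_velocity_um_s) != 2L)
      stop("drift_velocity_um_s must be a length-2 (vx, vy) vector")
    if (diffusion_coefficient < 0) stop("diffusion_coefficient must be >= 0")
    fov_x <- n_x * pixel_size_xy; fov_y <- n_y * pixel_size_xy
    drift_x <- abs(drift_velocity_um_s[1L]) * (n_t - 1L) * frame_interval
    drift_y <- abs(drift_velocity_um_s[2L]) * (n_t - 1L) * frame_interval
    if (2 * cell_radius + drift_x >= fov_x || 2 * cell_radius + drift_y >= fov_y)
      stop("cell (including drift) does not fit inside the field of view")
  })
  invisible(cfg)
}

#' Write / read a simulation or pipeline configuration as JSON
#'
#' Configurations round-trip losslessly; unknown keys in a file are an
#' error, which catches typos in parameter names.
#'
#' @param config A `simulation_config`.
#' @param path File path.
#' @return `read_config` returns the validated `simulation_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(simulation_config))
  known <- sub("^n_t$", "n_t", known)
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(simulation_config, raw)
}
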