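## End-to-end pipelines chaining the stages, with provenance manifests and
## deterministic tabular outputs.

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

.manifest <- function(output_dir, inputs, params, seed, counts) {
  list(package = "punctatrack",
       version = as.character(utils::packageVersion("punctatrack")),
       seed = seed,
       parameters = params,
       input_checksums = inputs,
       stage_counts = counts)
}

#' Run the live-cell tracking pipeline
#'
#' Chains: load stack, rolling-ball background subtraction (per z-slice),
#' 3D Gaussian blur, brightest-point projection, maxima detection, linking
#' with gap closing, pre-formed exclusion, cell segmentation on the raw
#' projection, drift correction, membrane/cytoplasm classification,
#' first-formation time, compartment counts over time and a two-step
#' lifetime fit on the membrane-initiated tracks.  All tabular outputs are
#' deterministic for a fixed input, parameter set and seed.
#'
#' @param input An [image_stack4d], a dataset list from
#'   [simulate_dataset()], or a path to a multi-page TIFF (with sidecar
#'   `config.json` or explicit calibration in `load_args`).
#' @param output_dir Directory for outputs; `NULL` skips writing.
#' @param params Parameter list as from [pipeline_defaults()]; entries can
#'   be overridden individually.
#' @param n_cells Cell count used to normalise the compartment counts.
#' @param fit_min_tracks Minimum number of usable lifetimes before a model
#'   fit is attempted.
#' @param n_boot Bootstrap resamples for the lifetime-fit confidence
#'   intervals.
#' @param seed Seed for the bootstrap.
#' @param load_args Extra arguments for [load_stack()] when `input` is a
#'   path.
#' @return A result bundle (list): `trajectories` (annotated
#'   `trajectory_set`), `geometry`, `first_formation_s`, `lifetimes`,
#'   `fit` (or `NULL`), `counts`, `stage_counts`, `outputs` (paths or
#'   `NULL`).
#' @export
run_live_pipeline <- function(input, output_dir = NULL,
                              params = pipeline_defaults(), n_cells = 1,
                              fit_min_tracks = 10, n_boot = 0, seed = 1,
                              load_args = list()) {
  p <- utils::modifyList(pipeline_defaults(), params)
  input_sums <- list()
  if (is.character(input)) {
    input_sums <- as.list(tools::md5sum(input))
    stack <- do.call(load_stack, c(list(input), load_args))
  } else if (inherits(input, "image_stack4d")) {
    stack <- input
  } else if (is.list(input) && inherits(input$stack, "image_stack4d")) {
    stack <- input$stack
  } else stop("input must be a stack, a simulated dataset, or a TIFF path")

  # segmentation uses the raw projection (the diffuse cell signal is the
  # foreground); detection uses the filtered projection
  geometry <- segment_cell(stack)
  filtered <- blur_3d(subtract_background(stack, p$ball_radius_px),
                      p$blur_sigma_px)
  proj <- project_brightest(filtered)

  n_t <- dim(proj)[3L]
  det_list <- vector("list", n_t)
  for (f in seq_len(n_t)) {
    d <- detect_puncta(proj[, , f], prominence = p$prominence)
    if (nrow(d)) d$frame <- f - 1L
    det_list[[f]] <- d
  }
  puncta <- do.call(rbind, det_list[vapply(det_list, nrow, 1L) > 0])
  if (is.null(puncta))
    puncta <- data.frame(frame = integer(), x_px = numeric(),
                         y_px = numeric(), peak = numeric())

  traj <- link_trajectories(puncta, search_range = p$search_range_px,
                            memory = p$memory_frames,
                            min_length = p$min_track_frames,
                            frame_interval = stack$frame_interval,
                            pixel_size_um = stack$pixel_size_xy)
  n_linked <- nrow(traj$tracks)
  traj <- filter_preformed(traj)
  n_postformed <- nrow(traj$tracks)
  traj <- correct_drift(traj, geometry)
  traj <- annotate_compartments(traj, geometry,
                                threshold = p$membrane_threshold_um)
  mem <- filter_membrane_initiated(traj)
  n_membrane <- nrow(mem$tracks)

  first_s <- if (n_postformed > 0) {
    first_formation_time(traj)
  } else {
    warning("no formation observed")
    NA_real_
  }
  counts <- counts_over_time(traj, geometry, n_cells = n_cells)
  # flag right-censored tracks (alive in the last frame); they stay in the
  # lifetime sample uncorrected but their count is reported
  censored <- mem$tracks$last_frame == n_t - 1L
  lifetimes <- mem$tracks$lifetime_s
  fit <- NULL
  if (length(lifetimes) >= fit_min_tracks)
    fit <- fit_two_step(lifetimes, n_boot = n_boot, seed = seed)

  stage_counts <- list(detections = nrow(puncta), tracks_linked = n_linked,
                       tracks_after_preformed_filter = n_postformed,
                       tracks_membrane_initiated = n_membrane,
                       tracks_censored_at_end = sum(censored))

  outputs <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    outputs <- list(
      trajectories = file.path(output_dir, "trajectories.csv"),
      tracks = file.path(output_dir, "tracks.csv"),
      counts = file.path(output_dir, "counts.csv"),
      results = file.path(output_dir, "results.json"),
      manifest = file.path(output_dir, "manifest.json"))
    write.csv(traj$points, outputs$trajectories, row.names = FALSE)
    tr <- traj$tracks
    tr$censored <- tr$last_frame == n_t - 1L
    write.csv(tr, outputs$tracks, row.names = FALSE)
    write.csv(counts, outputs$counts, row.names = FALSE)
    res <- list(first_formation_s = if (is.na(first_s))
      "no formation observed" else first_s,
      n_lifetimes = length(lifetimes))
    if (!is.null(fit)) {
      res$lifetime_fit <- list(k1 = fit$model$k1, k2 = fit$model$k2,
                               tau_mean_s = fit$tau_mean,
                               method = fit$method, n = fit$n,
                               degenerate = fit$degenerate)
    }
    .write_json(res, outputs$results)
    .write_json(.manifest(output_dir, input_sums, p, seed, stage_counts),
                outputs$manifest)
  }
  invisible(list(trajectories = traj, membrane_initiated = mem,
                 geometry = geometry, first_formation_s = first_s,
                 lifetimes = lifetimes, fit = fit, counts = counts,
                 stage_counts = stage_counts, outputs = outputs))
}

#' Run the fixed-cell morphometry pipeline
#'
#' For each cluster mask: area, sub-pixel perimeter and shape factor; the
#' colocalisation flag from the reference channel (clusters whose centroid
#' falls outside every reference ROI are excluded from the statistics); and
#' optionally FWHM/diameter from a 1D Gaussian fit through the centroid of
#' a matching intensity image.
#'
#' @param clusters A `cluster_set`, or a list of binary mask matrices.
#' @param reference_image Optional reference-channel image (same canvas
#'   coordinates as the cluster centroids); `NULL` treats every cluster as
#'   colocalised.
#' @param intensity_images Optional list of per-cluster intensity images
#'   (same grids as the masks) used for FWHM sizing.
#' @param pixel_size_nm Pixel size; taken from the `cluster_set` if absent.
#' @param condition,timepoint Metadata labels (recycled).
#' @param spherical_tolerance Tolerance for [spherical_fraction()] on these
#'   rasterised masks (default 0.05).
#' @param output_dir Directory for outputs; `NULL` skips writing.
#' @return List: `morphometry` (data.frame), `spherical_fraction`,
#'   `size_summary` (when FWHM available), `outputs`.
#' @export
run_fixed_pipeline <- function(clusters, reference_image = NULL,
                               intensity_images = NULL, pixel_size_nm = NULL,
                               condition = "unspecified", timepoint = "0",
                               spherical_tolerance = 0.05,
                               output_dir = NULL) {
  if (inherits(clusters, "cluster_set")) {
    masks <- clusters$masks
    if (is.null(pixel_size_nm)) pixel_size_nm <- clusters$pixel_size_nm
    centroids <- clusters$truth[, c("y_px", "x_px")]
  } else {
    masks <- clusters
    if (is.null(pixel_size_nm)) stop("pixel_size_nm required")
    centroids <- do.call(rbind, lapply(masks, function(m) {
      idx <- which(m > 0, arr.ind = TRUE)
      data.frame(y_px = mean(idx[, 1L]), x_px = mean(idx[, 2L]))
    }))
  }
  n <- length(masks)
  if (n == 0L) {
    warning("empty cluster set: no morphometry computed")
    morph <- data.frame(cluster_id = integer(), area_um2 = numeric(),
                        perimeter_um = numeric(), shape_factor = numeric(),
                        fwhm_nm = numeric(), diameter_nm = numeric(),
                        colocalised = logical(), condition = character(),
                        timepoint = character())
    return(list(morphometry = morph, spherical_fraction = NA_real_,
                size_summary = NULL, outputs = NULL))
  }
  coloc <- rep(TRUE, n)
  if (!is.null(reference_image)) {
    rois <- threshold_reference_rois(reference_image)
    coloc <- colocalise_clusters(centroids, rois)
  }
  condition <- rep_len(condition, n)
  timepoint <- rep_len(as.character(timepoint), n)

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sf <- shape_factor(masks[[i]], pixel_size = pixel_size_nm)
    fw <- NA_real_
    if (!is.null(intensity_images)) {
      img <- intensity_images[[i]]
      idx <- which(masks[[i]] > 0, arr.ind = TRUE)
      crow <- round(sum(idx[, 1L] * img[idx]) / sum(img[idx]))
      prof <- img[crow, ]
      fw <- tryCatch(fit_fwhm(prof, pixel_size = pixel_size_nm)$fwhm,
                     error = function(e) NA_real_)
    }
    rows[[i]] <- data.frame(
      cluster_id = i,
      area_um2 = sf$area * 1e-6,        # nm^2 -> um^2
      perimeter_um = sf$perimeter * 1e-3,
      shape_factor = sf$shape_factor,
      fwhm_nm = fw,
      diameter_nm = if (is.na(fw)) NA_real_ else fwhm_to_diameter(fw),
      colocalised = coloc[i],
      condition = condition[i], timepoint = timepoint[i])
  }
  morph <- do.call(rbind, rows)
  used <- morph[morph$colocalised, , drop = FALSE]
  sph <- if (nrow(used)) spherical_fraction(used$shape_factor,
                                            tolerance = spherical_tolerance)
  else NA_real_
  size_summary <- NULL
  if (any(!is.na(used$fwhm_nm)) && nrow(used) > 0)
    size_summary <- size_by_timepoint(used[!is.na(used$fwhm_nm), ,
                                           drop = FALSE])

  outputs <- NULL
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    outputs <- list(morphometry = file.path(output_dir, "morphometry.csv"),
                    summary = file.path(output_dir, "morphometry_summary.json"))
    write.csv(morph, outputs$morphometry, row.names = FALSE)
    summ <- list(n_clusters = n, n_colocalised = sum(coloc),
                 spherical_fraction = sph,
                 spherical_tolerance = spherical_tolerance)
    if (!is.null(size_summary)) {
      summ$size_by_timepoint <- size_summary$summary
      summ$size_tests <- size_summary$tests
    }
    .write_json(summ, outputs$summary)
  }
  list(morphometry = morph, spherical_fraction = sph,
       size_summary = size_summary, outputs = outputs)
}
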