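# Cell segmentation, drift correction, boundary distances and
# membrane/cytoplasm classification.

seg_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_t = 8, n_z = 8, n_y = 96, n_x = 96, cell_radius = 4,
         nucleation_rate = 1e-9, formation_delay = 0, rng_seed = 31),
    list(...))
  do.call(simulation_config, args)
}

test_that("segmentation recovers the synthetic disk", {
  cfg <- seg_cfg()
  ds <- simulate_dataset(cfg)
  geo <- segment_cell(ds$stack)
  true_c <- ds$geometry$centroid[1, ]
  expect_lt(max(abs(geo$centroid[1, ] - true_c)), 0.2)
  area_um2 <- sum(geo$masks[, , 1]) * cfg$pixel_size_xy^2
  expect_lt(abs(area_um2 - pi * 16) / (pi * 16), 0.05)
  expect_error(segment_cell(matrix(5, 64, 64), pixel_size_um = 0.1),
               "no foreground")
})

test_that("with two bright blobs the larger one is segmented", {
  img <- matrix(0, 96, 96)
  ys <- seq_len(96)
  img <- img + 50 * (outer((ys - 30)^2, (ys - 30)^2, "+") <= 20^2)
  img <- img + 50 * (outer((ys - 75)^2, (ys - 75)^2, "+") <= 8^2)
  geo <- segment_cell(img, pixel_size_um = 0.1)
  expect_lt(max(abs(geo$centroid[1, ] - c(2.95, 2.95))), 0.3)
  expect_lt(abs(sum(geo$masks[, , 1]) - pi * 400) / (pi * 400), 0.1)
})

test_that("boundary distances match the analytic disk geometry", {
  cfg <- seg_cfg()
  geo <- simulate_cell(cfg)
  ctr <- unname(geo$centroid[1, ])
  # centre of the disk: distance = radius, within half a pixel
  expect_lt(abs(boundary_distance(ctr[1], ctr[2], geo, 0) - 4),
            cfg$pixel_size_xy / 2)
  # a boundary point: distance ~ 0
  b <- geo$boundary[[1]][1, ]
  expect_lt(boundary_distance(b[1], b[2], geo, 0), cfg$pixel_size_xy / 2)
  # random interior points: distance = radius - |p - centre|
  pts <- withr::with_seed(8, {
    r <- sqrt(runif(100)) * 3.9; a <- runif(100, 0, 2 * pi)
    cbind(ctr[1] + r * cos(a), ctr[2] + r * sin(a))
  })
  d <- boundary_distance(pts[, 1], pts[, 2], geo, 0)
  d_true <- 4 - sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  expect_lt(max(abs(d - d_true)), cfg$pixel_size_xy)
  # rigid translation of point and geometry together leaves distances alone
  geo2 <- geo
  geo2$boundary <- lapply(geo$boundary, function(b) sweep(b, 2, c(1.3, -0.7), "+"))
  geo2$centroid <- sweep(geo$centroid, 2, c(1.3, -0.7), "+")
  d2 <- boundary_distance(pts[, 1] + 1.3, pts[, 2] - 0.7, geo2, 0)
  expect_equal(d2, d, tolerance = 1e-12)
  expect_error(boundary_distance(1, 1, geo, frame = 99), "missing frame")
})

test_that("drift correction brings co-moving puncta to rest", {
  cfg <- seg_cfg(n_t = 20, drift_velocity_um_s = c(0.01, 0))
  geo <- simulate_cell(cfg)
  # punctum fixed at +1 um from the centroid in x, co-moving with the cell
  pts <- data.frame(track_id = 1L, frame = 0:19, t_s = (0:19) * 10,
                    x_px = NA, y_px = NA,
                    x_um = geo$centroid[, 1] + 1,
                    y_um = geo$centroid[, 2], peak = 1)
  tr <- structure(list(points = pts,
                       tracks = data.frame(track_id = 1L, first_frame = 0L,
                                           last_frame = 19L, n_points = 20L,
                                           start_s = 0, lifetime_s = 200,
                                           preformed = TRUE),
                       frame_interval = 10, pixel_size_um = 0.10625),
                  class = "trajectory_set")
  cor <- correct_drift(tr, geo)
  expect_equal(max(abs(diff(cor$points$x_rel_um))), 0)
  expect_equal(max(abs(diff(cor$points$y_rel_um))), 0)
  # static cell: relative coordinates are absolute minus a constant
  geos <- simulate_cell(seg_cfg(n_t = 20))
  cors <- correct_drift(tr, geos)
  expect_equal(cors$points$x_rel_um, cors$points$x_um - geos$centroid[1, 1])
  # full loop: drifting cell segmented from rendered frames, static puncta
  # in the cell frame show sub-pixel RMS displacement after correction
  ds <- simulate_dataset(seg_cfg(n_t = 20, nucleation_rate = 0.05,
                                 k1 = 0.001, k2 = 0.002,
                                 photon_amplitude = 100,
                                 background_level = 50,
                                 drift_velocity_um_s = c(0.01, 0),
                                 rng_seed = 77))
  res <- run_live_pipeline(ds)
  p <- res$trajectories$points
  rms <- vapply(split(p, p$track_id), function(g)
    sqrt(mean((g$x_rel_um - mean(g$x_rel_um))^2 +
                (g$y_rel_um - mean(g$y_rel_um))^2)), numeric(1))
  expect_true(all(rms < 0.10625))
})

test_that("compartment classification uses the inclusive 1.4 um threshold", {
  expect_equal(classify_compartment(0.5), "membrane")
  expect_equal(classify_compartment(2.0), "cytoplasm")
  expect_equal(classify_compartment(1.4), "membrane")
  expect_equal(classify_compartment(c(0, 1.41)),
               c("membrane", "cytoplasm"))
  expect_error(classify_compartment(-0.1), "negative")
  expect_error(classify_compartment(1, threshold = 0), "> 0")
})

test_that("membrane-initiated filtering keeps the right trajectories", {
  cfg <- seg_cfg()
  geo <- simulate_cell(cfg)
  ctr <- unname(geo$centroid[1, ])
  mk <- function(id, x) data.frame(track_id = id, frame = 0:1,
                                   t_s = c(0, 10), x_px = NA, y_px = NA,
                                   x_um = x, y_um = ctr[2], peak = 1)
  # track 1 starts 0.3 um inside the boundary, track 2 at the centre (4 um)
  pts <- rbind(mk(1L, ctr[1] + 3.7), mk(2L, ctr[1]))
  tr <- structure(list(points = pts,
                       tracks = data.frame(track_id = 1:2, first_frame = 0L,
                                           last_frame = 1L, n_points = 2L,
                                           start_s = 0, lifetime_s = 20,
                                           preformed = FALSE),
                       frame_interval = 10, pixel_size_um = 0.10625),
                  class = "trajectory_set")
  ann <- annotate_compartments(tr, geo)
  expect_equal(ann$tracks$formation_compartment, c("membrane", "cytoplasm"))
  kept <- filter_membrane_initiated(ann)
  expect_equal(kept$tracks$track_id, 1L)
  expect_error(filter_membrane_initiated(tr), "annotate")
  # all-membrane synthetic data: everything retained
  cfgm <- seg_cfg(nucleation_rate = 0.05, membrane_fraction = 1,
                  photon_amplitude = 100, background_level = 50,
                  k1 = 0.002, k2 = 0.004, n_t = 15, rng_seed = 41)
  res <- run_live_pipeline(simulate_dataset(cfgm))
  expect_equal(res$stage_counts$tracks_membrane_initiated,
               res$stage_counts$tracks_after_preformed_filter)
})

test_that("compartment counts conserve totals and normalise by cell number", {
  cfg <- seg_cfg()
  geo <- simulate_cell(cfg)
  ctr <- unname(geo$centroid[1, ])
  pts <- data.frame(track_id = 1L, frame = 5:7, t_s = (5:7) * 10,
                    x_px = NA, y_px = NA, x_um = ctr[1] + 3.5,
                    y_um = ctr[2], peak = 1)
  tr <- structure(list(points = pts,
                       tracks = data.frame(track_id = 1L, first_frame = 5L,
                                           last_frame = 7L, n_points = 3L,
                                           start_s = 50, lifetime_s = 30,
                                           preformed = FALSE),
                       frame_interval = 10, pixel_size_um = 0.10625),
                  class = "trajectory_set")
  ann <- annotate_compartments(tr, geo)
  ct <- counts_over_time(ann, geo, n_cells = 1)
  expect_equal(ct$membrane_per_cell[ct$frame %in% 5:7], rep(1, 3))
  expect_equal(sum(ct$membrane_per_cell + ct$cytoplasm_per_cell), 3)
  ct2 <- counts_over_time(ann, geo, n_cells = 2)
  expect_equal(ct2$membrane_per_cell[ct2$frame == 6], 0.5)
  # conservation against alive membrane-initiated localisation count
  cfg2 <- seg_cfg(nucleation_rate = 0.05, membrane_fraction = 0.9,
                  photon_amplitude = 100, background_level = 50, n_t = 15,
                  rng_seed = 55)
  res <- run_live_pipeline(simulate_dataset(cfg2))
  mem <- filter_membrane_initiated(res$trajectories)
  ct3 <- counts_over_time(res$trajectories, res$geometry)
  per_frame <- table(factor(mem$points$frame, levels = 0:14))
  expect_equal(ct3$membrane_per_cell + ct3$cytoplasm_per_cell,
               as.numeric(per_frame))
})
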