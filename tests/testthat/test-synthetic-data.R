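# Synthetic-data generator: configuration, cell geometry, nucleation
# events, stack rendering and cluster masks.

small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_t = 12, n_z = 8, n_y = 64, n_x = 64, cell_radius = 2.5,
         nucleation_rate = 0.05, formation_delay = 20, rng_seed = 1),
    list(...))
  do.call(simulation_config, args)
}

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(k1 = -1), "positive")
  expect_error(simulation_config(membrane_fraction = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(frame_interval = 0), "positive")
  expect_error(small_cfg(cell_radius = 5), "field of view")
  cfg <- small_cfg()
  expect_s3_class(cfg, "simulation_config")
})

test_that("identical configuration yields bit-identical output", {
  a <- simulate_dataset(small_cfg())
  b <- simulate_dataset(small_cfg())
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$events$events, b$events$events)
  m1 <- simulate_cluster_masks(10, seed = 3)
  m2 <- simulate_cluster_masks(10, seed = 3)
  expect_identical(m1$masks, m2$masks)
  expect_identical(m1$truth, m2$truth)
})

test_that("simulated cell geometry is a disk with the configured motion", {
  cfg <- small_cfg()
  geo <- simulate_cell(cfg)
  expect_equal(nrow(unique(geo$centroid)), 1)   # static cell
  # boundary points lie at the radius from the centroid
  d <- sqrt((geo$boundary[[1]][, 1] - geo$centroid[1, 1])^2 +
              (geo$boundary[[1]][, 2] - geo$centroid[1, 2])^2)
  expect_lt(max(abs(d - cfg$cell_radius)), cfg$pixel_size_xy)
  # drift moves the centroid by v * dt per frame
  cfg2 <- small_cfg(drift_velocity_um_s = c(0.01, 0))
  geo2 <- simulate_cell(cfg2)
  expect_equal(diff(geo2$centroid[, 1]), rep(0.1, cfg2$n_t - 1))
  expect_equal(diff(geo2$centroid[, 2]), rep(0, cfg2$n_t - 1))
})

test_that("events respect the delay, compartment band and Poisson rate", {
  cfg <- simulation_config(n_t = 160, n_z = 6, n_y = 64, n_x = 64,
                           cell_radius = 2.5, nucleation_rate = 0.01,
                           formation_delay = 300, rng_seed = 2)
  geo <- simulate_cell(cfg)
  ev <- simulate_events(cfg, geo)$events
  expect_true(all(ev$birth_s >= 300))
  expect_true(all(ev$death_s >= ev$birth_s))
  expect_equal(ev$lifetime_s, ev$death_s - ev$birth_s)

  # membrane_fraction = 1: every event within the band of the boundary
  cfgm <- small_cfg(membrane_fraction = 1)
  geom <- simulate_cell(cfgm)
  evm <- simulate_events(cfgm, geom)$events
  dm <- boundary_distance(evm$x_um, evm$y_um, geom, 0)
  expect_true(all(dm <= cfgm$membrane_threshold_um + cfgm$pixel_size_xy))
  expect_true(all(evm$compartment == "membrane"))

  # mean event count over seeds matches rate x duration (Poisson mean 12)
  counts <- vapply(1:100, function(s) {
    c2 <- simulation_config(n_t = 151, n_z = 6, n_y = 64, n_x = 64,
                            cell_radius = 2.5, nucleation_rate = 0.01,
                            formation_delay = 0, rng_seed = s)
    nrow(simulate_events(c2, simulate_cell(c2))$events)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 15), 3 * sqrt(15 / 100))
})

test_that("membrane labels are consistent with the boundary distance", {
  cfg <- small_cfg(membrane_fraction = 0.5, rng_seed = 6)
  geo <- simulate_cell(cfg)
  ev <- simulate_events(cfg, geo)$events
  d <- boundary_distance(ev$x_um, ev$y_um, geo, 0)
  lbl <- ifelse(d <= cfg$membrane_threshold_um, "membrane", "cytoplasm")
  # agreement up to the boundary-point discretisation (half a pixel)
  off_band <- abs(d - cfg$membrane_threshold_um) > cfg$pixel_size_xy
  expect_equal(ev$compartment[off_band], lbl[off_band])
})

test_that("rendered stacks carry the configured signal and noise", {
  # no events: background statistics only
  cfg0 <- small_cfg(nucleation_rate = 1e-9, cell_intensity = 0)
  ds0 <- simulate_dataset(cfg0)
  expect_equal(mean(ds0$stack$data), cfg0$background_level, tolerance = 0.01)
  expect_equal(sd(as.numeric(ds0$stack$data)),
               sqrt(cfg0$background_level + cfg0$read_noise_sigma^2),
               tolerance = 0.05)

  # a single punctum, noise disabled: brightest voxel at its position
  cfg1 <- small_cfg(rng_seed = 4)
  geo <- simulate_cell(cfg1)
  ev <- structure(list(
    events = data.frame(event_id = 1L, birth_s = 0, death_s = 120,
                        lifetime_s = 120, x_um = 3.2, y_um = 4.1,
                        z_um = 0.8, compartment = "membrane"),
    positions = list(data.frame(frame = 0:11, t_s = (0:11) * 10, x_um = 3.2,
                                y_um = 4.1, z_um = 0.8))),
    class = "ground_truth_events")
  st <- render_stack(ev, geo, cfg1, noise = FALSE)
  idx <- arrayInd(which.max(st$data), dim(st$data))
  expect_equal(idx[1], round(4.1 / 0.10625 + 0.5))
  expect_equal(idx[2], round(3.2 / 0.10625 + 0.5))
  expect_equal(idx[3], round(0.8 / 0.2 + 0.5))
  # conservation: rendered puncta per frame = ground-truth events alive
  alive <- vapply(0:11, function(f)
    sum(vapply(ev$positions, function(p) f %in% p$frame, logical(1))),
    numeric(1))
  expect_equal(alive, rep(1, 12))
  expect_error(render_stack(ev, geo, small_cfg(photon_amplitude = 0)),
               "positive")
})

test_that("detection recovers nearly all rendered puncta at the stated SNR", {
  # amplitude 50 over background 100 with 2-count read noise
  cfg <- simulation_config(n_t = 20, n_z = 10, n_y = 96, n_x = 96,
                           cell_radius = 4, nucleation_rate = 0.04,
                           formation_delay = 0, k1 = 0.002, k2 = 0.004,
                           photon_amplitude = 50, background_level = 100,
                           read_noise_sigma = 2, rng_seed = 13)
  ds <- simulate_dataset(cfg)
  proj <- project_brightest(blur_3d(subtract_background(ds$stack, 80), 1))
  psz <- cfg$pixel_size_xy
  hits <- 0L; total <- 0L
  for (p in ds$events$positions) {
    for (r in seq_len(nrow(p))) {
      total <- total + 1L
      det <- detect_puncta(proj[, , p$frame[r] + 1L])
      if (nrow(det) == 0L) next
      dd <- sqrt((det$x_px - (p$x_um[r] / psz + 0.5))^2 +
                   (det$y_px - (p$y_um[r] / psz + 0.5))^2)
      if (min(dd) <= 2) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("cluster masks have the requested composition and exact truth", {
  cs <- simulate_cluster_masks(5, circular_fraction = 0.4, seed = 2)
  expect_equal(sum(cs$truth$circular), 2)
  cs1 <- simulate_cluster_masks(20, circular_fraction = 1, seed = 3)
  expect_true(all(cs1$truth$shape_factor_true == 1))
  expect_true(all(cs1$truth$diameter_nm >= 50 & cs1$truth$diameter_nm <= 500))
  # irregular truth: analytic polygon morphometry gives shape factor < 1
  cs0 <- simulate_cluster_masks(20, circular_fraction = 0, seed = 4)
  expect_true(all(cs0$truth$shape_factor_true < 1))
  expect_true(all(cs0$truth$shape_factor_true > 0))
  expect_equal(cs0$truth$shape_factor_true,
               4 * pi * cs0$truth$area_nm2 / cs0$truth$perimeter_nm^2)
  expect_error(simulate_cluster_masks(5, circular_fraction = 2),
               "\\[0, 1\\]")
})

test_that("rasterised disks measure as near-perfect circles", {
  # 100 disks of radius 10 px (diameter 100 nm at 5 nm/px)
  cs <- simulate_cluster_masks(100, pixel_size = 5, circular_fraction = 1,
                               size_range = c(100, 100), seed = 9)
  sf <- vapply(cs$masks, function(m) shape_factor(m)$shape_factor,
               numeric(1))
  expect_true(all(sf >= 0.95))
})

test_that("synthetic datasets round-trip through disk", {
  ds <- simulate_dataset(small_cfg())
  dir <- withr::local_tempdir()
  paths <- write_synthetic_dataset(ds, dir)
  st <- load_stack(paths$stack)
  expect_identical(st$data, ds$stack$data)
  expect_equal(st$pixel_size_xy, ds$stack$pixel_size_xy)
  ev <- read.csv(paths$events)
  expect_equal(nrow(ev), nrow(ds$events$events))
  cfg2 <- read_config(paths$config)
  expect_equal(unclass(cfg2), unclass(ds$config), tolerance = 1e-12)
})
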