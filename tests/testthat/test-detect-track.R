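# Preprocessing, maxima detection and trajectory linking.

test_that("rolling-ball subtraction removes flat and sloped backgrounds", {
  m <- matrix(100, 96, 96)
  expect_equal(max(abs(subtract_background(m, 80))), 0)
  expect_error(subtract_background(m, 0), ">= 1")

  # narrow spot on flat background: amplitude preserved within 5% of the
  # morphological-opening oracle (flat disc of the same radius)
  n <- 256
  ys <- seq_len(n)
  spot <- 50 * exp(-outer((ys - 128)^2, (ys - 128)^2, "+") / (2 * 3^2))
  img <- 100 + spot
  out <- subtract_background(img, 80)
  oracle_bg <- EBImage::imageData(EBImage::opening(
    EBImage::Image(img / 200), EBImage::makeBrush(159, "disc"))) * 200
  oracle_amp <- max(img - oracle_bg)
  expect_lt(abs(max(out) - oracle_amp) / oracle_amp, 0.05)

  # linear ramp + spot: residual background below 2% of the ramp range
  # away from the borders (the ball has no support outside the image)
  ramp <- outer(seq(0, 50, length.out = n), rep(1, n))
  out2 <- subtract_background(ramp + spot, 80)
  resid <- (out2 - spot)[81:176, 81:176]
  expect_lt(max(abs(resid)) / 50, 0.02)
})

test_that("3D blur reproduces the kernel, conserves intensity and is a semigroup", {
  a <- array(0, c(21, 21, 21)); a[11, 11, 11] <- 1
  b <- blur_3d(a, 1)
  k <- exp(-(-4:4)^2 / 2); k <- k / sum(k)
  # separable response: profile along one axis is k(0)^2 * k
  expect_equal(b[11, 7:15, 11], k[5]^2 * k, tolerance = 1e-12)
  expect_equal(b[7:15, 11, 11], k[5]^2 * k, tolerance = 1e-12)
  expect_equal(b[11, 11, 7:15], k[5]^2 * k, tolerance = 1e-12)
  expect_equal(sum(b), 1, tolerance = 1e-3)
  b2 <- blur_3d(blur_3d(a, 1), 1)
  bs <- blur_3d(a, sqrt(2))
  expect_lt(max(abs(b2 - bs)), 1e-4)
  expect_error(blur_3d(a, 0), "sigma")
})

test_that("brightest-point projection takes the pointwise z-maximum", {
  a <- array(0, c(8, 9, 5)); a[3, 7, 4] <- 11
  p <- project_brightest(a)
  expect_equal(dim(p), c(8, 9))
  expect_equal(p[3, 7], 11)
  a2 <- array(runif(8 * 9 * 5), c(8, 9, 5))
  p2 <- project_brightest(a2)
  for (z in 1:5) expect_true(all(p2 >= a2[, , z]))
  # peak ordering of isolated spots survives projection
  st <- array(0, c(40, 40, 6))
  st[10, 10, 2] <- 30; st[30, 30, 5] <- 50; st[10, 30, 3] <- 40
  pp <- project_brightest(st)
  expect_equal(order(c(pp[10, 10], pp[10, 30], pp[30, 30])), 1:3)
})

test_that("maxima detection honours the prominence threshold", {
  img <- spot_image(64, data.frame(y = 30, x = 40, amp = 50, sigma = 2))
  d <- detect_puncta(img)
  expect_equal(nrow(d), 1)
  expect_lt(abs(d$y_px - 30), 1)
  expect_lt(abs(d$x_px - 40), 1)
  # amplitude below the 20-count prominence: nothing detected
  d10 <- detect_puncta(spot_image(64, data.frame(y = 30, x = 40, amp = 10,
                                                 sigma = 2)))
  expect_equal(nrow(d10), 0)
  # two well-separated spots
  d2 <- detect_puncta(spot_image(64, data.frame(y = c(30, 30), x = c(20, 40),
                                                amp = c(50, 60),
                                                sigma = c(2, 2))))
  expect_equal(nrow(d2), 2)
  # empty image: empty result, not an error
  expect_equal(nrow(detect_puncta(matrix(0, 32, 32))), 0)
  expect_error(detect_puncta(matrix(0, 32, 32), prominence = 0), "> 0")
})

test_that("detection count is non-increasing in the prominence threshold", {
  img <- withr::with_seed(21, spot_image(
    96, data.frame(y = runif(8, 10, 86), x = runif(8, 10, 86),
                   amp = runif(8, 15, 80), sigma = 2)))
  counts <- vapply(c(5, 10, 20, 40, 60),
                   function(pr) nrow(detect_puncta(img, prominence = pr)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a shoulder of a brighter peak is not a separate punctum", {
  # second maximum 3 px away, only 10 counts below the main peak's flank
  img <- spot_image(64, data.frame(y = c(32, 35), x = c(32, 32),
                                   amp = c(60, 15), sigma = c(2, 1.5)))
  expect_equal(nrow(detect_puncta(img, prominence = 20)), 1)
})

test_that("linking reproduces the textbook cases", {
  # stationary punctum, frames 2..8: one track, lifetime 7 frames x 10 s
  tr <- link_trajectories(data.frame(frame = 2:8, x_px = 10, y_px = 10))
  expect_equal(nrow(tr$tracks), 1)
  expect_equal(tr$tracks$lifetime_s, 70)
  expect_false(tr$tracks$preformed)

  # two positions 10 px apart alternating: beyond the 8 px search range,
  # never linked
  tr2 <- link_trajectories(
    data.frame(frame = 0:9, x_px = ifelse(0:9 %% 2 == 0, 10, 20), y_px = 5),
    min_length = 1)
  expect_equal(nrow(tr2$tracks), 2)

  # a 7-frame gap exceeds the 6-frame memory: two tracks
  tr3 <- link_trajectories(data.frame(frame = c(1:3, 11:13), x_px = 10,
                                      y_px = 10))
  expect_equal(nrow(tr3$tracks), 2)
  # a gap within memory is bridged
  tr4 <- link_trajectories(data.frame(frame = c(1:3, 9:11), x_px = 10,
                                      y_px = 10))
  expect_equal(nrow(tr4$tracks), 1)
  expect_equal(tr4$tracks$lifetime_s, 110)

  expect_error(link_trajectories(data.frame(frame = c(-1, 0), x_px = 1,
                                            y_px = 1)), "0-based")
})

test_that("linking matches the exhaustive per-frame assignment oracle", {
  for (s in 1:40) {
    p <- random_tracking_instance(seed = 300 + s)
    if (!nrow(p)) next
    got <- link_trajectories(p, min_length = 2)
    want <- oracle_link(p, min_length = 2)
    expect_identical(canonical_tracks(got$points), canonical_tracks(want),
                     label = sprintf("instance seed %d", 300 + s))
  }
})

test_that("linking is invariant to the input order of puncta", {
  p <- random_tracking_instance(seed = 77, n_particles = 5)
  a <- link_trajectories(p)
  b <- link_trajectories(p[withr::with_seed(1, sample(nrow(p))), ])
  expect_identical(canonical_tracks(a$points), canonical_tracks(b$points))
})

test_that("pre-formed puncta are excluded and formation time reported", {
  p <- rbind(data.frame(frame = 0:5, x_px = 10, y_px = 10),
             data.frame(frame = 8:10, x_px = 30, y_px = 30))
  tr <- link_trajectories(p)
  expect_equal(nrow(tr$tracks), 2)
  kept <- filter_preformed(tr)
  expect_equal(nrow(kept$tracks), 1)
  expect_equal(kept$tracks$first_frame, 8)
  expect_equal(first_formation_time(kept), 80)

  one <- link_trajectories(data.frame(frame = 1:2, x_px = 5, y_px = 5))
  expect_equal(first_formation_time(one), 10)

  none <- filter_preformed(link_trajectories(
    data.frame(frame = 0:3, x_px = 5, y_px = 5)))
  expect_equal(nrow(none$points), 0)
  expect_warning(ff <- first_formation_time(none), "no formation observed")
  expect_true(is.na(ff))
})

test_that("first-formation time recovers the simulated onset over seeds", {
  # order statistic of the post-delay Poisson process: first birth is
  # delay + Exp(rate); the measured onset adds at most one frame of
  # discretisation.  Band: [delay, delay + 1/rate + dt] for the mean over
  # seeds, widened by the sampling error of the mean.
  rate <- 0.1; delay <- 300
  firsts <- vapply(1:20, function(s) {
    cfg <- simulation_config(n_t = 60, n_z = 6, n_y = 64, n_x = 64,
                             cell_radius = 2.5, nucleation_rate = rate,
                             formation_delay = delay, k1 = 0.005, k2 = 0.02,
                             photon_amplitude = 100, background_level = 50,
                             rng_seed = 500 + s)
    ds <- simulate_dataset(cfg)
    proj <- project_brightest(blur_3d(subtract_background(ds$stack, 80), 1))
    det <- do.call(rbind, lapply(seq_len(dim(proj)[3]), function(f) {
      d <- detect_puncta(proj[, , f])
      if (nrow(d)) d$frame <- f - 1L
      d
    }))
    tr <- filter_preformed(link_trajectories(det))
    first_formation_time(tr)
  }, numeric(1))
  slack <- 2.58 * (1 / rate) / sqrt(20)
  expect_gte(mean(firsts), delay)
  expect_lte(mean(firsts), delay + 1 / rate + 10 + slack)
})
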