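# Independent oracles used across the suite.

# -- hypoexponential CDF written directly from the closed form (independent
#    of the package's two_step_cdf)
oracle_hypoexp_cdf <- function(tau, k1, k2) {
  1 - (k2 * exp(-k1 * tau) - k1 * exp(-k2 * tau)) / (k2 - k1)
}

# -- quadrature oracle for moments of the lifetime density
oracle_moment <- function(k1, k2, power = 1) {
  integrand <- function(tau)
    tau^power * k1 * k2 / (k2 - k1) * (exp(-k1 * tau) - exp(-k2 * tau))
  integrate(integrand, 0, Inf, rel.tol = 1e-10)$value
}

# -- brute-force per-frame assignment oracle: enumerates every injective
#    mapping of detections to active tracks (plus "unmatched") and picks
#    the minimum-cost one, with the same deterministic tie-break as the
#    linker (tracks in preference order, first minimal assignment in
#    lexicographic option order wins)
oracle_assign <- function(cost, penalty) {
  nr <- nrow(cost); nc <- ncol(cost)
  opts <- lapply(seq_len(nc), function(j) c(which(is.finite(cost[, j])), 0L))
  grid <- expand.grid(rev(opts), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_len(nc)), drop = FALSE]  # col j = option for det j
  best_cost <- Inf; best <- integer(nc)
  for (r in seq_len(nrow(grid))) {
    asg <- as.integer(grid[r, ])
    rows <- asg[asg > 0L]
    if (anyDuplicated(rows)) next
    cst <- sum(vapply(seq_len(nc), function(j)
      if (asg[j] > 0L) cost[asg[j], j] else penalty, numeric(1L))) +
      penalty * (nr - length(rows))
    if (cst < best_cost - 1e-12) { best_cost <- cst; best <- asg }
  }
  best
}

# -- full reference tracker: same state machine as link_trajectories but
#    with the enumeration oracle as the per-frame solver
oracle_link <- function(puncta, search_range = 8, memory = 6,
                        min_length = 2) {
  puncta <- puncta[order(puncta$frame), , drop = FALSE]
  tid <- integer(); lx <- ly <- numeric(); lf <- integer(); np <- integer()
  nid <- 1L
  rows <- list()
  pen <- search_range^2
  for (f in 0:max(puncta$frame)) {
    det <- puncta[puncta$frame == f, , drop = FALSE]
    det <- det[order(det$y_px, det$x_px), , drop = FALSE]
    nd <- nrow(det)
    act <- which(lf >= f - 1L - memory)
    if (nd > 0L && length(act)) {
      act <- act[order(-np[act], tid[act])]
      cost <- outer(lx[act], det$x_px, "-")^2 + outer(ly[act], det$y_px, "-")^2
      cost[sqrt(cost) > search_range] <- Inf
      m <- oracle_assign(cost, pen)
    } else m <- integer(nd)
    for (j in seq_len(nd)) {
      if (length(act) && m[j] > 0L) {
        i <- act[m[j]]
        lx[i] <- det$x_px[j]; ly[i] <- det$y_px[j]; lf[i] <- f
        np[i] <- np[i] + 1L; id <- tid[i]
      } else {
        tid <- c(tid, nid); lx <- c(lx, det$x_px[j]); ly <- c(ly, det$y_px[j])
        lf <- c(lf, f); np <- c(np, 1L); id <- nid; nid <- nid + 1L
      }
      rows[[length(rows) + 1L]] <- c(id, f, det$y_px[j], det$x_px[j])
    }
  }
  m <- do.call(rbind, rows)
  df <- data.frame(track_id = m[, 1L], frame = m[, 2L], y_px = m[, 3L],
                   x_px = m[, 4L])
  cnt <- table(df$track_id)
  df[df$track_id %in% as.integer(names(cnt)[cnt >= min_length]), ,
     drop = FALSE]
}

# canonical string form of a set of tracks for comparison: each track is
# its sorted (frame, y, x) point list; the set is sorted
canonical_tracks <- function(points) {
  sp <- split(points[, c("frame", "y_px", "x_px")], points$track_id)
  keys <- vapply(sp, function(p) {
    p <- p[order(p$frame), ]
    paste(sprintf("%d:%.3f:%.3f", p$frame, p$y_px, p$x_px), collapse = ";")
  }, character(1L))
  sort(unname(keys))
}

# random tracking instance: n_particles random walks over n_frames with
# random birth/death and detection dropout
random_tracking_instance <- function(seed, n_particles = 5, n_frames = 10,
                                     field = 40, step = 3, p_drop = 0.15) {
  withr::with_seed(seed, {
    rows <- list()
    np <- sample(seq_len(n_particles), 1L)
    for (i in seq_len(np)) {
      b <- sample(0:(n_frames - 2L), 1L)
      d <- min(n_frames - 1L, b + sample(1:n_frames, 1L))
      x <- runif(1, 5, field - 5); y <- runif(1, 5, field - 5)
      for (f in b:d) {
        if (runif(1) > p_drop)
          rows[[length(rows) + 1L]] <- data.frame(frame = f, x_px = x,
                                                  y_px = y)
        x <- x + runif(1, -step, step); y <- y + runif(1, -step, step)
      }
    }
    if (!length(rows)) return(data.frame(frame = integer(), x_px = numeric(),
                                         y_px = numeric()))
    do.call(rbind, rows)
  })
}

# small Gaussian-spot image for detection tests
spot_image <- function(n = 64, spots = NULL, background = 0) {
  img <- matrix(background, n, n)
  if (is.null(spots)) return(img)
  ys <- seq_len(n)
  for (i in seq_len(nrow(spots)))
    img <- img + spots$amp[i] *
      exp(-outer((ys - spots$y[i])^2, (ys - spots$x[i])^2, "+") /
            (2 * spots$sigma[i]^2))
  img
}
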