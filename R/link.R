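## Frame-to-frame trajectory linking with gap closing (global nearest
## neighbour in the Crocker-Grier sense).
##
## Within each frame the assignment of detections to active tracks
## minimises the total cost: squared displacement for every link (links
## beyond the search range are forbidden) plus search_range^2 for every
## unlinked track and every unlinked detection.  Since any feasible link
## costs at most search_range^2 and saves two unlinked penalties, the
## optimum links as many particles as feasible with minimum total squared
## displacement.  A track may vanish for up to `memory` consecutive frames
## and still be continued from its last known position.  Cost ties are
## broken deterministically in favour of continuing the longer (then the
## older) track.

# exact assignment by depth-first branch and bound.
# cost[i, j]: track i x detection j (Inf = infeasible); penalty per
# unmatched row/column.  Rows must be pre-sorted in preference order.
# Returns assignment vector over columns (0 = unmatched) minimising
# total cost; first-found among equal-cost solutions wins, which together
# with the row ordering implements the tie-break.
.assign_bb <- function(cost, penalty) {
  nr <- nrow(cost); nc <- ncol(cost)
  # greedy upper bound (cheapest available row per column, in order);
  # epsilon added so an equal-cost solution found by the ordered DFS still
  # replaces it, keeping the DFS-order tie-break authoritative
  g_match <- integer(nc); g_used <- logical(nr); g_cost <- 0
  for (j in seq_len(nc)) {
    cc <- cost[, j]; cc[g_used] <- Inf
    i <- which.min(cc)
    if (length(i) && is.finite(cc[i]) && cc[i] < penalty) {
      g_match[j] <- i; g_used[i] <- TRUE; g_cost <- g_cost + cc[i]
    } else g_cost <- g_cost + penalty
  }
  g_cost <- g_cost + penalty * sum(!g_used)
  best <- list(cost = g_cost + 1e-9, match = g_match)
  col_match <- integer(nc)      # current partial assignment
  row_used <- logical(nr)
  rec <- function(j, acc) {
    if (acc >= best$cost) return()
    if (j > nc) {
      total <- acc + penalty * sum(!row_used)
      if (total < best$cost) best <<- list(cost = total, match = col_match)
      return()
    }
    # candidate rows in preference order, then "unmatched"
    for (i in seq_len(nr)) {
      if (row_used[i] || !is.finite(cost[i, j])) next
      col_match[j] <<- i; row_used[i] <<- TRUE
      rec(j + 1L, acc + cost[i, j])
      col_match[j] <<- 0L; row_used[i] <<- FALSE
    }
    rec(j + 1L, acc + penalty)
  }
  # bound refinement: remaining columns each cost at least 0; keep simple
  rec(1L, 0)
  # unmatched rows contribute penalty; accounted at the leaf
  best$match
}

#' Link per-frame puncta into trajectories
#'
#' @param puncta A data.frame of detections with columns `frame` (0-based
#'   integer), `x_px`, `y_px`, and optionally `peak`.
#' @param search_range Maximum displacement between consecutive frames, px
#'   (default 8).
#' @param memory Maximum number of consecutive frames a punctum may vanish
#'   and still be linked into the same track (default 6).
#' @param min_length Minimum number of detections a track must have to be
#'   kept (default 2).
#' @param frame_interval Frame interval in seconds, used to report
#'   lifetimes (`lifetime = (last - first + 1) * frame_interval`).
#' @param pixel_size_um Pixel size used to add micrometre coordinates.
#' @return A `trajectory_set`: list with `points` (track_id, frame, t_s,
#'   x_px, y_px, x_um, y_um, peak) and `tracks` (track_id, first_frame,
#'   last_frame, n_points, start_s, lifetime_s, preformed).
#' @export
link_trajectories <- function(puncta, search_range = 8, memory = 6,
                              min_length = 2, frame_interval = 10,
                              pixel_size_um = 0.10625) {
  req <- c("frame", "x_px", "y_px")
  if (!all(req %in% names(puncta)))
    stop("puncta must have columns frame, x_px, y_px")
  if (nrow(puncta) && (any(puncta$frame < 0) ||
                       any(puncta$frame != floor(puncta$frame))))
    stop("inconsistent frame indexing: frames must be 0-based integers")
  if (is.null(puncta$peak)) puncta$peak <- NA_real_
  puncta <- puncta[order(puncta$frame), , drop = FALSE]

  # active track state
  tid <- integer(); last_x <- numeric(); last_y <- numeric()
  last_frame <- integer(); npts <- integer()
  next_id <- 1L
  pts <- vector("list", 0L)
  pen <- search_range^2

  frames <- if (nrow(puncta)) 0:max(puncta$frame) else integer()
  for (f in frames) {
    det <- puncta[puncta$frame == f, , drop = FALSE]
    # canonical within-frame order: results are invariant to input order
    det <- det[order(det$y_px, det$x_px), , drop = FALSE]
    nd <- nrow(det)
    active <- which(last_frame >= f - 1L - memory)
    if (nd > 0L && length(active) > 0L) {
      # preference order: longer track first, then older id
      active <- active[order(-npts[active], tid[active])]
      dx <- outer(last_x[active], det$x_px, "-")
      dy <- outer(last_y[active], det$y_px, "-")
      cost <- dx^2 + dy^2
      cost[sqrt(cost) > search_range] <- Inf
      match <- .assign_bb(cost, pen)
    } else {
      match <- integer(nd)
    }
    for (j in seq_len(nd)) {
      if (nd > 0L && length(active) && match[j] > 0L) {
        i <- active[match[j]]
        last_x[i] <- det$x_px[j]; last_y[i] <- det$y_px[j]
        last_frame[i] <- f; npts[i] <- npts[i] + 1L
        id <- tid[i]
      } else {
        tid <- c(tid, next_id); last_x <- c(last_x, det$x_px[j])
        last_y <- c(last_y, det$y_px[j]); last_frame <- c(last_frame, f)
        npts <- c(npts, 1L)
        id <- next_id; next_id <- next_id + 1L
      }
      pts[[length(pts) + 1L]] <- data.frame(
        track_id = id, frame = f, x_px = det$x_px[j], y_px = det$y_px[j],
        peak = det$peak[j])
    }
  }

  points <- if (length(pts)) do.call(rbind, pts) else
    data.frame(track_id = integer(), frame = integer(), x_px = numeric(),
               y_px = numeric(), peak = numeric())
  # keep only tracks with enough detections
  cnt <- table(points$track_id)
  keep_ids <- as.integer(names(cnt)[cnt >= min_length])
  points <- points[points$track_id %in% keep_ids, , drop = FALSE]
  points <- points[order(points$track_id, points$frame), , drop = FALSE]
  # renumber consecutively in order of first appearance
  if (nrow(points)) {
    first_seen <- points$track_id[!duplicated(points$track_id)]
    points$track_id <- match(points$track_id, first_seen)
  }
  points$t_s <- points$frame * frame_interval
  points$x_um <- (points$x_px - 0.5) * pixel_size_um
  points$y_um <- (points$y_px - 0.5) * pixel_size_um
  points <- points[, c("track_id", "frame", "t_s", "x_px", "y_px",
                       "x_um", "y_um", "peak")]
  rownames(points) <- NULL

  tracks <- if (nrow(points)) {
    agg <- do.call(rbind, lapply(split(points, points$track_id), function(p)
      data.frame(track_id = p$track_id[1L], first_frame = min(p$frame),
                 last_frame = max(p$frame), n_points = nrow(p))))
    agg <- agg[order(agg$track_id), , drop = FALSE]
    agg$start_s <- agg$first_frame * frame_interval
    agg$lifetime_s <- (agg$last_frame - agg$first_frame + 1L) * frame_interval
    agg$preformed <- agg$first_frame == 0L
    rownames(agg) <- NULL
    agg
  } else {
    data.frame(track_id = integer(), first_frame = integer(),
               last_frame = integer(), n_points = integer(),
               start_s = numeric(), lifetime_s = numeric(),
               preformed = logical())
  }
  structure(list(points = points, tracks = tracks,
                 frame_interval = frame_interval,
                 pixel_size_um = pixel_size_um),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("Trajectory set: %d track(s), %d localisation(s)\n",
              nrow(x$tracks), nrow(x$points)))
  invisible(x)
}

# subset a trajectory_set to the given track ids
.subset_tracks <- function(trajectories, ids) {
  trajectories$points <-
    trajectories$points[trajectories$points$track_id %in% ids, , drop = FALSE]
  trajectories$tracks <-
    trajectories$tracks[trajectories$tracks$track_id %in% ids, , drop = FALSE]
  trajectories
}

#' Exclude pre-formed puncta
#'
#' Tracks already present in the first frame (frame 0) have an unobserved
#' formation time and are removed.
#'
#' @param trajectories A `trajectory_set`.
#' @return The filtered `trajectory_set`.
#' @export
filter_preformed <- function(trajectories) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  keep <- trajectories$tracks$track_id[!trajectories$tracks$preformed]
  .subset_tracks(trajectories, keep)
}

#' Time of first punctum formation
#'
#' @param trajectories A `trajectory_set` (pre-formed tracks should have
#'   been excluded first).
#' @param frame_interval Frame interval in seconds; defaults to the value
#'   stored in the trajectory set.
#' @return Earliest track start time in seconds, or `NA_real_` (with a
#'   warning, "no formation observed") when there are no tracks.
#' @export
first_formation_time <- function(trajectories,
                                 frame_interval = trajectories$frame_interval) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  if (nrow(trajectories$tracks) == 0L) {
    warning("no formation observed")
    return(NA_real_)
  }
  min(trajectories$tracks$first_frame) * frame_interval
}

#' Extract per-track lifetimes
#'
#' @param trajectories A `trajectory_set`.
#' @return Numeric vector of lifetimes in seconds (one per track).
#' @export
track_lifetimes <- function(trajectories) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  trajectories$tracks$lifetime_s
}
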