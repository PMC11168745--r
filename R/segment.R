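## Cell segmentation, drift correction, and membrane/cytoplasm
## classification of trajectories by distance to the cell boundary.

# Otsu threshold on a numeric matrix (256-level histogram between min/max)
.otsu_threshold <- function(m) {
  v <- as.numeric(m)
  r <- range(v)
  if (diff(r) == 0) stop("no foreground found: image is constant")
  h <- tabulate(pmin(255L, floor((v - r[1L]) / diff(r) * 256)) + 1L, 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256L))
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  r[1L] + k / 256 * diff(r)
}

# clean a thresholded binary matrix: opening removes isolated noise
# pixels, closing bridges small gaps, holes are filled; returns the labels
.clean_label <- function(bin, open_size = 3L, close_size = 5L) {
  img <- EBImage::Image(bin * 1)
  img <- EBImage::opening(img, EBImage::makeBrush(open_size, shape = "disc"))
  img <- EBImage::closing(img, EBImage::makeBrush(close_size, shape = "disc"))
  img <- EBImage::fillHull(img)
  EBImage::imageData(EBImage::bwlabel(img))
}

# largest connected component of a cleaned binary matrix
.clean_mask <- function(bin) {
  labs <- .clean_label(bin)
  if (max(labs) == 0) return(matrix(FALSE, nrow(bin), ncol(bin)))
  sizes <- tabulate(labs[labs > 0])
  labs == which.max(sizes)
}

# boundary pixels of a mask: set pixels with at least one 4-neighbour unset
.mask_boundary_idx <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  interior <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  which(mask & !interior, arr.ind = TRUE)
}

#' Segment the cell and extract its boundary and centroid per frame
#'
#' The time-median of the brightest-point projection is thresholded (Otsu),
#' morphologically closed, hole-filled, and the largest connected component
#' taken as the cell.  Each frame is then refined with the same threshold,
#' keeping the component that overlaps the median-projection mask most.
#'
#' @param stack An [image_stack4d], or a 3D array `(y, x, t)` of
#'   projections with a `pixel_size_xy` attribute, or a 2D matrix (single
#'   frame; `pixel_size_um` must then be given).
#' @param pixel_size_um Pixel size override, um/px.
#' @param min_area_fraction Minimum cell area as a fraction of the field
#'   (default 0.01); smaller foreground is an error.
#' @return A `cell_geometry`: `n_t`, `centroid` (t x 2, um), `boundary`
#'   (list of t matrices, columns x/y in um), `masks` (y, x, t logical),
#'   `pixel_size_xy`.
#' @export
segment_cell <- function(stack, pixel_size_um = NULL,
                         min_area_fraction = 0.01) {
  if (inherits(stack, "image_stack4d")) {
    proj <- project_brightest(stack)
    psz <- stack$pixel_size_xy
  } else if (is.matrix(stack)) {
    proj <- array(stack, dim = c(dim(stack), 1L))
    psz <- pixel_size_um
  } else {
    proj <- stack
    psz <- if (!is.null(pixel_size_um)) pixel_size_um else
      attr(stack, "pixel_size_xy")
  }
  if (is.null(psz)) stop("pixel size unknown; supply pixel_size_um")
  d <- dim(proj)
  med <- apply(proj, c(1L, 2L), median)
  # light smoothing before thresholding: the diffuse cell-body contrast is
  # weak relative to the projected shot noise
  med <- EBImage::gblur(med, sigma = 2)
  thr <- .otsu_threshold(med)
  ref_mask <- .clean_mask(med > thr)
  if (sum(ref_mask) < min_area_fraction * d[1L] * d[2L])
    stop("no foreground found: cell occupies < ",
         signif(100 * min_area_fraction, 2), "% of the field")

  masks <- array(FALSE, dim = d)
  centroid <- matrix(NA_real_, d[3L], 2L,
                     dimnames = list(NULL, c("x", "y")))
  boundary <- vector("list", d[3L])
  for (f in seq_len(d[3L])) {
    lab <- .clean_label(EBImage::gblur(proj[, , f], sigma = 2) > thr)
    if (max(lab) == 0) {           # fall back to the reference mask
      m <- ref_mask
    } else {
      overlap <- vapply(seq_len(max(lab)),
                        function(l) sum(lab == l & ref_mask), numeric(1L))
      pick <- if (any(overlap > 0)) which.max(overlap) else
        which.max(tabulate(lab[lab > 0]))
      m <- lab == pick
    }
    masks[, , f] <- m
    idx <- which(m, arr.ind = TRUE)
    centroid[f, ] <- c((mean(idx[, 2L]) - 0.5) * psz,
                       (mean(idx[, 1L]) - 0.5) * psz)
    b <- .mask_boundary_idx(m)
    boundary[[f]] <- cbind(x = (b[, 2L] - 0.5) * psz,
                           y = (b[, 1L] - 0.5) * psz)
  }
  structure(list(n_t = d[3L], centroid = centroid, boundary = boundary,
                 masks = masks, radius_um = NA_real_, pixel_size_xy = psz),
            class = "cell_geometry")
}

#' Distance from a point to the cell boundary
#'
#' Euclidean distance (in the projection plane) to the nearest boundary
#' point of the frame-matched boundary.
#'
#' @param x_um,y_um Point coordinates in um (vectorised).
#' @param geometry A `cell_geometry`.
#' @param frame 0-based frame index (scalar or vectorised with the points).
#' @return Distances in um.
#' @export
boundary_distance <- function(x_um, y_um, geometry, frame = 0L) {
  stopifnot(inherits(geometry, "cell_geometry"))
  frame <- rep_len(as.integer(frame), length(x_um))
  if (any(frame < 0L | frame >= geometry$n_t))
    stop("missing frame in geometry")
  out <- numeric(length(x_um))
  for (f in unique(frame)) {
    b <- geometry$boundary[[f + 1L]]
    sel <- which(frame == f)
    for (i in sel)
      out[i] <- sqrt(min((b[, 1L] - x_um[i])^2 + (b[, 2L] - y_um[i])^2))
  }
  out
}

#' Correct trajectories for cell movement
#'
#' Re-expresses every localisation relative to the frame's cell centroid,
#' adding `x_rel_um` / `y_rel_um` columns.
#'
#' @param trajectories A `trajectory_set`.
#' @param geometry A `cell_geometry` covering all trajectory frames.
#' @return The `trajectory_set` with drift-corrected coordinates added.
#' @export
correct_drift <- function(trajectories, geometry) {
  stopifnot(inherits(trajectories, "trajectory_set"),
            inherits(geometry, "cell_geometry"))
  p <- trajectories$points
  if (nrow(p) && max(p$frame) >= geometry$n_t)
    stop("missing frame in geometry")
  p$x_rel_um <- p$x_um - geometry$centroid[p$frame + 1L, 1L]
  p$y_rel_um <- p$y_um - geometry$centroid[p$frame + 1L, 2L]
  trajectories$points <- p
  trajectories
}

#' Classify a boundary distance as membrane or cytoplasm
#'
#' Membrane if and only if the distance is at most the threshold
#' (inclusive), 1.4 um by default.
#'
#' @param distance Distances to the cell boundary, um (non-negative).
#' @param threshold Membrane band width, um.
#' @return Character vector, `"membrane"` or `"cytoplasm"`.
#' @export
classify_compartment <- function(distance, threshold = 1.4) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (any(distance < 0)) stop("negative distance")
  ifelse(distance <= threshold, "membrane", "cytoplasm")
}

#' Annotate trajectories with boundary distance and compartment
#'
#' Adds `distance_um` and `compartment` to every localisation and a
#' `formation_compartment` (compartment of the first localisation) to every
#' track.
#'
#' @param trajectories A `trajectory_set`.
#' @param geometry A `cell_geometry`.
#' @param threshold Membrane band width, um.
#' @return The annotated `trajectory_set`.
#' @export
annotate_compartments <- function(trajectories, geometry, threshold = 1.4) {
  stopifnot(inherits(trajectories, "trajectory_set"),
            inherits(geometry, "cell_geometry"))
  p <- trajectories$points
  p$distance_um <- if (nrow(p))
    boundary_distance(p$x_um, p$y_um, geometry, p$frame) else numeric()
  p$compartment <- if (nrow(p))
    classify_compartment(p$distance_um, threshold) else character()
  trajectories$points <- p
  tr <- trajectories$tracks
  if (nrow(tr)) {
    first <- p[!duplicated(p$track_id), , drop = FALSE]
    tr$formation_compartment <-
      first$compartment[match(tr$track_id, first$track_id)]
    tr$first_distance_um <-
      first$distance_um[match(tr$track_id, first$track_id)]
  } else {
    tr$formation_compartment <- character()
    tr$first_distance_um <- numeric()
  }
  trajectories$tracks <- tr
  trajectories
}

#' Keep only membrane-initiated trajectories
#'
#' Retains tracks whose first localisation is classified membrane;
#' cytoplasm-formed trajectories are excluded from further analysis.
#'
#' @param trajectories A `trajectory_set` annotated by
#'   [annotate_compartments()].
#' @return The filtered `trajectory_set`.
#' @export
filter_membrane_initiated <- function(trajectories) {
  stopifnot(inherits(trajectories, "trajectory_set"))
  if (is.null(trajectories$tracks$formation_compartment))
    stop("trajectories must be annotated with annotate_compartments() first")
  keep <- trajectories$tracks$track_id[
    trajectories$tracks$formation_compartment == "membrane"]
  .subset_tracks(trajectories, keep)
}

#' Membrane and cytoplasm puncta counts over time
#'
#' For membrane-initiated trajectories, counts at each frame how many
#' localisations are currently classified membrane vs cytoplasm (the
#' compartment is re-evaluated per frame, so internalisation registers as a
#' membrane-to-cytoplasm transition), normalised by the number of cells.
#'
#' @param trajectories An annotated `trajectory_set`.
#' @param geometry A `cell_geometry` (defines the frame range).
#' @param n_cells Number of cells pooled into the counts (>= 1).
#' @return data.frame: `frame`, `t_s`, `membrane_per_cell`,
#'   `cytoplasm_per_cell`.
#' @export
counts_over_time <- function(trajectories, geometry, n_cells = 1) {
  stopifnot(inherits(trajectories, "trajectory_set"), n_cells >= 1)
  mem <- filter_membrane_initiated(trajectories)
  p <- mem$points
  frames <- 0:(geometry$n_t - 1L)
  m_cnt <- c_cnt <- numeric(length(frames))
  if (nrow(p)) {
    tm <- table(factor(p$frame[p$compartment == "membrane"], levels = frames))
    tc <- table(factor(p$frame[p$compartment == "cytoplasm"], levels = frames))
    m_cnt <- as.numeric(tm); c_cnt <- as.numeric(tc)
  }
  data.frame(frame = frames,
             t_s = frames * trajectories$frame_interval,
             membrane_per_cell = m_cnt / n_cells,
             cytoplasm_per_cell = c_cnt / n_cells)
}
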