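## Synthetic fixed-cell branch: binary cluster masks with analytically
## known morphometry, placed on a canvas with a matched reference channel.

# rasterise a polygon (continuous coords, rows x / cols y in px) onto a
# pixel grid: pixel centre in polygon (even-odd rule)
.rasterise_polygon <- function(px, py, nr, nc) {
  xs <- matrix(rep(seq_len(nc), each = nr), nr)   # x = column index
  ys <- matrix(rep(seq_len(nr), nc), nr)
  n <- length(px)
  inside <- matrix(FALSE, nr, nc)
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > ys) != (py[j] > ys)) &
      (xs < (px[j] - px[i]) * (ys - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

.polygon_area <- function(px, py) {
  n <- length(px); j <- c(n, seq_len(n - 1L))
  abs(sum(px * py[j] - px[j] * py)) / 2
}

.polygon_perimeter <- function(px, py) {
  dx <- diff(c(px, px[1L])); dy <- diff(c(py, py[1L]))
  sum(sqrt(dx^2 + dy^2))
}

#' Simulate binary cluster masks with known morphometry
#'
#' Generates `round(circular_fraction * n)` circular clusters (rasterised
#' disks; true shape factor exactly 1) and the rest as irregular clusters
#' (star polygons with randomly perturbed radii; true area and perimeter
#' computed analytically from the continuous polygon before rasterisation).
#' Cluster diameters are drawn uniformly from `size_range`.  Clusters are
#' placed on a non-overlapping grid canvas; a fraction `coloc_fraction` is
#' flagged colocalised (these get a matching reference-channel spot from
#' [render_reference_image()]).
#'
#' @param n Number of clusters.
#' @param pixel_size Rendering pixel size in nm/px (default 5, a typical
#'   super-resolved reconstruction grid).
#' @param circular_fraction Fraction of circular clusters, in `[0, 1]`.
#' @param size_range Diameter range in nm (default c(50, 500)).
#' @param seed Integer seed.
#' @param coloc_fraction Fraction of clusters flagged colocalised.
#' @param irregularity Relative radial perturbation amplitude of the
#'   irregular polygons (default 0.45).
#' @return A `cluster_set`: `masks` (list of logical matrices), `truth`
#'   (data.frame: cluster_id, x_px, y_px canvas centroid, circular,
#'   colocalised, diameter_nm, area_nm2, perimeter_nm, shape_factor_true),
#'   `pixel_size_nm`, `canvas` (c(n_y, n_x)).
#' @export
simulate_cluster_masks <- function(n, pixel_size = 5, circular_fraction = 0.5,
                                   size_range = c(50, 500), seed = 1,
                                   coloc_fraction = 1, irregularity = 0.45) {
  stopifnot(n >= 1)
  if (circular_fraction < 0 || circular_fraction > 1)
    stop("circular_fraction must lie in [0, 1]")
  if (length(size_range) != 2L || size_range[1L] <= 0 ||
      size_range[2L] < size_range[1L])
    stop("size_range must be increasing and positive (nm)")
  n_circ <- round(circular_fraction * n)
  circular <- c(rep(TRUE, n_circ), rep(FALSE, n - n_circ))

  # grid placement: cell pitch comfortably larger than the largest cluster
  pitch_px <- ceiling(size_range[2L] / pixel_size) + 24L
  n_side <- ceiling(sqrt(n))
  canvas <- c(n_side, n_side) * pitch_px

  withr::with_seed(as.integer(seed), {
    circular <- sample(circular)        # randomise placement order
    coloc <- seq_len(n) %in% sample(n, round(coloc_fraction * n))
    masks <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      d_nm <- runif(1L, size_range[1L], size_range[2L])
      r_px <- d_nm / 2 / pixel_size
      side <- 2L * ceiling(r_px * (1 + irregularity)) + 6L
      off <- runif(2L)                  # sub-pixel centre offset
      cx <- side / 2 + off[1L]; cy <- side / 2 + off[2L]
      if (circular[i]) {
        xs <- matrix(rep(seq_len(side), each = side), side)
        ys <- matrix(rep(seq_len(side), side), side)
        mask <- (xs - cx)^2 + (ys - cy)^2 <= r_px^2
        a_nm2 <- pi * (d_nm / 2)^2
        p_nm <- pi * d_nm
      } else {
        # resample the perturbation until the rasterised polygon is a
        # single connected component (thin spikes of very small clusters
        # can otherwise break off), so the analytic truth always describes
        # the emitted mask
        k <- 12L
        repeat {
          th <- seq(0, 2 * pi, length.out = k + 1L)[-(k + 1L)] +
            runif(1L, 0, 2 * pi / k)
          rad <- r_px * (1 + runif(k, -irregularity, irregularity))
          px <- cx + rad * cos(th); py <- cy + rad * sin(th)
          mask <- .rasterise_polygon(px, py, side, side)
          if (sum(mask) >= 4L &&
              max(EBImage::imageData(EBImage::bwlabel(
                EBImage::Image(mask * 1)))) == 1L) break
        }
        a_nm2 <- .polygon_area(px, py) * pixel_size^2
        p_nm <- .polygon_perimeter(px, py) * pixel_size
      }
      gi <- ((i - 1L) %% n_side); gj <- ((i - 1L) %/% n_side)
      masks[[i]] <- mask
      truth[[i]] <- data.frame(
        cluster_id = i,
        y_px = gi * pitch_px + pitch_px / 2,
        x_px = gj * pitch_px + pitch_px / 2,
        circular = circular[i], colocalised = coloc[i],
        diameter_nm = if (circular[i]) d_nm else 2 * sqrt(a_nm2 / pi),
        area_nm2 = a_nm2, perimeter_nm = p_nm,
        shape_factor_true = if (circular[i]) 1 else
          min(1, 4 * pi * a_nm2 / p_nm^2))
    }
    structure(list(masks = masks, truth = do.call(rbind, truth),
                   pixel_size_nm = pixel_size, canvas = canvas),
              class = "cluster_set")
  })
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "Synthetic cluster set: %d mask(s) at %g nm/px (%d circular, %d colocalised)\n",
    length(x$masks), x$pixel_size_nm, sum(x$truth$circular),
    sum(x$truth$colocalised)))
  invisible(x)
}

#' Render the matched reference-channel image of a cluster set
#'
#' Draws a diffraction-limited Gaussian spot at the canvas position of each
#' colocalised cluster, emulating the widefield reference channel used to
#' separate genuine clusters from non-specific signal.
#'
#' @param cluster_set From [simulate_cluster_masks()].
#' @param psf_sigma_nm Reference-channel PSF sigma in nm (default 130).
#' @param amplitude Spot peak intensity (counts).
#' @param background Constant background (counts).
#' @return 2D numeric matrix (canvas-sized, reference pixel grid =
#'   cluster pixel grid).
#' @export
render_reference_image <- function(cluster_set, psf_sigma_nm = 130,
                                   amplitude = 100, background = 10) {
  stopifnot(inherits(cluster_set, "cluster_set"))
  d <- cluster_set$canvas
  img <- matrix(background, d[1L], d[2L])
  s <- psf_sigma_nm / cluster_set$pixel_size_nm
  w <- ceiling(4 * s)
  tr <- cluster_set$truth[cluster_set$truth$colocalised, , drop = FALSE]
  for (i in seq_len(nrow(tr))) {
    iy <- max(1L, floor(tr$y_px[i] - w)):min(d[1L], ceiling(tr$y_px[i] + w))
    ix <- max(1L, floor(tr$x_px[i] - w)):min(d[2L], ceiling(tr$x_px[i] + w))
    g <- amplitude * exp(-((iy - tr$y_px[i])^2) / (2 * s^2)) %o%
      exp(-((ix - tr$x_px[i])^2) / (2 * s^2))
    img[iy, ix] <- img[iy, ix] + g
  }
  img
}

#' Render a super-resolved image from a localisation table
#'
#' Each localisation is drawn as a 2D Gaussian of its fitted precision,
#' the common way reconstructed images are generated from single-molecule
#' localisation tables.
#'
#' @param localisations data.frame with `x_nm`, `y_nm`, `sigma_nm` and
#'   optionally `intensity`.
#' @param pixel_size_nm Rendering pixel size (nm/px).
#' @param shape Output image shape `c(n_y, n_x)`; computed from the data
#'   extent if `NULL`.
#' @return 2D numeric matrix.
#' @export
render_localisations <- function(localisations, pixel_size_nm = 5,
                                 shape = NULL) {
  req <- c("x_nm", "y_nm", "sigma_nm")
  if (!all(req %in% names(localisations)))
    stop("localisation table needs columns: ", paste(req, collapse = ", "))
  if (is.null(localisations$intensity)) localisations$intensity <- 1
  if (is.null(shape)) {
    shape <- c(ceiling(max(localisations$y_nm) / pixel_size_nm) + 10L,
               ceiling(max(localisations$x_nm) / pixel_size_nm) + 10L)
  }
  img <- matrix(0, shape[1L], shape[2L])
  for (i in seq_len(nrow(localisations))) {
    s <- localisations$sigma_nm[i] / pixel_size_nm
    cy <- localisations$y_nm[i] / pixel_size_nm + 0.5
    cx <- localisations$x_nm[i] / pixel_size_nm + 0.5
    w <- ceiling(4 * s)
    iy <- max(1L, floor(cy - w)):min(shape[1L], ceiling(cy + w))
    ix <- max(1L, floor(cx - w)):min(shape[2L], ceiling(cx + w))
    g <- localisations$intensity[i] *
      exp(-((iy - cy)^2) / (2 * s^2)) %o% exp(-((ix - cx)^2) / (2 * s^2))
    img[iy, ix] <- img[iy, ix] + g
  }
  img
}

#' Write a cluster set to disk
#'
#' One binary TIFF per mask plus a CSV of the true morphometry.
#'
#' @param cluster_set From [simulate_cluster_masks()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_cluster_set <- function(cluster_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(cluster_set$masks)) {
    tiff::writeTIFF(cluster_set$masks[[i]] * 1,
                    file.path(dir, sprintf("mask_%04d.tif", i)),
                    bits.per.sample = 8L, compression = "none")
  }
  write.csv(cluster_set$truth, file.path(dir, "truth.csv"),
            row.names = FALSE)
  invisible(dir)
}
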