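## Calibrated 4D stack container and TIFF I/O.
##
## In memory the intensities are an integer array with dimensions
## (y, x, z, t); on disk a multi-page TIFF with pages ordered t-major,
## z-minor (page = (t-1)*n_z + z), the order in which a stage-scanning
## acquisition writes z-stacks.

#' Calibrated 4D image stack
#'
#' @param data Integer array of intensities with dim `(y, x, z, t)`; 2D or
#'   3D input is promoted by adding unit z and/or t dimensions.
#' @param pixel_size_xy Lateral pixel size, um/px.
#' @param z_spacing Axial slice spacing, um.
#' @param frame_interval Frame interval, s.
#' @return An `image_stack4d` object.
#' @export
image_stack4d <- function(data, pixel_size_xy, z_spacing, frame_interval) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) stop("data must have dimensions (y, x, z, t)")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (!all(is.finite(c(pixel_size_xy, z_spacing, frame_interval))) ||
      pixel_size_xy <= 0 || z_spacing <= 0 || frame_interval <= 0)
    stop("calibrations must be strictly positive")
  structure(list(data = data, pixel_size_xy = pixel_size_xy,
                 z_spacing = z_spacing, frame_interval = frame_interval),
            class = "image_stack4d")
}

#' @export
print.image_stack4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "4D image stack: %d frame(s) x %d z x %d y x %d x | %g um/px, %g um z-step, %g s/frame\n",
    d[4L], d[3L], d[1L], d[2L], x$pixel_size_xy, x$z_spacing,
    x$frame_interval))
  invisible(x)
}

#' Write a 4D stack as a multi-page 16-bit TIFF
#'
#' @param stack An [image_stack4d].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack4d"))
  d <- dim(stack$data)
  pages <- vector("list", d[3L] * d[4L])
  k <- 1L
  for (t in seq_len(d[4L])) for (z in seq_len(d[3L])) {
    pages[[k]] <- stack$data[, , z, t] / 65535
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Load a multi-page TIFF as a calibrated 4D stack
#'
#' Pages are interpreted in t-major, z-minor order.  The number of z-slices
#' per time point cannot be inferred from a plain TIFF, so it must be given
#' (`n_z`), along with the spatial and temporal calibration; alternatively a
#' sidecar `config.json` written by [write_synthetic_dataset()] next to the
#' stack supplies all four.  A 3D stack (single time point) is accepted with
#' `n_z = page count`.
#'
#' @param path TIFF file.
#' @param n_z Number of z-slices per frame; the page count must be an exact
#'   multiple.
#' @param pixel_size_um,z_step_um,frame_interval_s Calibration overrides.
#' @return An [image_stack4d].
#' @export
load_stack <- function(path, n_z = NULL, pixel_size_um = NULL,
                       z_step_um = NULL, frame_interval_s = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar <- file.path(dirname(path), "config.json")
  if (file.exists(sidecar)) {
    cfg <- tryCatch(read_config(sidecar), error = function(e) NULL)
    if (!is.null(cfg)) {
      if (is.null(n_z)) n_z <- cfg$n_z
      if (is.null(pixel_size_um)) pixel_size_um <- cfg$pixel_size_xy
      if (is.null(z_step_um)) z_step_um <- cfg$z_spacing
      if (is.null(frame_interval_s)) frame_interval_s <- cfg$frame_interval
    }
  }
  missing <- c("--pixel-size-um", "--z-step-um",
               "--frame-interval-s")[c(is.null(pixel_size_um),
                                       is.null(z_step_um),
                                       is.null(frame_interval_s))]
  if (length(missing))
    stop("calibration missing and no sidecar config.json found; supply: ",
         paste(missing, collapse = ", "))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e) stop("failed to read TIFF '", path,
                                             "': ", conditionMessage(e)))
  n_pages <- length(pages)
  if (is.null(n_z)) n_z <- n_pages    # single-timepoint 3D stack
  if (n_pages %% n_z != 0L)
    stop("ambiguous axes: ", n_pages, " pages is not a multiple of n_z = ",
         n_z)
  n_t <- n_pages %/% n_z
  d <- dim(pages[[1L]])
  arr <- array(0L, dim = c(d[1L], d[2L], n_z, n_t))
  k <- 1L
  for (t in seq_len(n_t)) for (z in seq_len(n_z)) {
    arr[, , z, t] <- as.integer(round(pages[[k]] * 65535))
    k <- k + 1L
  }
  image_stack4d(arr, pixel_size_xy = pixel_size_um, z_spacing = z_step_um,
                frame_interval = frame_interval_s)
}
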