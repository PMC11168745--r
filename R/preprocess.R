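## Stack preprocessing: rolling-ball background subtraction, separable 3D
## Gaussian blurring, and brightest-point z-projection.

# shift a (y, x, n) array by (dy, dx) with edge replication
.shift_yx <- function(a, dy, dx) {
  d <- dim(a)
  iy <- pmin(pmax(seq_len(d[1L]) + dy, 1L), d[1L])
  ix <- pmin(pmax(seq_len(d[2L]) + dx, 1L), d[2L])
  a[iy, ix, , drop = FALSE]
}

# shift with constant fill (valid-support morphology); shifts larger than
# the array leave it entirely filled
.shift_yx_fill <- function(a, dy, dx, fill) {
  d <- dim(a)
  out <- array(fill, d)
  y0 <- max(1L, 1L + dy); y1 <- min(d[1L], d[1L] + dy)
  x0 <- max(1L, 1L + dx); x1 <- min(d[2L], d[2L] + dx)
  if (y0 > y1 || x0 > x1) return(out)
  out[(y0:y1) - dy, (x0:x1) - dx, ] <- a[y0:y1, x0:x1, , drop = FALSE]
  out
}

# block-min / block-max downsample of (y, x, n) by integer factor s
.block_reduce <- function(a, s, op) {
  d <- dim(a)
  ny <- ceiling(d[1L] / s); nx <- ceiling(d[2L] / s)
  out <- NULL
  for (dy in 0:(s - 1L)) for (dx in 0:(s - 1L)) {
    iy <- pmin(seq_len(ny) * s - dy, d[1L])
    ix <- pmin(seq_len(nx) * s - dx, d[2L])
    sub <- a[iy, ix, , drop = FALSE]
    out <- if (is.null(out)) sub else op(out, sub)
  }
  out
}

# bilinear weights mapping a coarse grid of n_small block centres (block
# size s, centre of block i at (i - 0.5) * s + 0.5 in fine coords) to n_fine
.interp_weights <- function(n_fine, n_small, s) {
  centres <- (seq_len(n_small) - 0.5) * s + 0.5
  W <- matrix(0, n_fine, n_small)
  for (i in seq_len(n_fine)) {
    if (i <= centres[1L]) { W[i, 1L] <- 1; next }
    if (i >= centres[n_small]) { W[i, n_small] <- 1; next }
    k <- findInterval(i, centres)
    w <- (i - centres[k]) / (centres[k + 1L] - centres[k])
    W[i, k] <- 1 - w; W[i, k + 1L] <- w
  }
  W
}

# grey erosion (pmin, fill +Inf) or dilation (pmax, fill -Inf) over a ball
# structuring function; offsets outside the image are ignored
.ball_morph <- function(a, offsets, heights, combine, sign, fill) {
  out <- NULL
  for (k in seq_len(nrow(offsets))) {
    sh <- .shift_yx_fill(a, offsets[k, 1L], offsets[k, 2L], fill) +
      sign * heights[k]
    out <- if (is.null(out)) sh else combine(out, sh)
  }
  out
}

#' Rolling-ball background subtraction
#'
#' Estimates the slowly varying background of each image as the grey-scale
#' opening with a ball-shaped structuring function of the given radius (the
#' surface traced by rolling a ball of that radius under the image), then
#' subtracts it.  As in the classical implementation, large radii are
#' handled by block-downsampling the image, rolling a proportionally
#' smaller ball, and bilinearly interpolating the background back to full
#' resolution.  Output is clamped to be non-negative.
#'
#' @param image A 2D matrix, a 3D array of slices `(y, x, n)`, or an
#'   [image_stack4d] (every z-slice of every frame is processed
#'   independently).
#' @param ball_radius Ball radius in pixels (default 80).
#' @return Same shape/class as the input, background subtracted.
#' @export
subtract_background <- function(image, ball_radius = 80) {
  if (!is.numeric(ball_radius) || length(ball_radius) != 1L ||
      !is.finite(ball_radius) || ball_radius < 1)
    stop("ball_radius must be a positive number of pixels (>= 1)")
  if (inherits(image, "image_stack4d")) {
    d <- dim(image$data)
    a <- image$data
    dim(a) <- c(d[1L], d[2L], d[3L] * d[4L])
    bg <- .rolling_ball_background(a, ball_radius)
    out <- pmax(a - bg, 0)
    dim(out) <- d
    image$data <- as.integer(round(out))
    dim(image$data) <- d
    return(image)
  }
  was_matrix <- is.matrix(image)
  a <- if (was_matrix) array(image, dim = c(dim(image), 1L)) else image
  stopifnot(length(dim(a)) == 3L)
  bg <- .rolling_ball_background(a, ball_radius)
  out <- pmax(a - bg, 0)
  if (was_matrix) out[, , 1L] else out
}

.rolling_ball_background <- function(a, ball_radius) {
  s <- max(1L, floor(ball_radius / 10))
  r <- ball_radius / s
  w <- floor(r)
  off <- expand.grid(dy = -w:w, dx = -w:w)
  keep <- off$dy^2 + off$dx^2 <= r^2
  off <- as.matrix(off[keep, , drop = FALSE])
  hts <- sqrt(r^2 - off[, 1L]^2 - off[, 2L]^2)
  if (s > 1L) {
    # pre-smooth (3x3 mean) so that the block-minimum shrink does not bias
    # the background estimate toward noise minima, then shrink
    sm <- .shift_yx(a, -1L, 0L) + a + .shift_yx(a, 1L, 0L)
    sm <- .shift_yx(sm, 0L, -1L) + sm + .shift_yx(sm, 0L, 1L)
    small <- .block_reduce(sm / 9, s, pmin)
  } else small <- a
  er <- .ball_morph(small, off, hts, pmin, -1, Inf)
  bg <- .ball_morph(er, off, hts, pmax, +1, -Inf)
  if (s > 1L) {
    d <- dim(a); ds <- dim(bg)
    Wy <- .interp_weights(d[1L], ds[1L], s)
    Wx <- .interp_weights(d[2L], ds[2L], s)
    # apply along y: (ny x ny') %*% (ny' x nx'*n)
    m <- bg; dim(m) <- c(ds[1L], ds[2L] * ds[3L])
    m <- Wy %*% m
    dim(m) <- c(d[1L], ds[2L], ds[3L])
    m <- aperm(m, c(2L, 1L, 3L))
    dim(m) <- c(ds[2L], d[1L] * ds[3L])
    m <- Wx %*% m
    dim(m) <- c(d[2L], d[1L], ds[3L])
    bg <- aperm(m, c(2L, 1L, 3L))
  }
  # the ball must fit under the true background; never exceed the image
  pmin(bg, a)
}

# normalised Gaussian convolution matrix along one axis (rows renormalised
# at the borders, so constants are preserved)
.gauss_conv_matrix <- function(n, sigma) {
  w <- max(1L, ceiling(4 * sigma))
  K <- matrix(0, n, n)
  kern <- exp(-((-w:w)^2) / (2 * sigma^2))
  for (i in seq_len(n)) {
    j <- (i - w):(i + w)
    ok <- j >= 1L & j <= n
    K[i, j[ok]] <- kern[ok]
    K[i, ] <- K[i, ] / sum(K[i, ])
  }
  K
}

#' Separable 3D Gaussian blur
#'
#' Blurs a volume with an isotropic (in voxel units) Gaussian of standard
#' deviation `sigma` pixels, applied separably along y, x and z.  Border
#' rows of the kernel are renormalised, so constant volumes are preserved
#' and total intensity of interior structures is conserved.
#'
#' @param stack A 3D array `(y, x, z)` or an [image_stack4d] (each frame
#'   blurred independently).
#' @param sigma Gaussian standard deviation in pixels (default 1).
#' @return Blurred array (double) of the same shape, or the stack with
#'   blurred (rounded integer) data.
#' @export
blur_3d <- function(stack, sigma = 1) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, sigma > 0)
  if (inherits(stack, "image_stack4d")) {
    d <- dim(stack$data)
    out <- stack$data
    for (t in seq_len(d[4L]))
      out[, , , t] <- round(.blur3(stack$data[, , , t, drop = TRUE], sigma))
    stack$data <- out
    return(stack)
  }
  stopifnot(length(dim(stack)) == 3L)
  .blur3(stack, sigma)
}

.blur3 <- function(a, sigma) {
  d <- dim(a)
  if (length(d) != 3L) dim(a) <- d <- c(d, 1L)[1:3]
  Ky <- .gauss_conv_matrix(d[1L], sigma)
  Kx <- .gauss_conv_matrix(d[2L], sigma)
  m <- a; dim(m) <- c(d[1L], d[2L] * d[3L])
  m <- Ky %*% m
  dim(m) <- d; m <- aperm(m, c(2L, 1L, 3L))
  dim(m) <- c(d[2L], d[1L] * d[3L])
  m <- Kx %*% m
  dim(m) <- c(d[2L], d[1L], d[3L])
  m <- aperm(m, c(3L, 2L, 1L))          # (z, y, x)
  if (d[3L] > 1L) {
    Kz <- .gauss_conv_matrix(d[3L], sigma)
    dim(m) <- c(d[3L], d[1L] * d[2L])
    m <- Kz %*% m
    dim(m) <- c(d[3L], d[1L], d[2L])
  }
  aperm(m, c(2L, 3L, 1L))               # back to (y, x, z)
}

#' Brightest-point (maximum intensity) z-projection
#'
#' @param stack A 3D array `(y, x, z)` or an [image_stack4d].
#' @return For 3D input a 2D matrix; for a 4D stack a 3D array `(y, x, t)`
#'   with the stack's calibration attached as attributes `pixel_size_xy`
#'   and `frame_interval`.
#' @export
project_brightest <- function(stack) {
  if (inherits(stack, "image_stack4d")) {
    d <- dim(stack$data)
    out <- array(stack$data[, , 1L, ], dim = c(d[1L], d[2L], d[4L]))
    if (d[3L] > 1L) for (z in 2:d[3L])
      out <- pmax(out, array(stack$data[, , z, ], dim = dim(out)))
    attr(out, "pixel_size_xy") <- stack$pixel_size_xy
    attr(out, "frame_interval") <- stack$frame_interval
    return(out)
  }
  d <- dim(stack)
  stopifnot(length(d) == 3L)
  out <- stack[, , 1L]
  if (d[3L] > 1L) for (z in 2:d[3L]) out <- pmax(out, stack[, , z])
  out
}
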