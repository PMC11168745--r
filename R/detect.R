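## Prominence-based maxima detection on 2D projections.
##
## A punctum is a local maximum whose topographic prominence (height above
## the lowest contour that separates it from any higher region) exceeds a
## threshold, 20 counts by default.  Candidates are screened by flooding
## down from each peak to (peak - prominence): if the flood reaches a
## strictly higher pixel the candidate is a shoulder of a higher peak and
## is rejected; equal-valued plateau maxima are merged into one detection.

#' Detect puncta in a 2D image by prominence
#'
#' @param projection 2D numeric matrix (typically a background-subtracted,
#'   blurred, brightest-point projection).
#' @param prominence Minimum prominence in counts (default 20).
#' @param subpixel Refine each detection by intensity centre-of-mass in a
#'   5x5 window (default `TRUE`).
#' @return A data.frame with one row per punctum: `y_px`, `x_px`
#'   (sub-pixel, 1-based pixel-centre coordinates), `peak` (counts),
#'   `prominence` (counts, lower bound at the flood level).  Empty input or
#'   an image with no qualifying maxima yields zero rows.
#' @export
detect_puncta <- function(projection, prominence = 20, subpixel = TRUE) {
  stopifnot(is.matrix(projection))
  if (!is.numeric(prominence) || prominence <= 0)
    stop("prominence must be > 0")
  nr <- nrow(projection); nc <- ncol(projection)
  empty <- data.frame(y_px = numeric(), x_px = numeric(),
                      peak = numeric(), prominence = numeric())
  if (nr < 3L || nc < 3L) return(empty)

  # local maxima (>= all 8 neighbours), screened to peak value >= prominence
  # above the image minimum
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- projection
  ismax <- matrix(TRUE, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    ismax <- ismax & projection >= pad[(2:(nr + 1L)) + dy, (2:(nc + 1L)) + dx]
  }
  base <- min(projection)
  cand <- which(ismax & (projection - base) >= prominence)
  if (!length(cand)) return(empty)
  cv <- projection[cand]
  ord <- order(-cv, cand)
  cand <- cand[ord]; cv <- cv[ord]

  claimed <- logical(nr * nc)
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    if (claimed[cand[k]]) next
    v <- cv[k]
    level <- v - prominence
    # flood the 8-connected region of pixels with value > level
    visited <- logical(nr * nc)
    queue <- cand[k]; visited[queue] <- TRUE
    qi <- 1L; higher <- FALSE
    while (qi <= length(queue)) {
      p <- queue[qi]; qi <- qi + 1L
      py <- ((p - 1L) %% nr) + 1L; px <- ((p - 1L) %/% nr) + 1L
      for (dy in -1:1) for (dx in -1:1) {
        if (dy == 0L && dx == 0L) next
        ny <- py + dy; nx <- px + dx
        if (ny < 1L || ny > nr || nx < 1L || nx > nc) next
        q <- (nx - 1L) * nr + ny
        if (visited[q]) next
        val <- projection[q]
        if (val > v) { higher <- TRUE; break }
        if (val > level) { visited[q] <- TRUE; queue <- c(queue, q) }
      }
      if (higher) break
    }
    if (!higher) {
      keep[k] <- TRUE
      claimed[queue] <- TRUE   # absorb plateau/shoulder maxima of this peak
    }
  }
  cand <- cand[keep]; cv <- cv[keep]
  if (!length(cand)) return(empty)

  py <- ((cand - 1L) %% nr) + 1L
  px <- ((cand - 1L) %/% nr) + 1L
  y_sub <- as.numeric(py); x_sub <- as.numeric(px)
  if (subpixel) {
    for (k in seq_along(cand)) {
      iy <- max(1L, py[k] - 2L):min(nr, py[k] + 2L)
      ix <- max(1L, px[k] - 2L):min(nc, px[k] + 2L)
      w <- projection[iy, ix, drop = FALSE]
      w <- pmax(w - min(w), 0)
      if (sum(w) > 0) {
        y_sub[k] <- sum(iy * rowSums(w)) / sum(w)
        x_sub[k] <- sum(ix * colSums(w)) / sum(w)
      }
    }
  }
  # reported prominence: height of the peak above the image base level
  # (every kept peak additionally cleared the flood test at the threshold)
  data.frame(y_px = y_sub, x_px = x_sub, peak = cv, prominence = cv - base)
}
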