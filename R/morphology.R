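## Super-resolved cluster morphometry: colocalisation filtering, FWHM
## sizing by 1D Gaussian fitting, and circularity via the shape factor
## 4*pi*A/p^2.

#' Ratio between FWHM and standard deviation of a Gaussian
#'
#' `2 * sqrt(2 * ln 2)`, approximately 2.355.
#' @return The constant.
#' @export
fwhm_sigma_ratio <- function() 2 * sqrt(2 * log(2))

#' Convert a Gaussian standard deviation to FWHM
#' @param sigma Standard deviation (any length unit).
#' @return FWHM in the same unit.
#' @export
fwhm_from_sigma <- function(sigma) fwhm_sigma_ratio() * sigma

#' Convert a measured FWHM to the cluster diameter
#'
#' Uses the sizing relation `FWHM = 2 * sqrt(2 ln 2) * d ~ 2.355 d`, i.e.
#' `d = FWHM / 2.355`.
#'
#' @param fwhm FWHM in nm (non-negative).
#' @return Diameter in nm.
#' @export
fwhm_to_diameter <- function(fwhm) {
  if (any(fwhm < 0)) stop("FWHM must be non-negative")
  fwhm / fwhm_sigma_ratio()
}

#' Circularity (shape factor) from area and perimeter
#'
#' `4 * pi * A / p^2`, equal to 1 for a circle and smaller for any other
#' shape; values marginally above 1 (possible for discretised perimeter
#' estimates) are capped at 1.
#'
#' @param area,perimeter Area and perimeter in consistent units.
#' @param cap Cap values at 1 (default `TRUE`).
#' @return Shape factor in (0, 1] (capped) or the raw ratio.
#' @export
circularity <- function(area, perimeter, cap = TRUE) {
  if (any(area <= 0) || any(perimeter <= 0))
    stop("area and perimeter must be positive")
  sf <- 4 * pi * area / perimeter^2
  if (cap) pmin(sf, 1) else sf
}

## --- marching-squares sub-pixel contour ---------------------------------

# connected edges per marching-squares case (corners: TL=1 TR=2 BL=4 BR=8,
# crossings at edge midpoints of binary data); saddles carry two segments
.MS_CONN <- list(
  `1` = list(c("L", "T")), `2` = list(c("T", "R")), `3` = list(c("L", "R")),
  `4` = list(c("B", "L")), `5` = list(c("B", "T")),
  `6` = list(c("T", "L"), c("B", "R")),
  `7` = list(c("B", "R")), `8` = list(c("R", "B")),
  `9` = list(c("T", "R"), c("B", "L")),
  `10` = list(c("T", "B")), `11` = list(c("L", "B")),
  `12` = list(c("R", "L")), `13` = list(c("R", "T")),
  `14` = list(c("T", "L")))

# trace the outer iso-0.5 contour of a binary mask; returns ordered
# vertices (row, col) at edge midpoints of the padded pixel grid
.trace_contour <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(0L, nr + 2L, nc + 2L)
  m[2:(nr + 1L), 2:(nc + 1L)] <- mask * 1L
  cell_case <- function(i, j)
    m[i, j] + 2L * m[i, j + 1L] + 4L * m[i + 1L, j] + 8L * m[i + 1L, j + 1L]
  exit_for <- function(case, entry) {
    for (pr in .MS_CONN[[as.character(case)]]) {
      if (pr[1L] == entry) return(pr[2L])
      if (pr[2L] == entry) return(pr[1L])
    }
    NA_character_
  }
  mid <- function(i, j, e) switch(e,
    T = c(i, j + 0.5), B = c(i + 1, j + 0.5),
    L = c(i + 0.5, j), R = c(i + 0.5, j + 1))
  step <- function(i, j, e) switch(e,
    T = list(i - 1L, j, "B"), B = list(i + 1L, j, "T"),
    L = list(i, j - 1L, "R"), R = list(i, j + 1L, "L"))
  # first boundary cell in raster order
  start <- NULL
  for (ii in seq_len(nrow(m) - 1L)) {
    for (jj in seq_len(ncol(m) - 1L)) {
      cs <- cell_case(ii, jj)
      if (cs > 0L && cs < 15L) { start <- c(ii, jj); break }
    }
    if (!is.null(start)) break
  }
  if (is.null(start)) stop("empty mask")
  i <- start[1L]; j <- start[2L]
  cs <- cell_case(i, j)
  e_entry <- NA_character_
  for (cand in c("T", "L", "B", "R"))
    if (!is.na(exit_for(cs, cand))) { e_entry <- cand; break }
  i_s <- i; j_s <- j; e_s <- e_entry
  verts <- matrix(NA_real_, 4L * (nr + nc) * 4L, 2L)
  n <- 0L
  repeat {
    e_exit <- exit_for(cell_case(i, j), e_entry)
    n <- n + 1L
    if (n > nrow(verts)) verts <- rbind(verts, verts)
    verts[n, ] <- mid(i, j, e_exit)
    nx <- step(i, j, e_exit)
    i <- nx[[1L]]; j <- nx[[2L]]; e_entry <- nx[[3L]]
    if (i == i_s && j == j_s && identical(e_entry, e_s)) break
    if (n > 16L * (nr + 2L) * (nc + 2L)) stop("contour tracing failed")
  }
  verts[seq_len(n), , drop = FALSE]
}

# circular moving-average smoothing of a closed polygon
.smooth_closed <- function(v, w = 5L) {
  n <- nrow(v)
  if (n < w) return(v)
  k <- (w - 1L) %/% 2L
  out <- v * 0
  for (s in -k:k) out <- out + v[((seq_len(n) - 1L + s) %% n) + 1L, ]
  out / w
}

.polygon_length <- function(v) {
  d <- diff(rbind(v, v[1L, , drop = FALSE]))
  sum(sqrt(rowSums(d^2)))
}

#' Shape factor of a binary cluster mask
#'
#' Area is the pixel count times the pixel area; the perimeter is the
#' length of the sub-pixel marching-squares contour (iso-level 0.5),
#' smoothed with a 5-point circular moving average to suppress the
#' staircase overestimate of pixel-edge perimeters.  The shape factor is
#' `4 pi A / p^2`, capped at 1.
#'
#' @param mask Binary (logical or 0/1) matrix; must be non-empty, connected
#'   and contain at least 4 pixels.
#' @param pixel_size Pixel edge length (e.g. nm/px); default 1 returns
#'   pixel units.
#' @return List: `area`, `perimeter` (in `pixel_size` units), `shape_factor`
#'   (capped), `shape_factor_raw`.
#' @export
shape_factor <- function(mask, pixel_size = 1) {
  mask <- (mask > 0) * 1L
  npx <- sum(mask)
  if (npx == 0L) stop("empty mask")
  if (npx < 4L) stop("mask must contain at least 4 pixels")
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask)))
  if (max(lab) > 1L) stop("mask must be a single connected component")
  v <- .trace_contour(mask)
  p <- .polygon_length(.smooth_closed(v, 5L)) * pixel_size
  a <- npx * pixel_size^2
  raw <- 4 * pi * a / p^2
  list(area = a, perimeter = p, shape_factor = min(raw, 1),
       shape_factor_raw = raw)
}

#' Fraction of spherical clusters
#'
#' Fraction of clusters whose (capped) shape factor is at least
#' `1 - tolerance`.  The default tolerance 1e-3 suits analytic or capped
#' values; rasterised masks carry discretisation error and are typically
#' assessed with a wider tolerance (e.g. 0.05).
#'
#' @param shape_factors Numeric vector of shape factors (or a data.frame
#'   with a `shape_factor` column).
#' @param tolerance Non-negative tolerance below 1.
#' @return Fraction in `[0, 1]`.
#' @export
spherical_fraction <- function(shape_factors, tolerance = 1e-3) {
  if (is.data.frame(shape_factors)) shape_factors <- shape_factors$shape_factor
  if (length(shape_factors) == 0L) stop("empty shape-factor set")
  mean(shape_factors >= 1 - tolerance)
}

## --- colocalisation ------------------------------------------------------

#' Threshold a reference-channel image into ROIs
#'
#' The reference (e.g. widefield MyD88-YFP) image is thresholded (Otsu by
#' default), connected components are labelled, and a bounding-box ROI with
#' a margin is drawn around each.
#'
#' @param reference_image 2D numeric matrix.
#' @param threshold Intensity threshold; `NULL` for Otsu.
#' @param margin_px Margin added around each bounding box, px.
#' @param min_area_px Components smaller than this are discarded.
#' @return data.frame of ROIs: `roi_id`, `y0`, `y1`, `x0`, `x1` (1-based,
#'   inclusive pixel bounds).  No foreground gives zero rows.
#' @export
threshold_reference_rois <- function(reference_image, threshold = NULL,
                                     margin_px = 2L, min_area_px = 1L) {
  stopifnot(is.matrix(reference_image))
  empty <- data.frame(roi_id = integer(), y0 = integer(), y1 = integer(),
                      x0 = integer(), x1 = integer())
  if (diff(range(reference_image)) == 0) return(empty)
  if (is.null(threshold)) threshold <- .otsu_threshold(reference_image)
  bin <- reference_image > threshold
  if (!any(bin)) return(empty)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin * 1)))
  n <- max(lab)
  rois <- lapply(seq_len(n), function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    if (nrow(idx) < min_area_px) return(NULL)
    data.frame(roi_id = l,
               y0 = max(1L, min(idx[, 1L]) - margin_px),
               y1 = min(nrow(reference_image), max(idx[, 1L]) + margin_px),
               x0 = max(1L, min(idx[, 2L]) - margin_px),
               x1 = min(ncol(reference_image), max(idx[, 2L]) + margin_px))
  })
  rois <- do.call(rbind, rois)
  if (is.null(rois)) return(empty)
  rois$roi_id <- seq_len(nrow(rois))
  rois
}

#' Flag clusters colocalised with reference-channel ROIs
#'
#' A cluster is colocalised when its centroid lies inside any ROI; only
#' colocalised clusters correspond to genuine signal and enter downstream
#' statistics.
#'
#' @param centroids data.frame with `y_px`, `x_px` cluster centroids (same
#'   coordinate frame as the ROIs).
#' @param rois ROIs from [threshold_reference_rois()].
#' @return Logical vector, one flag per cluster.
#' @export
colocalise_clusters <- function(centroids, rois) {
  if (nrow(centroids) == 0L) return(logical())
  vapply(seq_len(nrow(centroids)), function(i) {
    any(centroids$y_px[i] >= rois$y0 & centroids$y_px[i] <= rois$y1 &
          centroids$x_px[i] >= rois$x0 & centroids$x_px[i] <= rois$x1)
  }, logical(1L))
}

## --- FWHM sizing ---------------------------------------------------------

#' Fit a 1D Gaussian to an intensity profile
#'
#' Least-squares fit of `a * exp(-(x - c)^2 / (2 s^2)) + o` to the profile,
#' initialised from the profile's peak and second moment.
#'
#' @param profile Numeric vector of intensities (length >= 5) with a single
#'   dominant peak.
#' @param pixel_size Length per sample (e.g. nm/px); FWHM is also reported
#'   in this unit.
#' @return A `gaussian_fit`: `amplitude`, `centre` (samples), `sigma`
#'   (samples), `offset`, `fwhm` (in `pixel_size` units), `sigma_scaled`.
#' @export
fit_fwhm <- function(profile, pixel_size = 1) {
  profile <- as.numeric(profile)
  if (length(profile) < 5L) stop("profile must have at least 5 samples")
  if (sd(profile) == 0) stop("flat profile: no peak to fit")
  x <- seq_along(profile)
  o0 <- min(profile); a0 <- max(profile) - o0
  c0 <- x[which.max(profile)]
  w <- pmax(profile - o0, 0)
  s0 <- sqrt(sum(w * (x - c0)^2) / sum(w))
  s0 <- max(s0, 0.5)
  resid_fn <- function(p)
    p[1L] * exp(-(x - p[2L])^2 / (2 * p[3L]^2)) + p[4L] - profile
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(a0, c0, s0, o0), fn = resid_fn,
                       lower = c(0, min(x) - 1, 0.1, -Inf),
                       upper = c(Inf, max(x) + 1, length(profile), Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gaussian fit did not converge: ",
                             conditionMessage(e)))
  if (fit$info %in% c(0L, 9L))
    stop("Gaussian fit did not converge: ", fit$message)
  cf <- fit$par
  structure(list(amplitude = cf[1L], centre = cf[2L],
                 sigma = cf[3L], offset = cf[4L],
                 sigma_scaled = cf[3L] * pixel_size,
                 fwhm = fwhm_from_sigma(cf[3L]) * pixel_size),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("1D Gaussian fit: amplitude %.3g, centre %.3g, sigma %.3g, FWHM %.4g\n",
              x$amplitude, x$centre, x$sigma, x$fwhm))
  invisible(x)
}

## --- group summaries -----------------------------------------------------

#' Summarise cluster sizes by condition and time point
#'
#' Per (condition, timepoint) group: n, mean and median FWHM and diameter;
#' plus an unpaired two-sided two-sample t-test between the two conditions
#' at every shared time point.  Groups with fewer than 2 clusters are
#' excluded from testing.
#'
#' @param morphologies data.frame with columns `condition`, `timepoint`,
#'   `fwhm_nm` (and optionally `diameter_nm`; derived from FWHM if absent).
#' @return List with `summary` (one row per condition x timepoint) and
#'   `tests` (one row per time point with both conditions present:
#'   `timepoint`, `mean_diff_nm`, `t`, `df`, `p.value`).
#' @export
size_by_timepoint <- function(morphologies) {
  req <- c("condition", "timepoint", "fwhm_nm")
  if (!all(req %in% names(morphologies)))
    stop("need columns: ", paste(req, collapse = ", "))
  m <- morphologies
  if (is.null(m$diameter_nm)) m$diameter_nm <- fwhm_to_diameter(m$fwhm_nm)
  grp <- interaction(m$condition, m$timepoint, drop = TRUE)
  summ <- do.call(rbind, lapply(split(m, grp), function(g)
    data.frame(condition = g$condition[1L], timepoint = g$timepoint[1L],
               n = nrow(g),
               mean_fwhm_nm = mean(g$fwhm_nm),
               median_fwhm_nm = median(g$fwhm_nm),
               mean_diameter_nm = mean(g$diameter_nm),
               median_diameter_nm = median(g$diameter_nm))))
  summ <- summ[order(summ$timepoint, summ$condition), , drop = FALSE]
  rownames(summ) <- NULL

  conds <- unique(m$condition)
  tests <- NULL
  if (length(conds) == 2L) {
    for (tp in unique(m$timepoint)) {
      a <- m$fwhm_nm[m$condition == conds[1L] & m$timepoint == tp]
      b <- m$fwhm_nm[m$condition == conds[2L] & m$timepoint == tp]
      if (length(a) < 2L || length(b) < 2L) next
      tt <- t.test(a, b, var.equal = FALSE)
      tests <- rbind(tests, data.frame(
        timepoint = tp, mean_diff_nm = mean(a) - mean(b),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p.value = tt$p.value))
    }
  }
  if (is.null(tests))
    tests <- data.frame(timepoint = character(), mean_diff_nm = numeric(),
                        t = numeric(), df = numeric(), p.value = numeric())
  list(summary = summ, tests = tests)
}
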