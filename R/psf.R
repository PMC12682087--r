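# Geometric-optics PSF: wavefront slopes give transverse ray aberrations; the
# PSF is the 2D histogram of ray intersections with the image plane, in
# angular (arcmin) coordinates.

RAD_TO_ARCMIN <- 180 / pi * 60

#' Wavefront slope field (transverse ray aberrations)
#'
#' Differentiates the OPD with respect to pupil position by central differences
#' (one-sided at the square-grid edges).  With OPD in micrometres and pupil
#' coordinates in mm, the derivative times 1e-3 is the ray angle in radians.
#'
#' @param w A `wavefront_map`.
#' @return A `slope_field` with matrices `slope_x`, `slope_y` (radians) on the
#'   same grid.
#' @export
wavefront_slopes <- function(w) {
  if (!inherits(w, "wavefront_map")) stop("`w` must be a wavefront_map")
  g <- w$grid
  n <- g$resolution
  if (n < 3L) stop("grid too coarse to differentiate (resolution < 3)")
  h <- g$step  # mm
  opd <- w$opd
  ddim <- function(m, along) {
    # central differences along rows (along = 1) or columns (along = 2)
    if (along == 2L) m <- t(m)
    d <- m
    d[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * h)
    d[1, ] <- (m[2, ] - m[1, ]) / h
    d[n, ] <- (m[n, ] - m[n - 1, ]) / h
    if (along == 2L) t(d) else d
  }
  # x varies along rows, y along columns (see pupil_grid)
  structure(list(grid = g,
                 slope_x = ddim(opd, 1L) * 1e-3,
                 slope_y = ddim(opd, 2L) * 1e-3),
            class = "slope_field")
}

#' @export
print.slope_field <- function(x, ...) {
  sx <- x$slope_x[x$grid$mask]; sy <- x$slope_y[x$grid$mask]
  cat(sprintf("<slope_field> max |slope| %.3g mrad over %d rays\n",
              max(sqrt(sx^2 + sy^2)) * 1e3, sum(x$grid$mask)))
  invisible(x)
}

#' Geometric PSF as a ray-intersection histogram
#'
#' Each in-pupil sample launches one ray landing at angular position
#' (slope_x, slope_y); the PSF is the 2D histogram of landing positions over a
#' square field of view.  Rays outside the field are counted separately and
#' never silently dropped, so in-field + out-of-field always equals the number
#' of in-pupil samples.
#'
#' @param slopes A `slope_field`.
#' @param bins Number of histogram bins per axis; odd and >= 3 so that a
#'   central bin exists (default 255).
#' @param half_width Angular half-extent of the field in arcmin (default 30).
#' @return A `geometric_psf` with `counts` (bins x bins integer matrix, first
#'   index = x), `bin_width` and `half_width` (arcmin), `rays_total` and
#'   `out_of_field`.
#' @export
geometric_psf <- function(slopes, bins = 255L, half_width = 30) {
  if (!inherits(slopes, "slope_field")) stop("`slopes` must be a slope_field")
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 3L || bins %% 2L == 0L) {
    stop("`bins` must be an odd integer >= 3 (so a central bin exists)")
  }
  if (!is.numeric(half_width) || half_width <= 0) {
    stop("`half_width` must be positive (arcmin)")
  }
  mask <- slopes$grid$mask
  tx <- slopes$slope_x[mask] * RAD_TO_ARCMIN
  ty <- slopes$slope_y[mask] * RAD_TO_ARCMIN
  bw <- 2 * half_width / bins
  ix <- floor((tx + half_width) / bw) + 1
  iy <- floor((ty + half_width) / bw) + 1
  # a ray exactly on the +half_width edge belongs to the last bin
  ix[tx == half_width] <- bins
  iy[ty == half_width] <- bins
  inf <- ix >= 1 & ix <= bins & iy >= 1 & iy <= bins
  counts <- matrix(0L, bins, bins)
  if (any(inf)) {
    tab <- tabulate((ix[inf] - 1L) + (iy[inf] - 1L) * bins + 1L,
                    nbins = bins * bins)
    counts <- matrix(as.integer(tab), bins, bins)
  }
  out <- sum(!inf)
  if (out == length(tx) && length(tx) > 0) {
    message("geometric_psf: all rays landed outside the field of view")
  }
  structure(list(counts = counts, bin_width = bw, half_width = half_width,
                 rays_total = length(tx), out_of_field = out),
            class = "geometric_psf")
}

#' @export
print.geometric_psf <- function(x, ...) {
  cat(sprintf(
    "<geometric_psf> %d x %d bins, +/-%.3g arcmin, %d rays (%d out of field)\n",
    nrow(x$counts), ncol(x$counts), x$half_width, x$rays_total, x$out_of_field))
  invisible(x)
}

#' Compute a geometric PSF straight from a wavefront
#'
#' Convenience wrapper: slopes then histogram.
#' @inheritParams geometric_psf
#' @param w A `wavefront_map`.
#' @export
psf_from_wavefront <- function(w, bins = 255L, half_width = 30) {
  geometric_psf(wavefront_slopes(w), bins = bins, half_width = half_width)
}
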