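#' Square-sampled circular pupil grid
#'
#' Builds a Cartesian sampling grid over a circular pupil aperture.  The grid
#' is a `resolution` x `resolution` square of sample points spanning the pupil
#' diameter; samples outside the circular aperture are masked out and never
#' contribute rays downstream.
#'
#' @param diameter Pupil diameter in mm (> 0).
#' @param resolution Number of samples across the diameter (integer >= 16).
#' @return An object of class `pupil_grid` with components `diameter`,
#'   `resolution`, `x`, `y` (square matrices of sample coordinates in mm,
#'   centred on the pupil axis) and `mask` (logical matrix, `TRUE` for samples
#'   inside the aperture, i.e. x^2 + y^2 <= (diameter/2)^2).
#' @examples
#' pg <- pupil_grid(6, 64)
#' sum(pg$mask) / pg$resolution^2  # ~ pi/4 fill factor
#' @export
pupil_grid <- function(diameter, resolution = 256L) {
  if (!is.numeric(diameter) || length(diameter) != 1L || !is.finite(diameter) ||
      diameter <= 0) {
    stop("`diameter` must be a single positive finite number (mm)")
  }
  resolution <- as.integer(resolution)
  if (is.na(resolution) || resolution < 16L) {
    stop("`resolution` must be an integer >= 16 samples per diameter")
  }
  r <- diameter / 2
  ax <- seq(-r, r, length.out = resolution)
  x <- matrix(ax, resolution, resolution)            # varies along rows
  y <- matrix(ax, resolution, resolution, byrow = TRUE)
  mask <- (x^2 + y^2) <= r^2 + 1e-12
  structure(
    list(diameter = diameter, resolution = resolution, x = x, y = y,
         mask = mask, step = ax[2] - ax[1]),
    class = "pupil_grid"
  )
}

#' @export
print.pupil_grid <- function(x, ...) {
  cat(sprintf("<pupil_grid> diameter %.3g mm, %d x %d samples (%d in pupil)\n",
              x$diameter, x$resolution, x$resolution, sum(x$mask)))
  invisible(x)
}

is_pupil_grid <- function(x) inherits(x, "pupil_grid")

new_wavefront_map <- function(grid, opd, wavelength = 570) {
  stopifnot(is_pupil_grid(grid), is.matrix(opd),
            all(dim(opd) == c(grid$resolution, grid$resolution)))
  if (any(!is.finite(opd[grid$mask]))) {
    stop("OPD must be finite at every in-pupil sample")
  }
  structure(list(grid = grid, opd = opd, wavelength = wavelength),
            class = "wavefront_map")
}

#' @export
print.wavefront_map <- function(x, ...) {
  opd <- x$opd[x$grid$mask]
  cat(sprintf(
    "<wavefront_map> %.3g mm pupil, OPD range [%.4g, %.4g] um, %g nm\n",
    x$grid$diameter, min(opd), max(opd), x$wavelength))
  invisible(x)
}
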