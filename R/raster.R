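# Grayscale image rasters for PSF presentation: max-normalized intensity in
# [0, 1], optional polarity inversion (computed PSFs are shown dark-on-light
# to match hand-drawn appearance), and angular rescaling so that images of
# different fields of view can be compared at equal visual angles.

#' Construct an image raster
#'
#' @param pixels Numeric matrix with values in `[0, 1]`.
#' @param scale Angular extent per pixel (arcmin).
#' @param polarity `"light_on_dark"` (intensity map) or `"dark_on_light"`
#'   (inverted, ink-like).
#' @return An `image_raster`.
#' @export
image_raster <- function(pixels, scale, polarity = "light_on_dark") {
  polarity <- match.arg(polarity, c("light_on_dark", "dark_on_light"))
  if (!is.matrix(pixels) || any(!is.finite(pixels)) ||
      any(pixels < -1e-12) || any(pixels > 1 + 1e-12)) {
    stop("pixels must be a finite matrix with values in [0, 1]")
  }
  pixels[pixels < 0] <- 0; pixels[pixels > 1] <- 1
  structure(list(pixels = pixels, scale = scale, polarity = polarity),
            class = "image_raster")
}

#' Invert raster polarity
#'
#' Maps intensity v to 1 - v and flips the polarity tag; applying it twice is
#' the identity.
#' @param img An `image_raster`.
#' @export
invert_raster <- function(img) {
  stopifnot(inherits(img, "image_raster"))
  image_raster(1 - img$pixels, img$scale,
               if (img$polarity == "light_on_dark") "dark_on_light"
               else "light_on_dark")
}

# Bilinear resampling of a raster onto a grid spanning a new half-width, same
# pixel count.  Coordinates are angular, centred; outside the source field the
# background value is used.
resample_raster <- function(img, target_half_width, background = NULL) {
  p <- img$pixels
  n <- nrow(p)
  if (is.null(background)) {
    background <- if (img$polarity == "dark_on_light") 1 else 0
  }
  src_hw <- n * img$scale / 2
  cen <- (n + 1) / 2
  new_scale <- 2 * target_half_width / n
  # angular coordinate of output pixel i: (i - cen) * new_scale
  pos <- ((seq_len(n) - cen) * new_scale) / img$scale + cen  # source pixel units
  i0 <- floor(pos); fr <- pos - i0
  get_row <- function(idx) {
    out <- matrix(background, length(idx), n)
    ok <- idx >= 1 & idx <= n
    out[ok, ] <- p[idx[ok], , drop = FALSE]
    out
  }
  rows <- get_row(i0) * (1 - fr) + get_row(i0 + 1L) * fr
  cols0 <- floor(pos); frc <- pos - cols0
  get_col <- function(m, idx) {
    out <- matrix(background, nrow(m), length(idx))
    ok <- idx >= 1 & idx <= n
    out[, ok] <- m[, idx[ok], drop = FALSE]
    out
  }
  out <- get_col(rows, cols0) * rep(1 - frc, each = n) +
    get_col(rows, cols0 + 1L) * rep(frc, each = n)
  image_raster(out, new_scale, img$polarity)
}

#' Render a geometric PSF as a grayscale raster
#'
#' Normalizes the histogram counts by their maximum, optionally inverts to
#' dark-on-light, and (optionally) resamples so the raster spans a target
#' angular half-width — used to equate visual angles across stimuli.
#'
#' @param psf A `geometric_psf`.
#' @param invert If `TRUE` (default), render dark-on-light.
#' @param target_half_width Optional half-width in arcmin to resample to.
#' @return An `image_raster`.
#' @export
render_psf <- function(psf, invert = TRUE, target_half_width = NULL) {
  stopifnot(inherits(psf, "geometric_psf"))
  tot <- sum(psf$counts)
  if (tot == 0) stop("cannot render a PSF with zero in-field counts")
  img <- image_raster(psf$counts / max(psf$counts), psf$bin_width,
                      "light_on_dark")
  if (invert) img <- invert_raster(img)
  if (!is.null(target_half_width)) {
    img <- resample_raster(img, target_half_width)
  }
  img
}
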