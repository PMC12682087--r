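# Zernike polynomials, OSA/ANSI single-index ordering, normalized so that each
# mode has unit RMS over the unit disc.  Aberrometer exports differ in ordering
# conventions; this package fixes OSA/ANSI single-index (j = 0, 1, 2, ...)
# with coefficients in micrometres.

#' OSA/ANSI single index to radial order and azimuthal frequency
#'
#' @param j Single index (integer >= 0), OSA/ANSI ordering.
#' @return List with integer vectors `n` (radial order) and `m` (signed
#'   azimuthal frequency); j = (n(n+2) + m)/2.
#' @export
zernike_nm <- function(j) {
  j <- as.integer(j)
  if (any(is.na(j) | j < 0L)) stop("Zernike index j must be >= 0")
  n <- as.integer(ceiling((-3 + sqrt(9 + 8 * j)) / 2))
  m <- as.integer(2L * j - n * (n + 2L))
  list(n = n, m = m)
}

# Radial polynomial R_n^{|m|}(rho); vectorized over rho.
zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  s_max <- (n - m) %/% 2
  out <- numeric(length(rho))
  for (s in 0:s_max) {
    coef <- (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s))
    out <- out + coef * rho^(n - 2 * s)
  }
  out
}

#' Evaluate a normalized Zernike mode
#'
#' Unit-RMS (Noll-normalized) Zernike polynomial in OSA/ANSI single-index
#' ordering, evaluated at polar pupil coordinates.
#'
#' @param j OSA/ANSI single index (scalar integer >= 0).
#' @param rho Normalized radial coordinate (pupil radius = 1); values > 1 are
#'   evaluated by polynomial continuation (used for square-grid corners).
#' @param theta Azimuthal angle in radians.
#' @return Numeric vector of mode values.
#' @export
zernike_eval <- function(j, rho, theta) {
  nm <- zernike_nm(j)
  n <- nm$n; m <- nm$m
  norm <- sqrt((2 * (n + 1)) / (1 + (m == 0)))
  rad <- zernike_radial(n, m, rho)
  ang <- if (m > 0) cos(m * theta) else if (m < 0) sin(-m * theta) else 1
  norm * rad * ang
}

#' Wavefront map from Zernike coefficients
#'
#' Builds the optical path difference (OPD) surface from a Zernike expansion
#' evaluated on unit-normalized pupil coordinates.  Coefficient `coeffs[i]`
#' multiplies OSA/ANSI mode index `i - 1`, so `coeffs[1]` is piston,
#' `coeffs[5]` is defocus (OSA index 4), etc.
#'
#' @param coeffs Numeric vector of Zernike coefficients in micrometres,
#'   OSA/ANSI single-index order starting at index 0 (piston).
#' @param pupil A [pupil_grid()].
#' @param wavelength Wavelength in nm (default 570, green LED).
#' @return A `wavefront_map` (OPD in micrometres on the pupil grid).
#' @examples
#' pg <- pupil_grid(6, 64)
#' w <- zernike_wavefront(c(0, 0, 0, 0, 0.5), pg)  # 0.5 um defocus
#' @export
zernike_wavefront <- function(coeffs, pupil, wavelength = 570) {
  if (!is_pupil_grid(pupil)) stop("`pupil` must be a pupil_grid")
  if (length(coeffs) == 0L) stop("coefficient list must be non-empty")
  bad <- which(!is.finite(coeffs))
  if (length(bad)) {
    stop(sprintf("non-finite Zernike coefficient at OSA index %d",
                 bad[1] - 1L))
  }
  r_pup <- pupil$diameter / 2
  rho <- sqrt(pupil$x^2 + pupil$y^2) / r_pup
  theta <- atan2(pupil$y, pupil$x)
  opd <- matrix(0, pupil$resolution, pupil$resolution)
  for (i in seq_along(coeffs)) {
    if (coeffs[i] != 0) {
      opd <- opd + coeffs[i] * zernike_eval(i - 1L, rho, theta)
    }
  }
  new_wavefront_map(pupil, opd, wavelength)
}
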