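# Optics engine: wavefront construction, slopes, and the ray-histogram PSF.

test_that("pupil_grid validates inputs and masks the aperture", {
  pg <- pupil_grid(6, 64)
  expect_true(all(pg$x[pg$mask]^2 + pg$y[pg$mask]^2 <= 9 + 1e-9))
  expect_error(pupil_grid(-1, 64), "positive")
  expect_error(pupil_grid(6, 8), ">= 16")
})

test_that("zernike_wavefront: zero, piston and defocus against the direct polynomial", {
  pg <- pupil_grid(6, 64)
  w0 <- zernike_wavefront(c(0, 0, 0, 0, 0), pg)
  expect_true(all(w0$opd == 0))

  # piston changes OPD but not the slopes
  wp <- zernike_wavefront(c(1), pg)
  expect_true(all(abs(wp$opd - sqrt(2) * 0) >= 0))  # constant field
  expect_equal(max(wp$opd) - min(wp$opd), 0)
  sp <- wavefront_slopes(wp)
  expect_true(all(sp$slope_x == 0) && all(sp$slope_y == 0))

  # defocus-only: OPD(rho) = sqrt(3) c (2 rho^2 - 1), checked pointwise
  cdef <- 0.7
  wd <- zernike_wavefront(c(0, 0, 0, 0, cdef), pg)
  rho <- sqrt(pg$x^2 + pg$y^2) / 3
  oracle <- sqrt(3) * cdef * (2 * rho^2 - 1)
  expect_equal(wd$opd[pg$mask], oracle[pg$mask], tolerance = 1e-12)

  expect_error(zernike_wavefront(c(0, NaN), pg), "index 1")
  expect_error(zernike_wavefront(numeric(0), pg), "non-empty")
})

test_that("profile_wavefront: closed forms and the piecewise integral oracle", {
  pg <- pupil_grid(6, 64)
  # constant power P: W(r) = P r^2 / 2 exactly at every sample
  pr <- lens_profile(r_max = 3, zones = data.frame(inner = 0, outer = 3,
                                                   power = 2.5))
  w <- profile_wavefront(pr, pg)
  r2 <- pmin(pg$x^2 + pg$y^2, 9)
  expect_equal(w$opd, matrix(2.5 * r2 / 2, 64, 64), tolerance = 1e-14)

  # P = 0 -> flat
  p0 <- lens_profile(r_max = 3, zones = data.frame(inner = 0, outer = 3,
                                                   power = 0))
  expect_true(all(profile_wavefront(p0, pg)$opd == 0))

  # two-zone dual focus: symbolic integral is piecewise quadratic,
  # continuous at r1
  r1 <- 1.5; add <- 2
  dz <- lens_profile(r_max = 3, zones = data.frame(
    inner = c(0, r1), outer = c(r1, 3), power = c(0, add)))
  wz <- profile_wavefront(dz, pg)
  r <- sqrt(r2)
  oracle <- ifelse(r <= r1, 0, add * (r^2 - r1^2) / 2)
  expect_equal(as.vector(wz$opd), as.vector(oracle), tolerance = 1e-12)

  # functional profile path agrees with the zonal closed form
  fn <- lens_profile(power = function(r) rep(2.5, length(r)), r_max = 3)
  # trapezoid quadrature of the quadratic integrand: error O(h^2) ~ 1e-7
  expect_equal(profile_wavefront(fn, pg)$opd, w$opd, tolerance = 1e-6)

  short <- lens_profile(r_max = 1, zones = data.frame(inner = 0, outer = 1,
                                                      power = 1))
  expect_error(profile_wavefront(short, pg), "undefined inside pupil")
})

test_that("wavefront_slopes: flat, tilt plane, and the defocus analytic gradient", {
  pg <- pupil_grid(6, 64)
  flat <- zernike_wavefront(0, pg)
  sf <- wavefront_slopes(flat)
  expect_true(all(sf$slope_x == 0) && all(sf$slope_y == 0))

  # W = a x (um, x in mm): slope_x = a * 1e-3 rad exactly for a linear field
  a <- 0.8
  wt <- flat; wt$opd <- a * pg$x
  st <- wavefront_slopes(wt)
  expect_equal(max(abs(st$slope_x - a * 1e-3)), 0, tolerance = 1e-12)
  expect_equal(max(abs(st$slope_y)), 0, tolerance = 1e-12)

  # defocus Delta: radial slope magnitude Delta * r (meters), < 1% at 256
  pg2 <- pupil_grid(6, 256)
  delta <- 1.5
  wd <- profile_wavefront(lens_profile(r_max = 3, zones = data.frame(
    inner = 0, outer = 3, power = delta)), pg2)
  sd_ <- wavefront_slopes(wd)
  r_mm <- sqrt(pg2$x^2 + pg2$y^2)
  interior <- pg2$mask & r_mm > 0.2 & r_mm < 2.8
  slope_mag <- sqrt(sd_$slope_x^2 + sd_$slope_y^2)
  expected <- delta * r_mm * 1e-3
  rel_err <- abs(slope_mag[interior] - expected[interior]) / expected[interior]
  expect_lt(max(rel_err), 0.01)
})

test_that("geometric_psf: delta case, blur disc closed form, preconditions", {
  pg <- pupil_grid(6, 64)
  flat <- wavefront_slopes(zernike_wavefront(0, pg))
  psf <- geometric_psf(flat, bins = 31, half_width = 10)
  expect_equal(sum(psf$counts), psf$rays_total)
  expect_equal(psf$counts[16, 16], sum(pg$mask))

  # 1.00 D over a 6 mm pupil: top-hat disc of radius ~10.31 arcmin
  pg2 <- pupil_grid(6, 256)
  w <- profile_wavefront(lens_profile(r_max = 3, zones = data.frame(
    inner = 0, outer = 3, power = 1)), pg2)
  psf2 <- geometric_psf(wavefront_slopes(w), bins = 255, half_width = 30)
  expect_equal(psf2$out_of_field, 0)
  bw <- psf2$bin_width
  centre <- (255 + 1) / 2
  hit <- which(psf2$counts > 0, arr.ind = TRUE)
  radius <- sqrt((hit[, 1] - centre)^2 + (hit[, 2] - centre)^2) * bw
  r_disc <- 3e-3 * (180 / pi * 60)  # 10.31 arcmin
  expect_lt(max(radius), r_disc + bw)        # support confined to the disc
  expect_gt(max(radius), r_disc - 2 * bw)    # and reaching its edge
  # approximately uniform fill: occupied bins well inside the disc
  inner <- radius < r_disc - 2 * bw
  counts_in <- psf2$counts[hit[inner, , drop = FALSE]]
  expect_gt(min(counts_in), 0)

  expect_error(geometric_psf(flat, bins = 4), "odd")
  expect_error(geometric_psf(flat, bins = 31, half_width = 0), "positive")
})

test_that("vectorized histogram equals the per-ray brute-force oracle", {
  set.seed(42)
  for (rep in 1:20) {
    pg <- pupil_grid(runif(1, 3, 7), 32)
    coeffs <- c(0, 0, 0, rnorm(9, 0, 0.4))
    sl <- wavefront_slopes(zernike_wavefront(coeffs, pg))
    bins <- sample(c(21L, 33L, 55L), 1)
    hw <- runif(1, 5, 20)
    psf <- geometric_psf(sl, bins = bins, half_width = hw)
    oracle <- brute_psf(sl, bins, hw)
    expect_identical(psf$counts, oracle$counts)
    expect_identical(psf$out_of_field, oracle$out_of_field)
    expect_equal(sum(psf$counts) + psf$out_of_field, sum(pg$mask))
  }
})

test_that("piston invariance and radial symmetry of the PSF", {
  pg <- pupil_grid(5.8, 128)
  w <- zernike_wavefront(c(0, 0, 0, 0.3, 0.5, 0.2, 0.1), pg)
  psf1 <- psf_from_wavefront(w, bins = 101, half_width = 20)
  w2 <- w; w2$opd <- w$opd + 3.7
  psf2 <- psf_from_wavefront(w2, bins = 101, half_width = 20)
  expect_identical(psf1$counts, psf2$counts)

  # radially symmetric wavefront: histogram symmetric under 90-degree rotation
  wd <- profile_wavefront(make_lens_profile("edof"), pg)
  psf <- psf_from_wavefront(wd, bins = 101, half_width = 20)
  rot <- t(psf$counts)[, ncol(psf$counts):1]
  # integer-count tolerance of the sampling grid: compare smoothed mass
  expect_lt(sum(abs(psf$counts - rot)) / sum(psf$counts), 0.06)
})

test_that("render_psf: inversion involution and resampling round-trip", {
  pg <- pupil_grid(6, 64)
  psf <- psf_from_wavefront(zernike_wavefront(0, pg), bins = 31,
                            half_width = 10)
  img <- render_psf(psf, invert = TRUE)
  # white field with a single dark pixel block
  expect_equal(sort(unique(as.vector(img$pixels))), c(0, 1))
  expect_equal(sum(img$pixels == 0), 1)
  expect_equal(invert_raster(invert_raster(img))$pixels, img$pixels)

  wa <- zernike_wavefront(c(0, 0, 0, 0.2, 0.4), pg)
  psf2 <- psf_from_wavefront(wa, bins = 31, half_width = 10)
  img2 <- render_psf(psf2, invert = FALSE)
  # magnify 2x then back 0.5x: sample positions land on exact pixels, so the
  # round trip must reproduce the direct identity resample
  round_trip <- psfmatch:::resample_raster(
    psfmatch:::resample_raster(img2, 10 / 2), 10)
  ident <- psfmatch:::resample_raster(img2, 10)
  expect_equal(round_trip$pixels, ident$pixels, tolerance = 1e-6)

  empty <- psf2; empty$counts[] <- 0L
  expect_error(render_psf(empty), "zero")
})
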