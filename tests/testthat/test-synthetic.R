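# Synthetic-data generators: lens designs, pupils, surrogate drawings,
# Likert and similarity simulation.

test_that("make_lens_profile: archetype shapes and zone validation", {
  sv <- make_lens_profile("single_vision", base_power = -0.25)
  expect_true(all(sv$power(seq(0, 4.5, 0.5)) == -0.25))

  dz <- make_lens_profile("dual_focus_zonal", base_power = 0, add_power = 2,
                          zone_radii = c(1.5, 2.5, 3.5))
  expect_equal(dz$power(2.0), 2)       # piecewise lookup oracle
  expect_equal(dz$power(1.0), 0)
  expect_equal(dz$power(3.0), 0)
  expect_equal(dz$power(4.0), 2)

  ed <- make_lens_profile("edof", base_power = -1, add_power = 2.5)
  expect_equal(ed$power(0), -1)
  expect_equal(ed$power(4.5), 1.5)

  cn <- make_lens_profile("centre_near_aspheric", base_power = 0,
                          add_power = 2)
  expect_equal(cn$power(0), 2)
  expect_equal(cn$power(4.5), 0, tolerance = 1e-12)
  cd <- make_lens_profile("centre_distance", base_power = 0, add_power = 2)
  expect_equal(cd$power(0), 0)
  expect_equal(cd$power(4.5), 2)

  expect_error(make_lens_profile("dual_focus_zonal",
                                 zone_radii = c(2, 1.5, 3)), "overlap")
  expect_error(make_lens_profile("edof", add_power = -1), ">= 0")
})

test_that("sample_pupils: degenerate SD, CLT bound, determinism", {
  cfg0 <- simulation_config(seed = 4, pupil_sd = 0)
  expect_true(all(sample_pupils(20, cfg0) == 5.82))

  cfg <- simulation_config(seed = 4)
  x <- sample_pupils(1e4, cfg)
  expect_true(all(x >= 2 & x <= 9))
  expect_lt(abs(mean(x) - 5.82), 3 * 1.05 / sqrt(1e4))
  expect_identical(x, sample_pupils(1e4, cfg))
})

test_that("surrogate_drawn_psf: noiseless support equality and error cases", {
  pg <- pupil_grid(5.8, 96)
  w <- profile_wavefront(make_lens_profile("dual_focus_zonal"), pg)
  psf <- psf_from_wavefront(w, bins = 63, half_width = 15)
  sur <- surrogate_drawn_psf(psf, sketch_noise = 0, seed = 1,
                             max_features = 1000L)
  inten <- psf$counts / max(psf$counts)
  thr <- quantile(inten[inten > 0], 0.5, names = FALSE)
  expect_identical(sur$pixels == 0, inten >= thr)
  expect_equal(sur$polarity, "dark_on_light")

  empty <- psf; empty$counts[] <- 0L
  expect_error(surrogate_drawn_psf(empty), "empty")
})

test_that("surrogate matching calibration: low noise recovers most matches", {
  # 15 distinct wavefronts -> surrogates at low noise -> NCC matcher
  cfg <- pipeline_config(seed = 11, grid_resolution = 64L, psf_bins = 63L,
                         psf_half_width = 20)
  eyes <- psfmatch:::build_image_wavefronts(cfg)
  psfs <- lapply(eyes, function(e) psf_from_wavefront(e$wavefront, 63L, 20))
  geo <- lapply(psfs, render_psf, invert = TRUE)
  acc <- vapply(c(0.2, 6), function(noise) {
    drawn <- lapply(seq_along(psfs), function(i) {
      surrogate_drawn_psf(psfs[[i]], sketch_noise = noise, seed = 100 + i)
    })
    ncc_match(drawn, geo)$n_correct
  }, integer(1))
  expect_gte(acc[1], 10)          # low noise: >= 10/15 correct
  expect_lte(acc[2], acc[1])      # heavy noise never helps
})

test_that("simulate_likert: exact limits and binomial consensus recovery", {
  truth <- simulate_feature_truth(15, 6)
  perfect <- simulate_likert(truth, simulation_config(seed = 6,
                                                      reliability = 1 - 1e-12,
                                                      fidelity = 1))
  st <- consensus_study(perfect$drawn, perfect$geometric)
  expect_true(all(st$pairs$q == 1))
  cv <- consensus_vector(perfect$geometric, 3)
  expect_equal(cv$bits, truth[3, ])

  # consensus recovery per bit ~ P(Bin(13, p) >= 7) at reliability p
  p <- 0.8
  rec <- mean(vapply(1:40, function(s) {
    tr <- simulate_feature_truth(5, s)
    lik <- simulate_likert(tr, simulation_config(seed = s, reliability = p,
                                                 fidelity = 1))
    mean(vapply(1:5, function(im) {
      mean(consensus_vector(lik$geometric, im)$bits == tr[im, ])
    }, numeric(1)))
  }, numeric(1)))
  expected <- pbinom(6, 13, p, lower.tail = FALSE)
  expect_lt(abs(rec - expected), 0.02)   # 40 x 65 bits: tight simulation CI

  # fidelity 0.5: drawn truth independent of geometric truth -> mean Q near 0
  qs <- vapply(1:25, function(s) {
    lik <- simulate_likert(simulate_feature_truth(8, s),
                           simulation_config(seed = s, reliability = 0.95,
                                             fidelity = 0.5))
    suppressWarnings(
      mean(consensus_study(lik$drawn, lik$geometric)$pairs$q, na.rm = TRUE))
  }, numeric(1))
  expect_lt(abs(mean(qs, na.rm = TRUE)), 0.2)  # some seeds: all pairs degenerate
})

test_that("simulate_similarity: exact diagonal, block ordering, reproducibility", {
  pl <- planted_configuration(10, 3, 13)
  cfg0 <- simulation_config(seed = 13, n_images = 10,
                            similarity_noise_sd = 0)
  st0 <- simulate_similarity(pl, cfg0)
  M <- mean_rating_matrix(st0, "D2D")
  expect_true(all(diag(M$S) == 10))

  cfg <- simulation_config(seed = 13, n_images = 10)
  st <- simulate_similarity(pl, cfg)
  d2g <- mean_rating_matrix(st, "D2G")
  d2d <- mean_rating_matrix(st, "D2D")
  # cross block uses the middle of the scale: higher off-diagonal mean,
  # lower diagonal mean than within-type blocks
  expect_gt(unname(d2g$off_diagonal["mean"]), unname(d2d$off_diagonal["mean"]))
  expect_lt(unname(d2g$diagonal["mean"]), unname(d2d$diagonal["mean"]))

  expect_identical(simulate_similarity(pl, cfg), st)
  expect_error(simulate_similarity(matrix(0, 5, 3), cfg), "degenerate")
})

test_that("simulate_study bundles a reproducible full study", {
  s1 <- simulate_study(simulation_config(seed = 9, n_images = 6,
                                         n_raters = 5))
  s2 <- simulate_study(simulation_config(seed = 9, n_images = 6,
                                         n_raters = 5))
  expect_identical(s1$similarity, s2$similarity)
  expect_identical(s1$truth, s2$truth)
  expect_length(s1$profiles, 5)
  expect_length(s1$pupils, 6)
})
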