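# Nonmetric MDS: dissimilarity conversion, SMACOF fits, stress properties,
# Shepard data, permutation test and bootstrap regions.

test_that("mean_rating_matrix: constants, averaging, and generator ordering", {
  mk <- function(ratings_by_rater) {
    rows <- do.call(rbind, lapply(seq_along(ratings_by_rater), function(r) {
      pairs <- expand.grid(image_a = 1:4, image_b = 1:4)
      pairs <- pairs[pairs$image_a <= pairs$image_b, ]
      data.frame(rater = r, pairs, block = "D2D",
                 rating = ratings_by_rater[[r]])
    }))
    similarity_study(rows)
  }
  const <- mk(list(rep(10L, 10), rep(10L, 10)))
  M <- mean_rating_matrix(const, "D2D")
  expect_true(all(M$S == 10))
  expect_equal(unname(M$diagonal["sd"]), 0)

  two <- mk(list(rep(4L, 10), rep(6L, 10)))
  expect_true(all(mean_rating_matrix(two, "D2D")$S == 5))

  # generator: positive self-boost makes the diagonal exceed the off-diagonal
  st <- simulate_similarity(planted_configuration(10, 3, 2),
                            simulation_config(seed = 2, n_images = 10))
  M2 <- mean_rating_matrix(st, "G2G")
  expect_gt(unname(M2$diagonal["mean"]), unname(M2$off_diagonal["mean"]))

  missing <- const[!(const$image_a == 1 & const$image_b == 3), ]
  class(missing) <- class(const)
  expect_error(mean_rating_matrix(missing, "D2D"), "no ratings for pair")
})

test_that("to_dissimilarity applies reverse scaling and is an involution", {
  S <- matrix(c(10, 4, 4, 10), 2) * 1.0
  S2 <- matrix(c(10, 1, 5, 1, 10, 2, 5, 2, 10), 3)
  d <- to_dissimilarity(S2)
  expect_equal(d$d, min(S2) + max(S2) - S2)
  expect_equal(unname(d$bounds), c(1, 10))
  # top of the scale maps to the observed minimum, not zero
  expect_equal(d$d[1, 1], 1)
  expect_equal(d$d[2, 1], 10)
  # involution under fixed bounds
  set.seed(9)
  R <- matrix(runif(25, 1, 10), 5); R <- (R + t(R)) / 2
  expect_equal(to_dissimilarity(to_dissimilarity(R)$d)$d, R,
               tolerance = 1e-12)
  expect_message(to_dissimilarity(matrix(5, 3, 3)), "constant")
})

test_that("smacof recovers a perfect metric configuration", {
  set.seed(20)
  X <- matrix(rnorm(10), 5, 2)
  D <- as.matrix(dist(X))
  fit <- smacof_nonmetric(D, 2)
  expect_lt(fit$stress1, 1e-6)
  expect_lt(procrustes_align(X, fit$coords)$residual, 1e-6)
  expect_equal(colMeans(fit$coords), c(0, 0), tolerance = 1e-9)
  # disparities nondecreasing in dissimilarity order
  ord <- order(fit$dissimilarities, fit$distances)
  expect_true(all(diff(fit$disparities[ord]) >= -1e-9))
  expect_error(smacof_nonmetric(D[1:4, 1:5], 2), "symmetric")
})

test_that("monotone distortion of a planted 3D configuration is undone", {
  set.seed(21)
  X <- matrix(rnorm(36), 12, 3)
  D <- as.matrix(dist(X))^2   # squared distances: monotone distortion
  fit <- smacof_best(D, 3, n_starts = 5, seed = 1)
  expect_lt(fit$stress1, 0.01)
  expect_gt(congruence_coefficient(X, fit$coords), 0.99)
})

test_that("stress decreases monotonically over iterations and matches multistart", {
  set.seed(22)
  D <- matrix(runif(64, 1, 10), 8); D <- (D + t(D)) / 2; diag(D) <- 0
  fit <- smacof_nonmetric(D, 2)
  expect_true(all(diff(fit$stress_trace) <= 1e-10))

  # 4-item instance: final stress within 1e-4 of the best of 200 restarts
  D4 <- matrix(c(0, 3, 5, 7, 3, 0, 4, 6, 5, 4, 0, 2, 7, 6, 2, 0), 4)
  ours <- smacof_best(D4, 2, n_starts = 10, seed = 1)$stress1
  ref <- min(vapply(1:200, function(k) {
    smacof_nonmetric(D4, 2, init = "random", seed = 1000 + k)$stress1
  }, numeric(1)))
  expect_lt(ours, ref + 1e-4)
})

test_that("stress is scale invariant and nonincreasing in dimension", {
  set.seed(23)
  D <- matrix(runif(100, 1, 10), 10); D <- (D + t(D)) / 2; diag(D) <- 0
  s1 <- smacof_nonmetric(D, 2)$stress1
  s2 <- smacof_nonmetric(3.7 * D, 2)$stress1
  expect_equal(s1, s2, tolerance = 1e-6)

  scan <- stress_dimension_scan(D, 1:4, n_starts = 3, seed = 1)
  expect_true(all(diff(scan$stress1) <= 1e-6))
  expect_equal(scan$fit_band,
               as.character(cut(scan$stress1, c(-Inf, 0.10, 0.20, Inf),
                                labels = c("excellent", "fair", "poor"))))
  expect_error(stress_dimension_scan(D, c(3, 2)), "ascending")

  # perfect 2D metric input: stress < 1e-6 at R = 2 and 3
  X <- matrix(rnorm(14), 7, 2)
  scan2 <- stress_dimension_scan(as.matrix(dist(X)), 2:3, n_starts = 2,
                                 seed = 1)
  expect_true(all(scan2$stress1 < 1e-6))
})

test_that("shepard_data reproduces the configuration stress and is monotone", {
  set.seed(24)
  D <- matrix(runif(81, 1, 10), 9); D <- (D + t(D)) / 2; diag(D) <- 0
  fit <- smacof_nonmetric(D, 2)
  sh <- shepard_data(D, fit)
  expect_true(all(diff(sh$disparity) >= -1e-9))
  expect_equal(attr(sh, "stress1"), fit$stress1, tolerance = 1e-10)

  # perfect fit: every point on the monotone line
  X <- matrix(rnorm(12), 6, 2)
  Dp <- as.matrix(dist(X))
  fp <- smacof_nonmetric(Dp, 2)
  shp <- shepard_data(Dp, fp)
  expect_equal(shp$distance, shp$disparity, tolerance = 1e-5)

  expect_error(shepard_data(D[1:5, 1:5], fit), "different number of items")
})

test_that("permutation test flags planted structure and bounds p from below", {
  set.seed(25)
  X <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(X))
  pt <- permutation_test(D, 2, n_perm = 99, seed = 4)
  expect_equal(pt$p_value, 0.01)     # minimum attainable with 99 permutations
  expect_length(pt$stress_null, 99)
  expect_error(permutation_test(D, 2, n_perm = 10), ">= 19")
})

test_that("null permutation p-values are roughly uniform (scaled-down calibration)", {
  # D itself a draw from the permutation null: p should not concentrate
  set.seed(26)
  pvals <- vapply(1:24, function(s) {
    D <- matrix(0, 6, 6)
    v <- sample(runif(15, 1, 10))
    D[lower.tri(D)] <- v
    permutation_test(D + t(D), 1, n_perm = 19, seed = s)$p_value
  }, numeric(1))
  expect_gt(mean(pvals), 0.25)
  expect_lt(mean(pvals), 0.85)
})

test_that("random_start_study: perfect input, classical bound, determinism", {
  set.seed(27)
  # small perfect-metric instance: every random start reaches the exact fit
  X4 <- matrix(rnorm(8), 4, 2)
  rs4 <- random_start_study(as.matrix(dist(X4)), 2, n_starts = 8, seed = 2,
                            tol = 1e-12, max_iter = 2000)
  # nonmetric MDS has genuine local minima even at n = 4: the best start (and
  # in practice most starts) reaches the exact fit, but not necessarily all
  expect_lt(rs4$best, 1e-6)
  expect_gt(mean(rs4$stresses < 1e-6), 0.5)

  # harder instance: spread reported, best bounded by the classical start
  X <- matrix(rnorm(16), 8, 2)
  D <- as.matrix(dist(X))
  rs <- random_start_study(D, 2, n_starts = 5, seed = 2)
  expect_lte(rs$best, rs$classical_stress + 1e-8)
  expect_true(rs$best <= rs$median && rs$median <= rs$worst)
  rs2 <- random_start_study(D, 2, n_starts = 5, seed = 2)
  expect_identical(rs, rs2)
})

test_that("bootstrap regions shrink to zero without rater noise and align to the reference", {
  cfg0 <- simulation_config(seed = 8, n_images = 8, n_raters = 6,
                            similarity_noise_sd = 0, self_boost = 0)
  st0 <- simulate_similarity(planted_configuration(8, 3, 8), cfg0)
  br <- bootstrap_regions(st0, "D2D", R = 2, n_boot = 12, seed = 1)
  expect_lt(max(vapply(br$covariances, function(C) max(abs(C)), numeric(1))),
            1e-10)
  # alignment removes global rotation: centers match the reference coords
  expect_equal(br$centers, unname(br$reference$coords), tolerance = 1e-4)

  cfg1 <- simulation_config(seed = 8, n_images = 8, n_raters = 6,
                            similarity_noise_sd = 0.75)
  st1 <- simulate_similarity(planted_configuration(8, 3, 8), cfg1)
  br1 <- bootstrap_regions(st1, "D2D", R = 2, n_boot = 12, seed = 1)
  vol <- function(b) mean(vapply(b$covariances, function(C) det(C),
                                 numeric(1)))
  expect_gt(vol(br1), vol(br))
})
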