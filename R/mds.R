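# Nonmetric multidimensional scaling by SMACOF majorization: alternate
# monotone (isotonic) regression of configuration distances onto the rank
# order of the input dissimilarities, and the Guttman-transform coordinate
# update.  Fit quality is Kruskal's stress-1,
#   stress1 = sqrt( sum_{i<j} (dhat_ij - rho_ij)^2 / sum_{i<j} rho_ij^2 ),
# with disparities dhat renormalized each pass so sum dhat^2 = sum rho^2.
# Conventional interpretation bands: > 0.20 poor, 0.10-0.20 fair,
# <= 0.10 excellent fit.

# lower-triangle (i < j) vector of a square matrix, column-major like dist()
lower_vec <- function(M) M[lower.tri(M)]

# Classical (Torgerson) scaling initial configuration.
torgerson_init <- function(Dm, R) {
  n <- nrow(Dm)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (Dm^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  lam <- pmax(e$values[seq_len(R)], 0)
  X <- e$vectors[, seq_len(R), drop = FALSE] %*% diag(sqrt(lam), R)
  X
}

dist_vec <- function(X) lower_vec(as.matrix(stats::dist(X)))

#' Nonmetric MDS by SMACOF majorization
#'
#' Embeds `n` items in `R` dimensions so that inter-point distances are
#' monotonically related to the rank order of the input dissimilarities.
#' Each pass (i) isotonically regresses the current configuration distances
#' onto the dissimilarity order (primary tie handling: ties may be untied),
#' normalizes disparities so their sum of squares equals that of the
#' distances, and (ii) applies the Guttman transform.  Iteration stops when
#' the stress-1 decrease falls below `tol`.
#'
#' @param D Dissimilarities: a [to_dissimilarity()] result, a `dist`, or a
#'   symmetric matrix.  The diagonal is ignored (self-dissimilarity is
#'   structurally zero).
#' @param R Target dimensionality (n >= R + 1).
#' @param init `"classical"` (Torgerson scaling, default) or `"random"`.
#' @param seed Seed used for random initialization (recorded in the result).
#' @param tol Convergence tolerance on the stress decrease (default 1e-6).
#' @param max_iter Maximum number of majorization passes (default 300).
#' @return An `mds_config`: list with `coords` (n x R, column-centred),
#'   `stress1`, `disparities`, `dissimilarities`, `distances` (lower-triangle
#'   vectors, `dist()` ordering), `stress_trace`, `iterations`, `converged`,
#'   `init`, `seed`, `R`.
#' @export
smacof_nonmetric <- function(D, R, init = c("classical", "random"),
                             seed = NULL, tol = 1e-6, max_iter = 300L) {
  Dm <- as_dissim_matrix(D)
  init <- match.arg(init)
  n <- nrow(Dm)
  if (n < R + 1) stop("need at least R + 1 items")
  delta <- lower_vec(Dm)
  if (init == "classical") {
    X <- torgerson_init(Dm, R)
  } else {
    if (!is.null(seed)) {
      X <- withr_seed(seed, matrix(stats::rnorm(n * R), n, R))
    } else {
      X <- matrix(stats::rnorm(n * R), n, R)
    }
  }
  X <- scale(X, scale = FALSE)
  # degenerate all-zero init (e.g. constant dissimilarities): nudge off origin
  if (all(abs(X) < 1e-12)) X[] <- seq_len(n * R) / (n * R)
  npairs <- length(delta)
  stress_of <- function(d, dhat) sqrt(sum((dhat - d)^2) / sum(d^2))
  d <- dist_vec(X)
  trace <- numeric(0)
  stress_prev <- Inf
  converged <- FALSE
  iter <- 0L
  dhat <- d
  repeat {
    iter <- iter + 1L
    # monotone regression: order by dissimilarity, ties untied by distance
    ord <- order(delta, d)
    dhat <- numeric(npairs)
    dhat[ord] <- pava(d[ord])
    s2 <- sum(dhat^2)
    if (s2 > 0) dhat <- dhat * sqrt(sum(d^2) / s2)
    stress <- stress_of(d, dhat)
    trace <- c(trace, stress)
    if (is.finite(stress_prev) && stress_prev - stress < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    stress_prev <- stress
    # Guttman transform (unit weights)
    Dhat <- matrix(0, n, n); Rho <- matrix(0, n, n)
    Dhat[lower.tri(Dhat)] <- dhat; Dhat <- Dhat + t(Dhat)
    Rho[lower.tri(Rho)] <- d; Rho <- Rho + t(Rho)
    Brat <- ifelse(Rho > 1e-12, -Dhat / Rho, 0)
    diag(Brat) <- 0
    diag(Brat) <- -rowSums(Brat)
    X <- (Brat %*% X) / n
    X <- scale(X, scale = FALSE)
    d <- dist_vec(X)
  }
  structure(list(coords = unclass(X)[, , drop = FALSE], stress1 = trace[iter],
                 disparities = dhat, dissimilarities = delta, distances = d,
                 stress_trace = trace, iterations = iter,
                 converged = converged, init = init, seed = seed, R = R),
            class = "mds_config")
}

#' @export
print.mds_config <- function(x, ...) {
  cat(sprintf(
    "<mds_config> %d items in %dD, stress-1 %.4g (%s after %d iterations, %s init)\n",
    nrow(x$coords), x$R, x$stress1,
    if (x$converged) "converged" else "NOT converged", x$iterations, x$init))
  invisible(x)
}

# evaluate expression under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit nonmetric MDS with random restarts
#'
#' Refits from the classical start plus `n_starts` seeded random starts and
#' keeps the lowest-stress solution.
#'
#' @inheritParams smacof_nonmetric
#' @param n_starts Number of random starts in addition to the classical one.
#' @return The best `mds_config`, with the stress of every start in
#'   `$start_stresses`.
#' @export
smacof_best <- function(D, R, n_starts = 10L, seed = 1L, tol = 1e-6,
                        max_iter = 300L) {
  fits <- vector("list", n_starts + 1L)
  fits[[1]] <- smacof_nonmetric(D, R, init = "classical", tol = tol,
                                max_iter = max_iter)
  for (k in seq_len(n_starts)) {
    fits[[k + 1L]] <- smacof_nonmetric(D, R, init = "random",
                                       seed = seed + k - 1L, tol = tol,
                                       max_iter = max_iter)
  }
  stresses <- vapply(fits, `[[`, numeric(1), "stress1")
  best <- fits[[which.min(stresses)]]
  best$start_stresses <- stresses
  best
}

#' Stress as a function of dimensionality
#'
#' Fits nonmetric MDS at each dimensionality in `R_list` (best of classical
#' plus random restarts) and reports stress-1 with the conventional fit band
#' (`excellent` <= 0.10 < `fair` <= 0.20 < `poor`).
#'
#' @inheritParams smacof_best
#' @param R_list Ascending integer vector of dimensionalities.
#' @return Data frame with columns `R`, `stress1`, `fit_band`.
#' @export
stress_dimension_scan <- function(D, R_list = 1:5, n_starts = 10L, seed = 1L,
                                  tol = 1e-6, max_iter = 300L) {
  if (is.unsorted(R_list, strictly = TRUE)) stop("R_list must be ascending")
  stress <- vapply(R_list, function(R) {
    smacof_best(D, R, n_starts = n_starts, seed = seed, tol = tol,
                max_iter = max_iter)$stress1
  }, numeric(1))
  band <- cut(stress, c(-Inf, 0.10, 0.20, Inf),
              labels = c("excellent", "fair", "poor"))
  data.frame(R = R_list, stress1 = stress, fit_band = as.character(band))
}

#' Shepard diagram data
#'
#' Triples (observed dissimilarity, configuration distance, disparity) sorted
#' by dissimilarity rank; the disparity column is the piecewise-constant
#' isotonic regression line.  Recomputing stress-1 from the triples reproduces
#' the configuration's stress.
#'
#' @param D Dissimilarities used to fit `config`.
#' @param config An `mds_config` fitted on `D`.
#' @return A data.frame with columns `dissimilarity`, `rank`, `distance`,
#'   `disparity`, plus attribute `stress1`.
#' @export
shepard_data <- function(D, config) {
  Dm <- as_dissim_matrix(D)
  delta <- lower_vec(Dm)
  if (length(delta) != length(config$distances)) {
    stop("config does not match D (different number of items)")
  }
  if (max(abs(delta - config$dissimilarities)) > 1e-9) {
    stop("config was not fitted on this dissimilarity matrix")
  }
  ord <- order(delta, config$distances)
  out <- data.frame(dissimilarity = delta[ord],
                    rank = rank(delta, ties.method = "first")[ord],
                    distance = config$distances[ord],
                    disparity = config$disparities[ord])
  attr(out, "stress1") <- sqrt(sum((out$disparity - out$distance)^2) /
                                 sum(out$distance^2))
  out
}

#' Permutation test for MDS structure
#'
#' Tests whether the observed stress could have arisen from a random
#' permutation of the dissimilarities: the n(n-1)/2 off-diagonal values are
#' jointly permuted (symmetry preserved), each permuted matrix is refit at
#' dimensionality `R`, and p = (1 + #{stress_perm <= stress_obs}) /
#' (n_perm + 1).
#'
#' @inheritParams smacof_nonmetric
#' @param n_perm Number of permutations (>= 19).
#' @param n_starts Random restarts per fit (0 = classical start only).
#' @return List with `p_value`, `stress_obs`, `stress_null` (length n_perm).
#' @export
permutation_test <- function(D, R, n_perm = 99L, seed = 1L, n_starts = 0L,
                             tol = 1e-6, max_iter = 300L) {
  if (n_perm < 19L) stop("n_perm must be >= 19")
  Dm <- as_dissim_matrix(D)
  n <- nrow(Dm)
  fit <- function(M) smacof_best(M, R, n_starts = n_starts, seed = seed,
                                 tol = tol, max_iter = max_iter)$stress1
  stress_obs <- fit(Dm)
  delta <- lower_vec(Dm)
  stress_null <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      M <- matrix(0, n, n)
      M[lower.tri(M)] <- sample(delta)
      fit(M + t(M))
    }, numeric(1))
  })
  list(p_value = (1 + sum(stress_null <= stress_obs)) / (n_perm + 1),
       stress_obs = stress_obs, stress_null = stress_null)
}

#' Rater-bootstrap confidence regions for an MDS configuration
#'
#' Resamples raters with replacement, recomputes the mean-rating matrix,
#' dissimilarities and MDS fit for each replicate, Procrustes-aligns every
#' replicate configuration to the full-data configuration, and summarises the
#' per-item scatter as 95% ellipsoids (chi-squared radius with R degrees of
#' freedom).
#'
#' @param study A [similarity_study()].
#' @param block Which rating block to analyse.
#' @param R Dimensionality.
#' @param n_boot Number of bootstrap replicates.
#' @param seed RNG seed.
#' @param tol,max_iter Passed to the SMACOF fit.
#' @return List with `reference` (full-data `mds_config`), `centers`,
#'   `covariances` (list of R x R matrices), `radius2`
#'   (chi-squared 0.95 quantile, R dof), `replicates` (array
#'   n_items x R x n_kept) and `n_skipped` (degenerate replicates).
#' @export
bootstrap_regions <- function(study, block, R = 3L, n_boot = 100L, seed = 1L,
                              tol = 1e-6, max_iter = 300L) {
  raters <- unique(study$rater[study$block == block])
  if (length(raters) < 5L) stop("need >= 5 raters to bootstrap")
  ref_D <- to_dissimilarity(mean_rating_matrix(study, block))
  ref <- smacof_nonmetric(ref_D, R, tol = tol, max_iter = max_iter)
  n_items <- nrow(ref$coords)
  reps <- list(); skipped <- 0L
  withr_seed(seed, {
    for (b in seq_len(n_boot)) {
      take <- sample(raters, length(raters), replace = TRUE)
      sub <- do.call(rbind, lapply(seq_along(take), function(k) {
        rows <- study[study$block == block & study$rater == take[k], ,
                      drop = FALSE]
        rows$rater <- paste0("boot", k)
        rows
      }))
      sub <- similarity_study(sub)
      M <- mean_rating_matrix(sub, block)
      if (max(M$S) == min(M$S)) { skipped <- skipped + 1L; next }
      fitb <- smacof_nonmetric(to_dissimilarity(M), R, tol = tol,
                               max_iter = max_iter)
      al <- procrustes_align(ref$coords, fitb$coords)
      reps[[length(reps) + 1L]] <- al$aligned
    }
  })
  if (!length(reps)) stop("all bootstrap replicates degenerate")
  arr <- array(unlist(reps), dim = c(n_items, R, length(reps)))
  centers <- apply(arr, c(1, 2), mean)
  covs <- lapply(seq_len(n_items), function(i) {
    pts <- t(arr[i, , , drop = TRUE])
    if (R == 1L) pts <- matrix(arr[i, 1, ], ncol = 1)
    stats::cov(pts)
  })
  list(reference = ref, centers = centers, covariances = covs,
       radius2 = stats::qchisq(0.95, df = R), replicates = arr,
       n_skipped = skipped)
}

#' Stress distribution over random initializations
#'
#' Fits from `n_starts` seeded random initial configurations (plus the
#' classical start, reported alongside) and summarises the stress spread.
#'
#' @inheritParams smacof_nonmetric
#' @param n_starts Number of random starts.
#' @return List with `stresses` (per random start), `classical_stress`,
#'   `best`, `median`, `worst`.
#' @export
random_start_study <- function(D, R, n_starts = 20L, seed = 1L, tol = 1e-6,
                               max_iter = 300L) {
  classical <- smacof_nonmetric(D, R, init = "classical", tol = tol,
                                max_iter = max_iter)$stress1
  stresses <- vapply(seq_len(n_starts), function(k) {
    smacof_nonmetric(D, R, init = "random", seed = seed + k - 1L, tol = tol,
                     max_iter = max_iter)$stress1
  }, numeric(1))
  all_s <- c(stresses, classical)
  list(stresses = stresses, classical_stress = classical,
       best = min(all_s), median = stats::median(stresses), worst = max(all_s))
}
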