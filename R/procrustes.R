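# Procrustes superimposition of point configurations: closed-form optimal
# rotation (optionally with reflection), dilation and translation via the SVD
# of the cross-covariance of the centred configurations, plus Tucker-style
# congruence coefficients and distance-based configuration correlations.

#' Procrustes alignment of two configurations
#'
#' Finds the similarity transform (scale s > 0, orthogonal rotation Q,
#' translation t) minimising `sum_i || x_i - (s Q y_i + t) ||^2` and applies
#' it to `Y`.  MDS solutions are determined only up to rotation, translation,
#' dilation and reflection, so reflections are permitted by default.
#'
#' @param X Reference configuration (n x R matrix).
#' @param Y Target configuration to align (n x R).
#' @param allow_reflection If `TRUE` (default) `Q` may include a reflection.
#' @return A `procrustes_result`: list with `aligned` (n x R), `rotation`,
#'   `scale`, `translation`, `residual` (sum of squared differences after
#'   alignment) and `congruence` (Tucker congruence on aligned, centred
#'   coordinates).
#' @export
procrustes_align <- function(X, Y, allow_reflection = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y))) stop("X and Y must have identical dimensions")
  if (nrow(X) < 2) stop("need at least 2 points")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  ssY <- sum(Yc^2); ssX <- sum(Xc^2)
  if (ssY < 1e-24 || ssX < 1e-24) {
    stop("all points coincident: rotation undefined")
  }
  M <- crossprod(Xc, Yc)            # R x R cross-covariance
  sv <- svd(M)
  Q <- sv$u %*% t(sv$v)
  d_sv <- sv$d
  if (!allow_reflection && det(Q) < 0) {
    # flip the smallest singular direction to force a proper rotation
    k <- ncol(Q)
    D <- diag(c(rep(1, k - 1), -1), k)
    Q <- sv$u %*% D %*% t(sv$v)
    d_sv[k] <- -d_sv[k]
  }
  s <- sum(d_sv) / ssY
  if (s <= 0) stop("degenerate configurations: nonpositive optimal scale")
  t_vec <- cx - s * as.vector(Q %*% cy)
  aligned <- s * Y %*% t(Q) + matrix(t_vec, nrow(Y), ncol(Y), byrow = TRUE)
  residual <- sum((X - aligned)^2)
  Ac <- sweep(aligned, 2, colMeans(aligned))
  congruence <- sum(Xc * Ac) / sqrt(sum(Xc^2) * sum(Ac^2))
  structure(list(aligned = aligned, rotation = Q, scale = s,
                 translation = t_vec, residual = residual,
                 congruence = congruence,
                 allow_reflection = allow_reflection),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf(
    "<procrustes_result> scale %.4g, residual %.4g, congruence %.4f\n",
    x$scale, x$residual, x$congruence))
  invisible(x)
}

#' Tucker congruence coefficient between configurations
#'
#' Centres both configurations, Procrustes-aligns `Y` to `X` (reflections per
#' `allow_reflection`), and returns the normalized inner product
#' `sum_i <x_i, y_i'> / sqrt(sum ||x_i||^2 sum ||y_i'||^2)`, which is 1 when
#' the configurations agree up to a similarity transform.
#'
#' @inheritParams procrustes_align
#' @return Scalar in `[-1, 1]`.
#' @export
congruence_coefficient <- function(X, Y, allow_reflection = TRUE) {
  procrustes_align(X, Y, allow_reflection = allow_reflection)$congruence
}

#' Distance-based configuration correlation
#'
#' Pearson correlation between the vectorized inter-point distance matrices
#' of two configurations — invariant to rotation, translation, dilation and
#' reflection by construction.
#'
#' @param X,Y Configurations with the same number of items (dimensionality may
#'   differ).
#' @return Pearson r, or `NA` with a warning if either distance vector is
#'   constant.
#' @export
configuration_correlation <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of items")
  dx <- as.vector(stats::dist(X)); dy <- as.vector(stats::dist(Y))
  if (stats::sd(dx) == 0 || stats::sd(dy) == 0) {
    warning("constant distance vector: correlation undefined")
    return(NA_real_)
  }
  stats::cor(dx, dy)
}
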