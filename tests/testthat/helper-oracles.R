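# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: per-ray loops, full permutation enumeration,
# grid searches and stats::isoreg stand in as ground truth.

# all permutations of 1..n (n small), one per row
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(k, rest[sub[i, ]])
    }
  }
  out
}

# naive per-ray histogram: scalar loop, independent of the vectorized binning
brute_psf <- function(slopes, bins, half_width) {
  mask <- slopes$grid$mask
  tx <- slopes$slope_x[mask] * (180 / pi * 60)
  ty <- slopes$slope_y[mask] * (180 / pi * 60)
  bw <- 2 * half_width / bins
  counts <- matrix(0L, bins, bins)
  out <- 0L
  for (r in seq_along(tx)) {
    i <- floor((tx[r] + half_width) / bw) + 1
    j <- floor((ty[r] + half_width) / bw) + 1
    if (tx[r] == half_width) i <- bins
    if (ty[r] == half_width) j <- bins
    if (i >= 1 && i <= bins && j >= 1 && j <= bins) {
      counts[i, j] <- counts[i, j] + 1L
    } else {
      out <- out + 1L
    }
  }
  list(counts = counts, out_of_field = out)
}

# 2D Procrustes residual by brute-force grid search over rotation angle,
# reflection and scale
grid_procrustes_residual <- function(X, Y, n_angle = 2000, scales) {
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  best <- Inf
  for (refl in c(1, -1)) {
    for (a in seq(0, 2 * pi, length.out = n_angle)) {
      R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2) %*%
        diag(c(1, refl))
      Yr <- Yc %*% t(R)
      for (s in scales) {
        best <- min(best, sum((Xc - s * Yr)^2))
      }
    }
  }
  best
}

# random likert response set with given truth-agreement structure
random_binary_pair <- function(n = 13L) {
  list(va = sample(0:1, n, replace = TRUE), vb = sample(0:1, n, replace = TRUE))
}

make_likert <- function(mat, image_type = "drawn") {
  # mat: raters x 13 responses for a single image (image id 1)
  df <- expand.grid(rater = seq_len(nrow(mat)), descriptor = 1:13)
  df$image <- 1L
  df$response <- mat[cbind(df$rater, df$descriptor)]
  likert_responses(df, image_type = image_type)
}
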