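#' Isotonic (monotone nondecreasing) least-squares regression
#'
#' Pool-adjacent-violators algorithm (PAVA): given a sequence `y` (optionally
#' weighted), returns the nondecreasing sequence minimising the weighted sum
#' of squared deviations.  This is the monotone-regression step of nonmetric
#' MDS and the piecewise-constant line of a Shepard diagram.
#'
#' @param y Numeric vector.
#' @param w Positive weights, same length as `y` (default all 1).
#' @return Numeric vector, nondecreasing, same length as `y`.
#' @export
pava <- function(y, w = rep(1, length(y))) {
  n <- length(y)
  if (n == 0L) return(numeric(0))
  if (length(w) != n || any(w <= 0)) stop("weights must be positive, length(y)")
  # blocks stored as running (value, weight, size) triples
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    val[k] <- y[i]; wt[k] <- w[i]; sz[k] <- 1L
    while (k > 1L && val[k - 1L] > val[k]) {
      wtot <- wt[k - 1L] + wt[k]
      val[k - 1L] <- (wt[k - 1L] * val[k - 1L] + wt[k] * val[k]) / wtot
      wt[k - 1L] <- wtot
      sz[k - 1L] <- sz[k - 1L] + sz[k]
      k <- k - 1L
    }
  }
  rep(val[seq_len(k)], sz[seq_len(k)])
}
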