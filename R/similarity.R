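# Similarity-rating studies: long-format rater-level 1-10 ratings in three
# blocks (D2D drawn-to-drawn, G2G geometric-to-geometric, D2G cross), group
# mean matrices, and reverse-scaling conversion to dissimilarities.

#' Long-format similarity rating study
#'
#' @param df Data frame with columns `rater`, `image_a`, `image_b`, `block`
#'   (one of `"D2D"`, `"G2G"`, `"D2G"`) and `rating` (integer 1..10,
#'   1 = extremely dissimilar, 10 = identical).  Within-type blocks include
#'   self-pairings (`image_a == image_b`); in the cross block `image_a`
#'   indexes drawn images and `image_b` geometric images.
#' @return A `similarity_study` (validated data.frame).
#' @export
similarity_study <- function(df) {
  df <- as.data.frame(df)
  need <- c("rater", "image_a", "image_b", "block", "rating")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$block %in% c("D2D", "G2G", "D2G"))) {
    stop("block must be one of D2D, G2G, D2G")
  }
  if (!all(df$rating %in% 1:10)) stop("ratings must be integers in 1..10")
  class(df) <- c("similarity_study", "data.frame")
  df
}

#' Group-mean similarity matrix for one block
#'
#' Averages ratings over raters cell by cell.  If both orders (i, j) and
#' (j, i) were collected, they are averaged, so the result is symmetric (for
#' the cross block this resolves the drawn-i-vs-geometric-j asymmetry).
#' Diagonal (self-pair) and off-diagonal cells are summarised separately with
#' t-based 95% confidence intervals over item-level means.
#'
#' @param study A [similarity_study()].
#' @param block Block to aggregate (`"D2D"`, `"G2G"` or `"D2G"`).
#' @return A `mean_rating_matrix`: list with `S` (n x n symmetric mean-rating
#'   matrix), `block`, `n_raters`, and `diagonal` / `off_diagonal` summaries
#'   (mean, sd, ci_lower, ci_upper).
#' @export
mean_rating_matrix <- function(study, block = c("D2D", "G2G", "D2G")) {
  stopifnot(inherits(study, "similarity_study"))
  block <- match.arg(block)
  sub <- study[study$block == block, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no ratings in block ", block)
  if (length(unique(sub$rater)) < 2L) stop("need >= 2 raters")
  items <- sort(unique(c(sub$image_a, sub$image_b)))
  n <- length(items)
  idx_a <- match(sub$image_a, items); idx_b <- match(sub$image_b, items)
  sums <- matrix(0, n, n); cnt <- matrix(0L, n, n)
  for (k in seq_len(nrow(sub))) {
    i <- idx_a[k]; j <- idx_b[k]
    sums[i, j] <- sums[i, j] + sub$rating[k]
    cnt[i, j] <- cnt[i, j] + 1L
  }
  # average over raters and over both collection orders
  tot <- sums + t(sums); m <- cnt + t(cnt)
  diag(tot) <- diag(sums); diag(m) <- diag(cnt)
  if (any(m == 0)) {
    bad <- which(m == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("no ratings for pair (%s, %s) in block %s",
                 items[bad[1]], items[bad[2]], block))
  }
  S <- tot / m
  dimnames(S) <- list(items, items)
  summ <- function(v) {
    m_ <- mean(v); s <- stats::sd(v)
    half <- if (length(v) > 1) stats::qt(0.975, length(v) - 1) * s / sqrt(length(v)) else NA_real_
    c(mean = m_, sd = s, ci_lower = m_ - half, ci_upper = m_ + half)
  }
  structure(list(S = S, block = block,
                 n_raters = length(unique(sub$rater)),
                 diagonal = summ(diag(S)),
                 off_diagonal = summ(S[row(S) != col(S)])),
            class = "mean_rating_matrix")
}

#' @export
print.mean_rating_matrix <- function(x, ...) {
  cat(sprintf(
    "<mean_rating_matrix> %s, %d items, %d raters; diag mean %.2f, off-diag mean %.2f\n",
    x$block, nrow(x$S), x$n_raters, x$diagonal["mean"], x$off_diagonal["mean"]))
  invisible(x)
}

#' Reverse-scale similarities to dissimilarities
#'
#' Applies d_ij = min(s) + max(s) - s_ij with the min/max taken over all cells
#' of the supplied matrix.  Note the formula maps the top of the rating scale
#' to the observed minimum (e.g. "identical" maps to 1, not 0).  Under fixed
#' bounds the transform is an involution.
#'
#' @param S A symmetric numeric matrix of mean similarities, or a
#'   [mean_rating_matrix()].
#' @return A `dissimilarity_matrix`: list with `d` (matrix), `bounds`
#'   (observed min and max used).
#' @export
to_dissimilarity <- function(S) {
  if (inherits(S, "mean_rating_matrix")) S <- S$S
  if (!is.matrix(S) || any(!is.finite(S))) stop("S must be a finite matrix")
  if (max(abs(S - t(S))) > 1e-9) stop("S must be symmetric")
  lo <- min(S); hi <- max(S)
  if (lo == hi) {
    message("to_dissimilarity: constant similarity matrix (degenerate case)")
  }
  structure(list(d = lo + hi - S, bounds = c(min = lo, max = hi)),
            class = "dissimilarity_matrix")
}

# Accept a dissimilarity_matrix, dist, or plain symmetric matrix.
as_dissim_matrix <- function(D) {
  if (inherits(D, "dissimilarity_matrix")) return(D$d)
  if (inherits(D, "dist")) return(as.matrix(D))
  if (is.matrix(D)) {
    if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-9) {
      stop("dissimilarity matrix must be square and symmetric")
    }
    return(D)
  }
  stop("cannot interpret D as a dissimilarity matrix")
}
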