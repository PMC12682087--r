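# Exact null distribution for the direct image-matching task.  Matching n
# drawn images one-to-one to n computed images uniformly at random, the
# number of correct matches K follows the rencontres distribution:
#   P(K = k) = C(n, k) * !(n - k) / n!
# where !m is the derangement number (permutations with no fixed point).
# All probabilities are exact integer ratios; floats appear only at output.

big_factorial <- function(n) {
  out <- big(1)
  if (n >= 2) for (m in 2:n) out <- big_mul_small(out, m)
  out
}

big_choose <- function(n, k) {
  # Pascal recurrence in exact integers
  row <- list(big(1))
  if (n >= 1) for (i in 1:n) {
    new <- vector("list", i + 1L)
    new[[1]] <- big(1); new[[i + 1L]] <- big(1)
    if (i >= 2) for (j in 2:i) new[[j]] <- big_add(row[[j - 1L]], row[[j]])
    row <- new
  }
  row[[k + 1L]]
}

#' Exact derangement number
#'
#' Number of permutations of `m` items with no fixed point, by the recurrence
#' `!m = (m - 1)(!(m - 1) + !(m - 2))` with `!0 = 1`, `!1 = 0`, in exact
#' arbitrary-precision integer arithmetic.
#'
#' @param m Nonnegative integer.
#' @return A `bigint` (printable; `as.character()` for the decimal string).
#' @examples
#' derangement_count(4)  # 9
#' @export
derangement_count <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || m < 0 || m != floor(m)) {
    stop("`m` must be a single nonnegative integer")
  }
  if (m == 0) return(big(1))
  if (m == 1) return(big(0))
  prev2 <- big(1); prev1 <- big(0)
  for (k in 2:m) {
    cur <- big_mul_small(big_add(prev1, prev2), k - 1)
    prev2 <- prev1; prev1 <- cur
  }
  prev1
}

#' Rencontres probability mass function
#'
#' Exact probability of exactly `k` correct matches when `n` items are matched
#' one-to-one uniformly at random: `C(n, k) !(n-k) / n!`.  Note
#' `P(K = n - 1) = 0`: with all but one item matched correctly the last is
#' forced.
#'
#' @param n Number of items (>= 1).
#' @param k Number of correct matches (0 <= k <= n).
#' @return A `rencontres_prob`: list with exact `numerator`, `denominator`
#'   (`bigint`s) and `value` (double rendering of the exact ratio).
#' @examples
#' round(rencontres_pmf(15, 0)$value, 2)  # 0.37
#' @export
rencontres_pmf <- function(n, k) {
  check_nk(n, k)
  num <- big_mul(big_choose(n, k), derangement_count(n - k))
  den <- big_factorial(n)
  new_rencontres_prob(num, den)
}

check_nk <- function(n, k) {
  if (!is.numeric(n) || n < 1 || n != floor(n)) stop("`n` must be integer >= 1")
  if (!is.numeric(k) || k < 0 || k != floor(k)) stop("`k` must be integer >= 0")
  if (k > n) stop("`k` cannot exceed `n`")
}

new_rencontres_prob <- function(num, den) {
  structure(list(numerator = num, denominator = den,
                 value = big_to_double(num) / big_to_double(den)),
            class = "rencontres_prob")
}

#' @export
print.rencontres_prob <- function(x, ...) {
  cat(sprintf("%s / %s = %.6g\n", format(x$numerator), format(x$denominator),
              x$value))
  invisible(x)
}

#' Full rencontres distribution table
#'
#' @param n Number of items.
#' @return Data frame with columns `k`, `probability` (double) and
#'   `numerator` (character; shared denominator is `n!`).
#' @export
rencontres_distribution <- function(n) {
  probs <- lapply(0:n, function(k) rencontres_pmf(n, k))
  data.frame(k = 0:n,
             probability = vapply(probs, `[[`, numeric(1), "value"),
             numerator = vapply(probs, function(p) format(p$numerator), ""),
             stringsAsFactors = FALSE)
}

#' Exact upper-tail matching probability
#'
#' `P(K >= k)` under random one-to-one matching, as an exact sum of rencontres
#' terms.
#'
#' @inheritParams rencontres_pmf
#' @return A `rencontres_prob` for the tail.
#' @examples
#' match_tail_probability(15, 6)$value  # < 0.001
#' @export
match_tail_probability <- function(n, k) {
  check_nk(n, k)
  num <- big(0)
  for (j in k:n) {
    num <- big_add(num, big_mul(big_choose(n, j), derangement_count(n - j)))
  }
  new_rencontres_prob(num, big_factorial(n))
}

#' Outcome of a direct matching task
#'
#' @param n Number of image pairs (>= 1).
#' @param n_correct Observed number of correct matches (0..n).  Note that
#'   `n_correct = n - 1` is range-valid as input but has probability zero
#'   under one-to-one matching.
#' @return A `matching_outcome`.
#' @export
matching_outcome <- function(n, n_correct) {
  check_nk(n, n_correct)
  structure(list(n = as.integer(n), n_correct = as.integer(n_correct)),
            class = "matching_outcome")
}

#' Exact test of matching performance against the rencontres null
#'
#' Computes the exact point probability and upper-tail p-value of the observed
#' number of correct matches under uniform random one-to-one matching, plus
#' the most likely outcomes under the null (for n >= 2 these are 0 and 1
#' correct matches, tied at n -> infinity toward 1/e each).
#'
#' @param outcome A [matching_outcome()] or a list/vector with `n` and
#'   `n_correct`.
#' @param alpha Significance level for flagging (default 0.001).
#' @return A `match_test`: list with `n`, `n_correct`, `pmf_value`,
#'   `tail_p` (exact `P(K >= n_correct)` as double), `tail_exact`
#'   (`rencontres_prob`), `significant`, `alpha`, `mode_k`,
#'   `mode_probability`, `expected_matches` (always 1).
#' @export
exact_match_test <- function(outcome, alpha = 0.001) {
  if (!inherits(outcome, "matching_outcome")) {
    outcome <- matching_outcome(outcome[["n"]], outcome[["n_correct"]])
  }
  n <- outcome$n; k <- outcome$n_correct
  dist <- rencontres_distribution(n)
  tail <- match_tail_probability(n, k)
  mode_p <- max(dist$probability)
  structure(list(
    n = n, n_correct = k,
    pmf_value = dist$probability[k + 1L],
    tail_p = tail$value, tail_exact = tail,
    significant = tail$value < alpha, alpha = alpha,
    mode_k = dist$k[dist$probability == mode_p],
    mode_probability = mode_p,
    expected_matches = 1,
    distribution = dist), class = "match_test")
}

#' @export
print.match_test <- function(x, ...) {
  cat(sprintf(
    "<match_test> %d/%d correct; P(K = %d) = %.3g, P(K >= %d) = %.3g (%s at alpha = %g)\n",
    x$n_correct, x$n, x$n_correct, x$pmf_value, x$n_correct, x$tail_p,
    if (x$significant) "significant" else "not significant", x$alpha))
  invisible(x)
}
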