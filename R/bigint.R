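# Minimal arbitrary-precision nonnegative integers (base 1e7 little-endian
# digit vectors).  15! and !15 already exceed 32-bit range and !30 exceeds the
# exact range of doubles, so the rencontres null is computed in exact integer
# arithmetic and converted to floating point only for presentation.

BIG_BASE <- 1e7

big_norm <- function(d) {
  i <- 1L
  while (i <= length(d)) {
    if (d[i] >= BIG_BASE) {
      carry <- floor(d[i] / BIG_BASE)
      d[i] <- d[i] - carry * BIG_BASE
      if (i == length(d)) d <- c(d, 0)
      d[i + 1L] <- d[i + 1L] + carry
    }
    i <- i + 1L
  }
  while (length(d) > 1L && d[length(d)] == 0) d <- d[-length(d)]
  structure(d, class = "bigint")
}

big <- function(x) {
  if (inherits(x, "bigint")) return(x)
  stopifnot(is.numeric(x), length(x) == 1L, x >= 0, x == floor(x),
            x < 2^53)
  d <- numeric(0)
  repeat {
    d <- c(d, x %% BIG_BASE)
    x <- floor(x / BIG_BASE)
    if (x == 0) break
  }
  big_norm(d)
}

big_add <- function(a, b) {
  la <- length(a); lb <- length(b); n <- max(la, lb)
  d <- numeric(n)
  d[seq_len(la)] <- unclass(a)
  d[seq_len(lb)] <- d[seq_len(lb)] + unclass(b)
  big_norm(d)
}

# multiply by a small nonnegative integer scalar (< 2^26 keeps products exact)
big_mul_small <- function(a, s) {
  stopifnot(s >= 0, s == floor(s), s < 2^26)
  if (s == 0) return(big(0))
  big_norm(unclass(a) * s)
}

big_mul <- function(a, b) {
  da <- unclass(a); db <- unclass(b)
  out <- numeric(length(da) + length(db))
  for (i in seq_along(db)) {
    if (db[i] == 0) next
    # split b's digit to keep partial products below 2^53
    hi <- floor(db[i] / 1e3); lo <- db[i] - hi * 1e3
    idx <- seq_along(da) + i - 1L
    out[idx] <- out[idx] + da * lo
    out <- big_norm_raw(out)
    if (hi > 0) {
      out[idx] <- out[idx] + (da * hi) %% BIG_BASE * 1e3
      out <- big_norm_raw(out)
      out[idx + 1L] <- out[idx + 1L] + floor(da * hi / BIG_BASE) * 1e3
      out <- big_norm_raw(out)
    }
  }
  big_norm(out)
}

big_norm_raw <- function(d) {
  carry <- 0
  for (i in seq_along(d)) {
    v <- d[i] + carry
    carry <- floor(v / BIG_BASE)
    d[i] <- v - carry * BIG_BASE
  }
  while (carry > 0) {
    d <- c(d, carry %% BIG_BASE)
    carry <- floor(carry / BIG_BASE)
  }
  d
}

big_eq <- function(a, b) identical(as.numeric(unclass(a)),
                                   as.numeric(unclass(b)))

big_to_double <- function(a) {
  d <- unclass(a)
  sum(d * BIG_BASE^(seq_along(d) - 1))
}

#' @export
format.bigint <- function(x, ...) {
  d <- rev(unclass(x))
  paste0(format(d[1], scientific = FALSE),
         paste(sprintf("%07.0f", d[-1]), collapse = ""))
}

#' @export
print.bigint <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.bigint <- function(x, ...) format(x)
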