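# Feature assessment and agreement: Likert responses on a fixed catalog of 13
# PSF feature descriptors are aggregated into binary consensus vectors (one
# per image), and per-pair association between the "drawn" and "geometric"
# consensus vectors is quantified with Yule's Q plus sensitivity metrics
# (Phi, Cohen's kappa, mutual information).

#' The 13 PSF feature descriptors
#'
#' Returns the fixed, ordered catalog of declarative feature statements used
#' throughout the agreement analysis.  Indices are stable; descriptor 7 is
#' the "central core" item, etc.
#'
#' @return Character vector of length 13.
#' @export
feature_descriptors <- function() {
  path <- system.file("extdata", "feature_descriptors.json",
                      package = "psfmatch")
  out <- jsonlite::fromJSON(path)
  stopifnot(length(out) == 13L)
  out
}

#' Long-format Likert response set
#'
#' Validates and wraps a long-format table of ordinal responses: one row per
#' (rater, image, descriptor) with response in 1..5
#' (1 = Strongly disagree ... 5 = Strongly agree).
#'
#' @param df Data frame with columns `rater`, `image`, `descriptor`
#'   (1..13) and `response` (1..5); optionally `image_type`
#'   (`"drawn"` or `"geometric"`).
#' @param image_type Type tag applied if `df` lacks an `image_type` column.
#' @return A `likert_responses` object (a validated data.frame).
#' @export
likert_responses <- function(df, image_type = NULL) {
  df <- as.data.frame(df)
  need <- c("rater", "image", "descriptor", "response")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!("image_type" %in% names(df))) {
    if (is.null(image_type)) stop("supply `image_type` column or argument")
    df$image_type <- image_type
  }
  if (!all(df$response %in% 1:5)) stop("responses must be integers in 1..5")
  if (!all(df$descriptor %in% 1:13)) stop("descriptor indices must be in 1..13")
  if (anyDuplicated(df[c("rater", "image", "descriptor")])) {
    stop("duplicated (rater, image, descriptor) cells")
  }
  class(df) <- c("likert_responses", "data.frame")
  df
}

#' Binary consensus vector for one image
#'
#' For each descriptor, computes the fraction of (non-missing) raters who
#' responded Agree (4) or Strongly Agree (5).  The consensus bit is 1 when
#' that fraction strictly exceeds 50%: an exact 50/50 split codes 0.
#'
#' @param responses A [likert_responses()] set.
#' @param image Image identifier present in `responses$image`.
#' @return A `consensus_vector`: list with `bits` (integer 0/1, length 13) and
#'   `agree_fraction` (numeric, length 13).
#' @export
consensus_vector <- function(responses, image) {
  stopifnot(inherits(responses, "likert_responses"))
  sub <- responses[responses$image == image, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no responses for image ", image)
  frac <- bits <- rep(NA_real_, 13)
  for (d in 1:13) {
    r <- sub$response[sub$descriptor == d]
    if (length(r) == 0L) {
      stop(sprintf("descriptor %d has zero responses for image %s", d, image))
    }
    frac[d] <- mean(r >= 4)
  }
  structure(list(bits = as.integer(frac > 0.5), agree_fraction = frac,
                 image = image),
            class = "consensus_vector")
}

# 2x2 table of two binary vectors: a = both 1, b = va only, c = vb only,
# d = neither.
binary_table <- function(va, vb) {
  va <- if (inherits(va, "consensus_vector")) va$bits else as.integer(va)
  vb <- if (inherits(vb, "consensus_vector")) vb$bits else as.integer(vb)
  if (length(va) != length(vb)) stop("vectors must have equal length")
  if (!all(va %in% 0:1) || !all(vb %in% 0:1)) stop("vectors must be binary")
  c(a = sum(va == 1 & vb == 1), b = sum(va == 1 & vb == 0),
    c = sum(va == 0 & vb == 1), d = sum(va == 0 & vb == 0))
}

#' Yule's Q between two binary feature vectors
#'
#' Q = (ad - bc)/(ad + bc) on the 2x2 cross-table.  When ad + bc = 0 with one
#' product positive, the signed limit (+1 or -1) is returned with a warning;
#' when both products vanish Q is undefined and an error is raised.
#'
#' @param va,vb Binary vectors (or `consensus_vector`s) of equal length.
#' @return List with `q` and `table` (named counts a, b, c, d).
#' @export
yules_q <- function(va, vb) {
  tab <- binary_table(va, vb)
  ad <- tab["a"] * tab["d"]; bc <- tab["b"] * tab["c"]
  if (ad + bc == 0) {
    if (ad == 0 && bc == 0) {
      stop("Yule's Q undefined: ad = bc = 0")
    }
  }
  q <- if (ad + bc == 0) NA_real_ else unname((ad - bc) / (ad + bc))
  if (bc == 0 && ad > 0 && tab["b"] + tab["c"] > 0) {
    warning("degenerate table (bc = 0): Q reported as signed limit +1")
  }
  if (ad == 0 && bc > 0 && tab["a"] + tab["d"] > 0) {
    warning("degenerate table (ad = 0): Q reported as signed limit -1")
  }
  list(q = q, table = tab)
}

# Large-sample two-sided p-value for association on a 2x2 table via the
# log-odds-ratio z-test; 0.5 added to every cell (Haldane-Anscombe) for the
# test only, never for the reported Q.
lnor_p_value <- function(tab) {
  t2 <- tab + 0.5
  z <- log(t2["a"] * t2["d"] / (t2["b"] * t2["c"])) /
    sqrt(sum(1 / t2))
  unname(2 * stats::pnorm(-abs(z)))
}

#' Association suite on a 2x2 feature table
#'
#' Computes Yule's Q, the Phi coefficient, Cohen's kappa and mutual
#' information (bits) on the same 2x2 cross-table of two binary vectors.
#' Metrics whose denominators vanish (zero marginal) are reported as `NA`,
#' not zero.
#'
#' @param va,vb Binary vectors or `consensus_vector`s of equal length.
#' @return An `association_result`: list with `q`, `phi`, `kappa`, `mi`,
#'   `p_value` (for Q, log-odds z-test) and `table`.
#' @export
association_suite <- function(va, vb) {
  qres <- withCallingHandlers(yules_q(va, vb),
                              warning = function(w) invokeRestart("muffleWarning"))
  tab <- qres$table
  a <- tab[["a"]]; b <- tab[["b"]]; c_ <- tab[["c"]]; d <- tab[["d"]]
  n <- a + b + c_ + d
  m1 <- a + b; m0 <- c_ + d; k1 <- a + c_; k0 <- b + d
  phi <- if (m1 * m0 * k1 * k0 == 0) NA_real_ else
    (a * d - b * c_) / sqrt(m1 * m0 * k1 * k0)
  po <- (a + d) / n
  pe <- (m1 * k1 + m0 * k0) / n^2
  kappa <- if (abs(1 - pe) < 1e-15) {
    if (po >= 1 - 1e-15) 1 else NA_real_
  } else (po - pe) / (1 - pe)
  # mutual information in bits from the empirical joint distribution
  pj <- tab / n
  pr <- c(m1, m0) / n; pc <- c(k1, k0) / n
  grid <- rbind(c(pj[["a"]], pr[1] * pc[1]), c(pj[["b"]], pr[1] * pc[2]),
                c(pj[["c"]], pr[2] * pc[1]), c(pj[["d"]], pr[2] * pc[2]))
  nz <- grid[, 1] > 0
  mi <- sum(grid[nz, 1] * log2(grid[nz, 1] / grid[nz, 2]))
  mi <- max(mi, 0)  # clip -0 rounding
  structure(list(q = qres$q, phi = unname(phi), kappa = unname(kappa),
                 mi = mi, p_value = lnor_p_value(tab), table = tab),
            class = "association_result")
}

#' Per-pair consensus study across drawn and geometric response sets
#'
#' For every image pair (same image index in the drawn and geometric sets),
#' builds both consensus vectors, computes the association suite, and
#' summarises Yule's Q (mean, SD, min, max) across pairs together with the
#' Pearson correlation matrix between the four metrics.
#'
#' @param drawn,geometric [likert_responses()] sets with the same image ids.
#' @return A `consensus_study`: list with `pairs` (data.frame of per-pair
#'   metrics), `q_summary`, `metric_correlations` (4x4 Pearson r), and
#'   `metric_p_values` (two-sided t-test p-values).
#' @export
consensus_study <- function(drawn, geometric) {
  imgs_d <- sort(unique(drawn$image)); imgs_g <- sort(unique(geometric$image))
  if (!identical(imgs_d, imgs_g)) {
    stop("drawn and geometric response sets cover different image indices")
  }
  res <- lapply(imgs_d, function(im) {
    va <- consensus_vector(drawn, im); vb <- consensus_vector(geometric, im)
    tryCatch(association_suite(va, vb), error = function(e) {
      # ad = bc = 0: Q undefined for this pair; report NA, keep the table
      warning(sprintf("image %s: %s", im, conditionMessage(e)), call. = FALSE)
      structure(list(q = NA_real_, phi = NA_real_, kappa = NA_real_,
                     mi = NA_real_, p_value = NA_real_,
                     table = binary_table(va, vb)),
                class = "association_result")
    })
  })
  pairs <- data.frame(
    image = imgs_d,
    q = vapply(res, `[[`, numeric(1), "q"),
    phi = vapply(res, `[[`, numeric(1), "phi"),
    kappa = vapply(res, `[[`, numeric(1), "kappa"),
    mi = vapply(res, `[[`, numeric(1), "mi"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"))
  q <- pairs$q
  q_summary <- c(mean = mean(q, na.rm = TRUE), sd = stats::sd(q, na.rm = TRUE),
                 min = min(q, na.rm = TRUE), max = max(q, na.rm = TRUE))
  mets <- as.matrix(pairs[c("q", "phi", "kappa", "mi")])
  k <- ncol(mets)
  rmat <- pmat <- matrix(NA_real_, k, k, dimnames = list(colnames(mets),
                                                         colnames(mets)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(mets[, c(i, j)])
    if (sum(ok) >= 3 && stats::sd(mets[ok, i]) > 0 && stats::sd(mets[ok, j]) > 0) {
      ct <- stats::cor.test(mets[ok, i], mets[ok, j])
      rmat[i, j] <- unname(ct$estimate); pmat[i, j] <- ct$p.value
    } else if (i == j) {
      rmat[i, j] <- 1
    }
  }
  structure(list(pairs = pairs, results = res, q_summary = q_summary,
                 metric_correlations = rmat, metric_p_values = pmat),
            class = "consensus_study")
}

#' @export
print.consensus_study <- function(x, ...) {
  s <- x$q_summary
  cat(sprintf(
    "<consensus_study> %d pairs; Yule's Q mean %.3f (SD %.3f, range [%.3f, %.3f])\n",
    nrow(x$pairs), s["mean"], s["sd"], s["min"], s["max"]))
  invisible(x)
}

#' Likert distribution summary for one image
#'
#' Collapses the five response categories into combined percentages of
#' disagreement (1-2), neutral (3) and agreement (4-5) per descriptor, ordered
#' by descending agreement (ties broken by descriptor index) as in a stacked
#' diverging-bar display.
#'
#' @param responses A [likert_responses()] set.
#' @param image Image identifier.
#' @return Data frame with columns `descriptor`, `pct_disagree`,
#'   `pct_neutral`, `pct_agree`, sorted by `pct_agree` descending.
#' @export
likert_distribution_summary <- function(responses, image) {
  stopifnot(inherits(responses, "likert_responses"))
  sub <- responses[responses$image == image, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no responses for image ", image)
  out <- do.call(rbind, lapply(1:13, function(d) {
    r <- sub$response[sub$descriptor == d]
    data.frame(descriptor = d,
               pct_disagree = 100 * mean(r <= 2),
               pct_neutral = 100 * mean(r == 3),
               pct_agree = 100 * mean(r >= 4))
  }))
  out[order(-out$pct_agree, out$descriptor), , drop = FALSE]
}
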