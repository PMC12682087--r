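# Plain-text readers and writers for every domain type: long-format CSVs for
# ratings, JSON for Zernike coefficients and reports, plain (P2) PGM plus a
# sidecar scale for PSF rasters, TSV for matrices.  All writers round-trip
# through their matching readers.

#' Write / read a Likert response CSV
#'
#' Long format: one observation per row with columns
#' `rater, image, image_type, descriptor, response`.
#' @param responses A [likert_responses()] set.
#' @param path File path.
#' @export
write_likert_csv <- function(responses, path) {
  stopifnot(inherits(responses, "likert_responses"))
  utils::write.csv(responses[c("rater", "image", "image_type", "descriptor",
                               "response")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_likert_csv
#' @export
read_likert_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, c("rater", "image", "image_type", "descriptor", "response"),
             path)
  check_integer_col(df, "descriptor", path)
  check_integer_col(df, "response", path)
  likert_responses(df)
}

#' Write / read a similarity rating CSV
#'
#' Long format with columns `rater, image_a, image_b, block, rating`.
#' @param study A [similarity_study()].
#' @param path File path.
#' @export
write_similarity_csv <- function(study, path) {
  stopifnot(inherits(study, "similarity_study"))
  utils::write.csv(study[c("rater", "image_a", "image_b", "block", "rating")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_csv
#' @export
read_similarity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cols(df, c("rater", "image_a", "image_b", "block", "rating"), path)
  check_integer_col(df, "rating", path)
  similarity_study(df)
}

check_cols <- function(df, need, path) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing columns %s", path, paste(miss, collapse = ", ")))
  }
}

check_integer_col <- function(df, col, path) {
  v <- df[[col]]
  if (!is.numeric(v) || any(is.na(v)) || any(v != floor(v))) {
    bad <- which(!is.numeric(v) | is.na(suppressWarnings(as.numeric(v))) |
                   suppressWarnings(as.numeric(v)) != floor(suppressWarnings(as.numeric(v))))
    stop(sprintf("%s: column `%s` not integer at data row(s) %s", path, col,
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
}

#' Write / read Zernike coefficients
#'
#' JSON with fields `pupil_diameter_mm`, `wavelength_nm` and `coefficients`
#' (objects with OSA/ANSI `index` and `value_um`).
#' @param coeffs Numeric coefficient vector (index 0 first, micrometres).
#' @param pupil_diameter Pupil diameter in mm.
#' @param path File path.
#' @param wavelength Wavelength in nm.
#' @export
write_zernike_json <- function(coeffs, pupil_diameter, path,
                               wavelength = 570) {
  obj <- list(pupil_diameter_mm = pupil_diameter, wavelength_nm = wavelength,
              coefficients = data.frame(index = seq_along(coeffs) - 1L,
                                        value_um = coeffs))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_zernike_json
#' @export
read_zernike_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  co <- obj$coefficients
  if (is.null(co$index) || is.null(co$value_um)) {
    stop(path, ": malformed Zernike file (need index and value_um)")
  }
  coeffs <- numeric(max(co$index) + 1L)
  coeffs[co$index + 1L] <- co$value_um
  list(coeffs = coeffs, pupil_diameter = obj$pupil_diameter_mm,
       wavelength = if (is.null(obj$wavelength_nm)) 570 else obj$wavelength_nm)
}

#' Write / read a PSF histogram as plain PGM plus sidecar
#'
#' P2 (ASCII) portable graymap of the raw counts, with a JSON sidecar
#' (`<path>.json`) carrying bin width, half-width, ray totals and the
#' out-of-field count so that the round-trip is lossless.
#' @param psf A `geometric_psf`.
#' @param path Output `.pgm` path.
#' @export
write_psf_pgm <- function(psf, path) {
  stopifnot(inherits(psf, "geometric_psf"))
  maxv <- max(psf$counts, 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(psf$counts), nrow(psf$counts)),
               sprintf("%d", maxv)), con)
  # PGM raster order: rows top to bottom; store counts row-wise
  utils::write.table(psf$counts, con, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(bin_width = psf$bin_width,
                            half_width = psf$half_width,
                            rays_total = psf$rays_total,
                            out_of_field = psf$out_of_field),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_psf_pgm
#' @export
read_psf_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1] != "P2") stop(path, ": not a plain (P2) PGM file")
  dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  vals <- as.integer(unlist(strsplit(trimws(lines[-(1:3)]), "\\s+")))
  if (length(vals) != prod(dims)) {
    stop(path, ": pixel count does not match header dimensions")
  }
  counts <- matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  structure(list(counts = counts, bin_width = meta$bin_width,
                 half_width = meta$half_width, rays_total = meta$rays_total,
                 out_of_field = meta$out_of_field),
            class = "geometric_psf")
}

#' Write a matrix (configuration, dissimilarity, ...) as TSV
#' @param m Numeric matrix.
#' @param path File path.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = !is.null(colnames(m)), quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param header Whether the file has a header row.
#' @export
read_matrix_tsv <- function(path, header = FALSE) {
  as.matrix(utils::read.table(path, sep = "\t", header = header))
}

#' Write a raster as PNG (presentation only)
#' @param img An `image_raster`.
#' @param path Output path.
#' @export
write_raster_png <- function(img, path) {
  stopifnot(inherits(img, "image_raster"))
  grDevices::png(path, width = ncol(img$pixels), height = nrow(img$pixels))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::image(img$pixels[, ncol(img$pixels):1],
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  useRaster = TRUE)
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}
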