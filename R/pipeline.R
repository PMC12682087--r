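# Pipeline: ties the stages together (synthesize -> optics -> agreement ->
# MDS -> Procrustes -> matching) with one serializable configuration, and a
# small command-line front end.

#' Study-design counts
#'
#' Item and comparison counts implied by the study design: a Likert
#' questionnaire over all images and descriptors, and the full comparison
#' grid (all ordered pairs including self-pairs) for one image block.
#'
#' @param n_images Total number of images rated (e.g. 30 = 15 drawn +
#'   15 geometric).
#' @param n_descriptors Number of feature descriptors (default 13).
#' @return Number of Likert items (`n_images * n_descriptors`).
#' @export
questionnaire_item_count <- function(n_images, n_descriptors = 13L) {
  stopifnot(n_images >= 1, n_descriptors >= 1)
  as.integer(n_images) * as.integer(n_descriptors)
}

#' @rdname questionnaire_item_count
#' @param n Number of images in the block.
#' @return `pair_comparison_count`: size of the full n x n comparison grid.
#' @export
pair_comparison_count <- function(n) {
  stopifnot(n >= 1)
  as.integer(as.integer(n)^2)
}

#' Pipeline configuration
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param out_dir Output directory for all reports and images.
#' @param stages Character vector of stages to run, a subset of
#'   `c("optics", "agreement", "mds", "procrustes", "matching")`.
#' @param sim A [simulation_config()] (seed is overridden by `seed`).
#' @param grid_resolution Pupil grid samples per diameter for the optics
#'   stage (default 128; coarser than the analysis default to keep pipeline
#'   runs fast).
#' @param psf_bins,psf_half_width PSF histogram geometry.
#' @param mds_dim MDS dimensionality (default 3).
#' @param n_starts Random restarts for MDS fits.
#' @param sketch_noise Surrogate drawing noise level.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("psfmatch_run_"),
                            stages = c("optics", "agreement", "mds",
                                       "procrustes", "matching"),
                            sim = simulation_config(seed = seed),
                            grid_resolution = 128L, psf_bins = 101L,
                            psf_half_width = 30, mds_dim = 3L,
                            n_starts = 5L, sketch_noise = 0.5) {
  stages <- match.arg(stages, several.ok = TRUE)
  sim$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
                 sim = sim, grid_resolution = as.integer(grid_resolution),
                 psf_bins = as.integer(psf_bins),
                 psf_half_width = psf_half_width, mds_dim = as.integer(mds_dim),
                 n_starts = as.integer(n_starts),
                 sketch_noise = sketch_noise),
            class = "pipeline_config")
}

# FNV-1a hash of the canonical JSON of a config: stable across sessions,
# recorded in every output header.
config_hash <- function(config) {
  cfg <- unclass_rec(config)
  cfg$out_dir <- NULL  # output location is not part of the run's identity
  txt <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

unclass_rec <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x[!vapply(x, is.function, logical(1))], unclass_rec)
  else x
}

# deterministic per-image wavefront: lens profile + seeded higher-order
# aberrations, so the 15 emulated eyes differ in both design and aberration.
build_image_wavefronts <- function(cfg) {
  sim <- cfg$sim
  designs <- rep(c("single_vision", "centre_distance", "centre_near_aspheric",
                   "dual_focus_zonal", "edof"), length.out = sim$n_images)
  pupils <- sample_pupils(sim$n_images, sim)
  withr_seed(sim$seed + 1L, {
    lapply(seq_len(sim$n_images), function(i) {
      pg <- pupil_grid(pupils[i], cfg$grid_resolution)
      w <- profile_wavefront(make_lens_profile(designs[i]), pg)
      # OSA indices 3..9: astigmatism, coma, trefoil; ~0.15 um RMS each
      hoa <- c(0, 0, 0, stats::rnorm(7, 0, 0.15))
      w2 <- zernike_wavefront(hoa, pg)
      w$opd <- w$opd + w2$opd
      list(index = i, design = designs[i], pupil = pupils[i], wavefront = w)
    })
  })
}

#' Run the full pipeline
#'
#' Executes the selected stages on synthesized data and writes a JSON summary
#' (stamped with the seed and config hash), TSV tables and PGM/PNG images
#' under `config$out_dir`.  Rerunning with the same config reproduces all
#' non-figure outputs byte-identically.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) the summary list that was written to
#'   `summary.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed, config_hash = config_hash(config),
                  stages = config$stages)
  sim <- config$sim
  eyes <- NULL
  psfs <- NULL

  if (any(c("optics", "matching") %in% config$stages)) {
    eyes <- build_image_wavefronts(config)
    psfs <- lapply(eyes, function(e) {
      psf_from_wavefront(e$wavefront, bins = config$psf_bins,
                         half_width = config$psf_half_width)
    })
  }
  if ("optics" %in% config$stages) {
    for (i in seq_along(psfs)) {
      write_psf_pgm(psfs[[i]], file.path(config$out_dir,
                                         sprintf("psf_%02d.pgm", i)))
    }
    summary$optics <- list(
      n_images = length(psfs),
      designs = vapply(eyes, `[[`, character(1), "design"),
      pupil_mm = vapply(eyes, `[[`, numeric(1), "pupil"),
      out_of_field = vapply(psfs, `[[`, integer(1), "out_of_field"))
  }

  if ("agreement" %in% config$stages) {
    lik <- simulate_likert(simulate_feature_truth(sim$n_images, sim$seed), sim)
    write_likert_csv(lik$drawn,
                     file.path(config$out_dir, "likert_drawn.csv"))
    write_likert_csv(lik$geometric,
                     file.path(config$out_dir, "likert_geometric.csv"))
    st <- consensus_study(lik$drawn, lik$geometric)
    utils::write.table(st$pairs, file.path(config$out_dir, "agreement.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    summary$agreement <- list(
      q_mean = unname(st$q_summary["mean"]), q_sd = unname(st$q_summary["sd"]),
      q_min = unname(st$q_summary["min"]), q_max = unname(st$q_summary["max"]),
      n_items = questionnaire_item_count(2L * sim$n_images))
  }

  study <- NULL
  configs <- list()
  if (any(c("mds", "procrustes") %in% config$stages)) {
    study <- simulate_similarity(
      planted_configuration(sim$n_images, sim$planted_dim, sim$seed), sim)
    write_similarity_csv(study,
                         file.path(config$out_dir, "similarity.csv"))
  }
  if ("mds" %in% config$stages) {
    mds_sum <- list()
    for (block in c("D2D", "G2G", "D2G")) {
      M <- mean_rating_matrix(study, block)
      fit <- smacof_best(to_dissimilarity(M), config$mds_dim,
                         n_starts = config$n_starts, seed = config$seed)
      configs[[block]] <- fit
      write_matrix_tsv(fit$coords,
                       file.path(config$out_dir,
                                 sprintf("config_%s.tsv", block)))
      mds_sum[[block]] <- list(stress1 = fit$stress1,
                               converged = fit$converged,
                               diag_mean = unname(M$diagonal["mean"]),
                               offdiag_mean = unname(M$off_diagonal["mean"]))
    }
    summary$mds <- c(mds_sum,
                     list(n_comparisons = pair_comparison_count(sim$n_images)))
  }

  if ("procrustes" %in% config$stages && length(configs) == 3L) {
    pairs <- list(c("G2G", "D2D"), c("D2G", "G2G"), c("D2G", "D2D"))
    summary$procrustes <- lapply(pairs, function(p) {
      X <- configs[[p[1]]]$coords; Y <- configs[[p[2]]]$coords
      list(pair = paste(p, collapse = "_vs_"),
           congruence = congruence_coefficient(X, Y),
           distance_correlation = configuration_correlation(X, Y))
    })
  }

  if ("matching" %in% config$stages) {
    drawn <- lapply(seq_along(psfs), function(i) {
      surrogate_drawn_psf(psfs[[i]], sketch_noise = config$sketch_noise,
                          seed = config$seed + i)
    })
    geo <- lapply(psfs, render_psf, invert = TRUE)
    mt <- exact_match_test(ncc_match(drawn, geo))
    summary$matching <- list(n = mt$n, n_correct = mt$n_correct,
                             tail_p = mt$tail_p,
                             significant = mt$significant)
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Command-line interface
#'
#' Subcommands: `synthesize`, `psf`, `agreement`, `mds`, `procrustes`,
#' `match-test`, `run`.  `--seed` is mandatory for stochastic commands.
#' Example: `match-test --n 15 --correct 10` prints a JSON report.
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Exit status (0 on success), invisibly.
#' @export
psfmatch_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: psfmatch <synthesize|psf|agreement|mds|procrustes|match-test|run> [--key value ...]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- parse_cli_opts(args[-1])
  need_seed <- function() {
    if (is.null(opt$seed)) stop("--seed is mandatory for stochastic commands")
    as.integer(opt$seed)
  }
  out <- switch(cmd,
    "match-test" = {
      mt <- exact_match_test(matching_outcome(as.integer(opt$n),
                                              as.integer(opt$correct)))
      cat(jsonlite::toJSON(list(n = mt$n, n_correct = mt$n_correct,
                                pmf_value = mt$pmf_value, tail_p = mt$tail_p,
                                significant = mt$significant),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE),
          "\n")
      0L
    },
    "synthesize" = ,
    "run" = {
      stages <- if (cmd == "synthesize") "agreement" else
        c("optics", "agreement", "mds", "procrustes", "matching")
      if (!is.null(opt$stages)) stages <- strsplit(opt$stages, ",")[[1]]
      cfg <- pipeline_config(seed = need_seed(),
                             out_dir = if (is.null(opt$out)) "psfmatch_out"
                                       else opt$out,
                             stages = stages)
      run_pipeline(cfg)
      cat("outputs written to ", cfg$out_dir, "\n", sep = "")
      0L
    },
    "psf" = {
      z <- read_zernike_json(opt$wavefront)
      pg <- pupil_grid(z$pupil_diameter,
                       if (is.null(opt$resolution)) 256L
                       else as.integer(opt$resolution))
      psf <- psf_from_wavefront(zernike_wavefront(z$coeffs, pg, z$wavelength))
      write_psf_pgm(psf, opt$out)
      0L
    },
    "agreement" = {
      st <- consensus_study(read_likert_csv(opt$drawn),
                            read_likert_csv(opt$geometric))
      cat(jsonlite::toJSON(as.list(st$q_summary), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE), "\n")
      0L
    },
    "mds" = {
      seed <- need_seed()
      study <- read_similarity_csv(opt$ratings)
      block <- if (is.null(opt$block)) "D2G" else opt$block
      fit <- smacof_best(to_dissimilarity(mean_rating_matrix(study, block)),
                         if (is.null(opt$dim)) 3L else as.integer(opt$dim),
                         seed = seed)
      cat(sprintf("stress1\t%.6f\n", fit$stress1))
      if (!is.null(opt$out)) write_matrix_tsv(fit$coords, opt$out)
      0L
    },
    "procrustes" = {
      X <- read_matrix_tsv(opt$reference)
      Y <- read_matrix_tsv(opt$target)
      al <- procrustes_align(X, Y)
      cat(jsonlite::toJSON(list(scale = al$scale, residual = al$residual,
                                congruence = al$congruence),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE),
          "\n")
      0L
    },
    stop("unknown subcommand: ", cmd))
  invisible(out)
}

parse_cli_opts <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i])
    key <- sub("^--", "", args[i])
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opt[[key]] <- TRUE
      i <- i + 1L
    } else {
      opt[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opt
}
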