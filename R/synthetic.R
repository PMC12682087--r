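# Seeded synthetic-data generators emulating the two-phase study: multifocal
# lens design archetypes, pupil diameters, surrogate "hand-drawn" PSFs,
# ordinal Likert responses over 13 latent binary features, and similarity
# ratings generated from a planted 3-dimensional configuration with a noisier
# cross-type (drawn-vs-geometric) block.

#' Simulation configuration
#'
#' Collects every tunable of the synthetic study in one validated record.
#' Defaults state the emulated world: 15 image pairs, 13 raters, pupil
#' diameters 5.82 +/- 1.05 mm, a planted 3-dimensional similarity structure,
#' and a cross-type block with inflated noise and mid-scale self-pairs.
#'
#' @param seed Integer seed; recorded in every generated output.
#' @param n_images Number of PSF image pairs (default 15).
#' @param n_raters Number of Phase-2 raters (default 13).
#' @param pupil_mean,pupil_sd Pupil diameter distribution in mm
#'   (defaults 5.82 and 1.05).
#' @param reliability Rater reliability p in (0.5, 1]: probability that a
#'   rater endorses (response >= 4) a truly present feature (default 0.9).
#' @param fidelity Probability that a drawn image preserves each feature bit
#'   of its geometric counterpart (default 0.9).
#' @param similarity_noise_sd Rater noise SD on the 1-10 similarity scale
#'   (default 0.75).
#' @param self_boost Within-type self-pair ratings are this close to 10
#'   (noise shrink factor, default 0.1).
#' @param d2g_inflation Multiplier on rating noise in the cross block
#'   (default 2).
#' @param d2g_mid,d2g_shrink Cross-block ratings are shrunk toward `d2g_mid`
#'   by factor `d2g_shrink`, emulating mid-scale usage (defaults 6, 0.6).
#' @param planted_dim Dimensionality of the planted configuration (default 3).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L, n_images = 15L, n_raters = 13L,
                              pupil_mean = 5.82, pupil_sd = 1.05,
                              reliability = 0.9, fidelity = 0.9,
                              similarity_noise_sd = 0.75, self_boost = 0.1,
                              d2g_inflation = 2, d2g_mid = 6,
                              d2g_shrink = 0.6, planted_dim = 3L) {
  if (reliability <= 0.5 || reliability > 1) {
    stop("`reliability` must be in (0.5, 1]")
  }
  if (pupil_sd < 0 || similarity_noise_sd < 0) stop("SDs must be >= 0")
  structure(list(seed = as.integer(seed), n_images = as.integer(n_images),
                 n_raters = as.integer(n_raters), pupil_mean = pupil_mean,
                 pupil_sd = pupil_sd, reliability = reliability,
                 fidelity = fidelity,
                 similarity_noise_sd = similarity_noise_sd,
                 self_boost = self_boost, d2g_inflation = d2g_inflation,
                 d2g_mid = d2g_mid, d2g_shrink = d2g_shrink,
                 planted_dim = as.integer(planted_dim)),
            class = "simulation_config")
}

#' Multifocal lens design archetypes
#'
#' Builds the radial power profile of one of five design archetypes:
#' `single_vision` (constant base power), `centre_distance` (base power
#' centrally, progressing to base + add peripherally), `centre_near_aspheric`
#' (base + add centrally with smooth aspheric falloff to base),
#' `dual_focus_zonal` (alternating concentric zones of base and base + add),
#' and `edof` (continuous sweep across the focal range).
#'
#' @param design Design archetype name.
#' @param base_power Distance power in diopters (default 0: lens-plus-eye
#'   residual at distance).
#' @param add_power Add power in diopters (>= 0, default 2).
#' @param zone_radii Strictly increasing zone boundary radii (mm), used by
#'   `dual_focus_zonal` (default `c(1.5, 2.5, 3.5)`).
#' @param r_max Profile support radius in mm (default 4.5, covering the
#'   largest emulated pupils).
#' @return A [lens_profile()].
#' @export
make_lens_profile <- function(design = c("single_vision", "centre_distance",
                                         "centre_near_aspheric",
                                         "dual_focus_zonal", "edof"),
                              base_power = 0, add_power = 2,
                              zone_radii = c(1.5, 2.5, 3.5), r_max = 4.5) {
  design <- match.arg(design)
  if (add_power < 0) stop("`add_power` must be >= 0")
  if (design == "dual_focus_zonal") {
    if (is.unsorted(zone_radii, strictly = TRUE) || any(zone_radii <= 0)) {
      stop("zone radii must be positive and strictly increasing (overlap)")
    }
    if (any(zone_radii >= r_max)) stop("zone radii must lie inside r_max")
    edges <- c(0, zone_radii, r_max)
    powers <- rep(c(base_power, base_power + add_power),
                  length.out = length(edges) - 1L)
    zones <- data.frame(inner = edges[-length(edges)], outer = edges[-1],
                        power = powers)
    return(lens_profile(r_max = r_max, design = design, zones = zones,
                        base_power = base_power, add_power = add_power))
  }
  pw <- switch(design,
    single_vision = local({
      b <- base_power
      function(r) rep(b, length(r))
    }),
    centre_distance = local({
      b <- base_power; a <- add_power; rm <- r_max
      function(r) b + a * (pmin(r, rm) / rm)^2
    }),
    centre_near_aspheric = local({
      b <- base_power; a <- add_power; rm <- r_max
      function(r) b + a * (1 - (pmin(r, rm) / rm)^2)
    }),
    edof = local({
      b <- base_power; a <- add_power; rm <- r_max
      function(r) b + a * pmin(r, rm) / rm
    }))
  if (design == "single_vision") {
    zones <- data.frame(inner = 0, outer = r_max, power = base_power)
    return(lens_profile(r_max = r_max, design = design, zones = zones,
                        base_power = base_power, add_power = 0))
  }
  lens_profile(power = pw, r_max = r_max, design = design,
               base_power = base_power, add_power = add_power)
}

#' Sample pupil diameters
#'
#' Normal draws with the study's mean and SD, truncated by resampling to the
#' physiologically plausible range 2-9 mm.
#'
#' @param n Number of draws.
#' @param config A [simulation_config()] (uses `pupil_mean`, `pupil_sd`,
#'   `seed`).
#' @return Numeric vector of diameters (mm).
#' @export
sample_pupils <- function(n, config = simulation_config()) {
  # fixed offset decorrelates this stream from other generators sharing the
  # same base seed
  withr_seed(config$seed + 101L, {
    out <- numeric(n)
    need <- seq_len(n)
    while (length(need)) {
      out[need] <- stats::rnorm(length(need), config$pupil_mean,
                                config$pupil_sd)
      need <- which(out < 2 | out > 9)
    }
    out
  })
}

# Connected-component labelling of a logical matrix (4-neighbour), iterative
# flood fill.  Returns an integer matrix of labels (0 = background).
label_components <- function(bw) {
  n <- nrow(bw); m <- ncol(bw)
  lab <- matrix(0L, n, m)
  cur <- 0L
  todo <- which(bw)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      px <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- (px - 1L) %% n + 1L; j <- (px - 1L) %/% n + 1L
      for (nb in c(if (i > 1) px - 1L, if (i < n) px + 1L,
                   if (j > 1) px - n, if (j < m) px + n)) {
        if (bw[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          stack <- c(stack, nb)
        }
      }
    }
  }
  lab
}

#' Surrogate "hand-drawn" PSF
#'
#' Stands in for undeposited participant drawings (synthetic): thresholds the
#' PSF at an intensity quantile, keeps the largest connected features (core,
#' rings, rays), perturbs their outlines with seeded jitter (per-feature pixel
#' shifts and random pixel dropout), and renders dark-on-light.  With
#' `sketch_noise = 0` the binarized support equals the thresholded PSF
#' support exactly.
#'
#' @param psf A `geometric_psf` with at least one in-field ray.
#' @param sketch_noise Nonnegative noise level; pixel-shift SD (in pixels)
#'   and dropout rate both scale with it.
#' @param seed RNG seed.
#' @param threshold_q Intensity quantile (over positive pixels) defining the
#'   drawn support (default 0.5).
#' @param max_features Keep at most this many largest components (default 6).
#' @return An `image_raster`, dark-on-light.
#' @export
surrogate_drawn_psf <- function(psf, sketch_noise = 0.5, seed = 1L,
                                threshold_q = 0.5, max_features = 6L) {
  stopifnot(inherits(psf, "geometric_psf"))
  if (sum(psf$counts) == 0) stop("empty PSF: nothing to draw")
  inten <- psf$counts / max(psf$counts)
  thr <- stats::quantile(inten[inten > 0], threshold_q, names = FALSE)
  bw <- inten >= thr
  lab <- label_components(bw)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- order(sizes, decreasing = TRUE)[seq_len(min(max_features,
                                                        length(sizes)))]
    bw <- lab %in% keep & bw
    bw <- matrix(bw, nrow(inten), ncol(inten))
  }
  n <- nrow(bw); m <- ncol(bw)
  if (sketch_noise > 0) {
    bw <- withr_seed(seed, {
      out <- matrix(FALSE, n, m)
      lab2 <- label_components(bw)
      for (comp in seq_len(max(lab2))) {
        px <- which(lab2 == comp)
        di <- round(stats::rnorm(1, 0, sketch_noise))
        dj <- round(stats::rnorm(1, 0, sketch_noise))
        i <- (px - 1L) %% n + 1L + di; j <- (px - 1L) %/% n + 1L + dj
        ok <- i >= 1 & i <= n & j >= 1 & j <= m
        # seeded dropout roughens the outline
        ok <- ok & stats::runif(length(px)) > min(0.5, 0.15 * sketch_noise)
        out[cbind(i[ok], j[ok])] <- TRUE
      }
      out
    })
  }
  image_raster(1 - (bw * 1), psf$bin_width, "dark_on_light")
}

#' Simulate Likert feature responses
#'
#' Thresholded-latent ordinal model: each rater's latent endorsement of a
#' feature is `+1` (present) or `-1` (absent) plus Gaussian noise calibrated
#' so that P(response >= 4 | present) equals `reliability`; the latent value
#' is cut at (-1.5, -0.5, 0, 0.5) into the five ordinal tiers.  Drawn images
#' share the geometric truth bits, with each bit flipped independently with
#' probability `1 - fidelity`.
#'
#' @param truth Integer matrix `n_images x 13` of 0/1 feature-truth bits for
#'   the geometric images.
#' @param config A [simulation_config()].
#' @return List with `drawn` and `geometric` [likert_responses()], plus
#'   `truth_drawn` (the flipped truth actually used for drawn images).
#' @export
simulate_likert <- function(truth, config = simulation_config()) {
  stopifnot(is.matrix(truth), ncol(truth) == 13, all(truth %in% 0:1))
  n_img <- nrow(truth)
  sigma <- 1 / stats::qnorm(config$reliability)
  cuts <- c(-1.5, -0.5, 0, 0.5)
  withr_seed(config$seed + 211L, {  # offset: independent of truth generation
    truth_drawn <- truth
    flips <- matrix(stats::runif(length(truth)) < (1 - config$fidelity),
                    n_img, 13)
    truth_drawn[flips] <- 1L - truth_drawn[flips]
    gen <- function(tr, type) {
      grid <- expand.grid(rater = seq_len(config$n_raters),
                          image = seq_len(n_img), descriptor = 1:13)
      mu <- ifelse(tr[cbind(grid$image, grid$descriptor)] == 1, 1, -1)
      lat <- mu + sigma * stats::rnorm(nrow(grid))
      grid$response <- findInterval(lat, cuts) + 1L
      grid$image_type <- type
      likert_responses(grid)
    }
    list(geometric = gen(truth, "geometric"),
         drawn = gen(truth_drawn, "drawn"),
         truth_drawn = truth_drawn)
  })
}

#' Random feature-truth matrix
#'
#' @param n_images Number of images.
#' @param seed RNG seed.
#' @param prevalence Per-bit presence probability (default 0.5).
#' @return Integer matrix `n_images x 13` of 0/1 bits.
#' @export
simulate_feature_truth <- function(n_images = 15L, seed = 1L,
                                   prevalence = 0.5) {
  withr_seed(seed, {
    matrix(as.integer(stats::runif(n_images * 13) < prevalence), n_images, 13)
  })
}

#' Planted low-dimensional configuration
#'
#' @param n_images Number of items.
#' @param dim Dimensionality (default 3).
#' @param seed RNG seed.
#' @return Centred `n_images x dim` coordinate matrix.
#' @export
planted_configuration <- function(n_images = 15L, dim = 3L, seed = 1L) {
  withr_seed(seed, {
    X <- matrix(stats::rnorm(n_images * dim), n_images, dim)
    scale(X, scale = FALSE)[, , drop = TRUE]
  })
}

#' Simulate a similarity-rating study with planted structure
#'
#' Ratings are a monotone (convex, decreasing) map of planted inter-point
#' distances onto the 1-10 scale plus per-rater Gaussian noise, rounded and
#' clipped to 1..10.  Within-type self-pairs sit at 10 with noise shrunk by
#' `self_boost`; cross-block (D2G) cells get noise multiplied by
#' `d2g_inflation` and are shrunk toward mid-scale (`d2g_mid`, `d2g_shrink`),
#' with D2G self-pairs centred at mid-scale — emulating the greater difficulty
#' of cross-type judgements.
#'
#' @param planted Centred `n x dim` coordinate matrix (see
#'   [planted_configuration()]).
#' @param config A [simulation_config()].
#' @return A [similarity_study()] with D2D, G2G and D2G blocks.
#' @export
simulate_similarity <- function(planted, config = simulation_config()) {
  planted <- as.matrix(planted)
  n <- nrow(planted)
  Dm <- as.matrix(stats::dist(planted))
  dmax <- max(Dm)
  if (dmax == 0) stop("planted configuration is degenerate (all coincident)")
  # convex monotone map: distance 0 -> 10, max distance -> 1; the quadratic
  # decay keeps most unrelated pairs near the bottom of the scale, as raters
  # use it
  Smap <- 1 + 9 * (1 - Dm / dmax)^2
  sd0 <- config$similarity_noise_sd
  withr_seed(config$seed + 433L, {  # offset: independent of the planted draw
    rows <- list()
    for (block in c("D2D", "G2G")) {
      pairs <- which(upper.tri(Smap, diag = TRUE), arr.ind = TRUE)
      for (r in seq_len(config$n_raters)) {
        base <- Smap[pairs]
        is_self <- pairs[, 1] == pairs[, 2]
        noise <- stats::rnorm(nrow(pairs), 0, sd0)
        noise[is_self] <- noise[is_self] * config$self_boost
        base[is_self] <- 10
        rating <- pmin(10, pmax(1, round(base + noise)))
        rows[[length(rows) + 1L]] <- data.frame(
          rater = r, image_a = pairs[, 1], image_b = pairs[, 2],
          block = block, rating = rating)
      }
    }
    pairs <- as.matrix(expand.grid(i = seq_len(n), j = seq_len(n)))
    for (r in seq_len(config$n_raters)) {
      base <- Smap[pairs]
      is_self <- pairs[, 1] == pairs[, 2]
      base <- config$d2g_mid + (base - config$d2g_mid) * config$d2g_shrink
      base[is_self] <- config$d2g_mid
      noise <- stats::rnorm(nrow(pairs), 0, sd0 * config$d2g_inflation)
      rating <- pmin(10, pmax(1, round(base + noise)))
      rows[[length(rows) + 1L]] <- data.frame(
        rater = r, image_a = pairs[, 1], image_b = pairs[, 2],
        block = "D2G", rating = rating)
    }
    similarity_study(do.call(rbind, rows))
  })
}

#' Normalized-cross-correlation image matcher
#'
#' For each geometric image, picks the candidate drawn image maximising the
#' centred normalized cross-correlation.  Because drawings are binary ink
#' while rendered PSFs are graded intensity, both images are reduced to their
#' ink-support shape (thresholded at an intensity quantile) before
#' correlating, unless `binarize = FALSE`.  Used to exercise the matching
#' task on surrogate drawings.
#'
#' @param drawn,geometric Lists of `image_raster`s of equal length and size.
#' @param binarize Compare thresholded support shapes (default) rather than
#'   raw intensities.
#' @param threshold_q Intensity quantile (over positive ink values) for the
#'   support threshold.
#' @return A [matching_outcome()] with attribute `assignment` (chosen drawn
#'   index per geometric image).
#' @export
ncc_match <- function(drawn, geometric, binarize = TRUE, threshold_q = 0.5) {
  stopifnot(length(drawn) == length(geometric))
  n <- length(drawn)
  ink <- function(img) {
    v <- if (img$polarity == "dark_on_light") 1 - img$pixels else img$pixels
    if (binarize && any(v > 0)) {
      v <- (v >= stats::quantile(v[v > 0], threshold_q, names = FALSE)) * 1
    }
    v
  }
  drawn <- lapply(drawn, function(x) { x$pixels <- ink(x); x })
  geometric <- lapply(geometric, function(x) { x$pixels <- ink(x); x })
  ncc <- function(a, b) {
    a <- as.vector(a$pixels) - mean(a$pixels)
    b <- as.vector(b$pixels) - mean(b$pixels)
    den <- sqrt(sum(a^2) * sum(b^2))
    if (den == 0) return(0)
    sum(a * b) / den
  }
  pick <- vapply(seq_len(n), function(g) {
    which.max(vapply(seq_len(n), function(d) ncc(drawn[[d]], geometric[[g]]),
                     numeric(1)))
  }, integer(1))
  out <- matching_outcome(n, sum(pick == seq_len(n)))
  attr(out, "assignment") <- pick
  out
}

#' Simulate the full synthetic study
#'
#' Generates everything the pipeline consumes: lens profiles and pupils, the
#' planted configuration, feature truth, Likert responses and similarity
#' ratings.  (PSF images are generated on demand by the optics engine.)
#'
#' @param config A [simulation_config()].
#' @return List with `config`, `profiles`, `pupils`, `planted`, `truth`,
#'   `likert` (drawn + geometric response sets), `similarity`.
#' @export
simulate_study <- function(config = simulation_config()) {
  designs <- c("single_vision", "centre_distance", "centre_near_aspheric",
               "dual_focus_zonal", "edof")
  profiles <- lapply(designs, make_lens_profile)
  names(profiles) <- designs
  list(config = config,
       profiles = profiles,
       pupils = sample_pupils(config$n_images, config),
       planted = planted_configuration(config$n_images, config$planted_dim,
                                       config$seed),
       truth = simulate_feature_truth(config$n_images, config$seed),
       likert = simulate_likert(simulate_feature_truth(config$n_images,
                                                       config$seed), config),
       similarity = simulate_similarity(
         planted_configuration(config$n_images, config$planted_dim,
                               config$seed), config))
}
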