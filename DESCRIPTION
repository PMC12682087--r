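Package: psfmatch
Title: Geometric Point-Spread Functions and Perceptual Agreement Analysis for
    Multifocal Contact-Lens Optics
Version: 0.1.0
Authors@R: person("Indiana", "Optics Lab", email = "optics@example.org",
    role = c("aut", "cre"))
Description: Computes geometric-optics point-spread functions (PSFs) from
    ocular wavefront data (Zernike expansions or radial power profiles of
    multifocal contact-lens designs) by histogramming transverse ray
    aberrations, and quantifies agreement between computed ("objective") and
    perceived ("subjective", e.g. hand-drawn) PSFs.  Provides feature-consensus
    statistics on Likert ratings (Yule's Q, Phi, Cohen's kappa, mutual
    information), nonmetric multidimensional scaling by SMACOF majorization
    with Kruskal stress-1, Shepard diagrams, permutation tests and rater
    bootstrap regions, Procrustes alignment with Tucker congruence
    coefficients, an exact rencontres (derangement) null for image-matching
    tasks, and a seeded synthetic-data generator emulating a two-phase
    psychophysical study so the whole pipeline is testable without
    participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
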