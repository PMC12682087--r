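---
title: "Methods: geometric PSFs and perceptual agreement statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric PSFs and perceptual agreement statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psfmatch)
```

## The problem

Multifocal soft contact lenses correct presbyopia and slow myopia progression
by varying power across the optic zone.  That power variation deliberately
creates multiple simultaneous foci, and with them point-spread functions
(PSFs) containing rings, rays, lobes and halos that conventional image-quality
metrics (acuity, contrast sensitivity) do not capture.  A natural validation
question is whether a PSF computed from on-eye aberrometry looks like what the
wearer actually perceives.  `psfmatch` implements the full analysis chain for
that question: compute geometric-optics PSFs from wavefront data, and
quantify the agreement between computed ("objective") and perceived
("subjective", e.g. hand-drawn) PSF images with feature-consensus statistics,
nonmetric multidimensional scaling (MDS), Procrustes congruence, and an exact
combinatorial null for a direct image-matching task.

Because no participant data ship with the package, a first-class synthetic
module generates every input the pipeline needs, with planted ground truth so
that recovery can be tested.

## Geometric-optics PSF

A wavefront map gives the optical path difference $W(x, y)$ over the entrance
pupil.  In the geometric approximation each pupil sample launches a ray whose
transverse angular aberration is the wavefront gradient,
$\theta_x = \partial W / \partial x$, $\theta_y = \partial W / \partial y$,
and the PSF is the density of ray arrivals in the image plane: a 2D histogram
of $(\theta_x, \theta_y)$.  No diffraction, Stiles–Crawford apodization or
polychromatic effects are modelled; the computation is monochromatic at
570 nm (a green LED stimulus).

**Units.** The wavefront is stored in µm over pupil coordinates in mm, so a
derivative of 1 µm/mm is $10^{-3}$ rad; PSF axes are in arcmin.  These
conventions are fixed throughout and stated in the I/O documentation because
aberrometer exports vary.

**Wavefront sources.** Two input paths are supported, since instrument
exports may be either modal or zonal:

* `zernike_wavefront()` — OSA/ANSI single-indexed, unit-RMS-normalized
  Zernike coefficients in µm.
* `profile_wavefront()` — a radial power profile $P(r)$ in diopters
  (a multifocal design description), integrated through the local-vergence
  relation $W(r) = \int_0^r P(u)\, u \, du$.  Zonal (piecewise-constant)
  profiles use the exact closed form; smooth profiles use fine trapezoid
  quadrature with zone boundaries as knots.

Wavefronts are assumed distance-referenced as exported; no extra defocus
bookkeeping is performed.

**Numerical choices.** The pupil is sampled on a square Cartesian grid with a
circular mask, default 256 samples per diameter; slopes use central
differences (one-sided at grid edges); the histogram default is 255 × 255
bins over ±30 arcmin.  Published descriptions of such software rarely state
ray counts or fields of view, so these are engineering defaults; every ray
outside the field is counted (never dropped), so in-field plus out-of-field
always equals the number of in-pupil samples.  Piston changes the OPD but
not its gradient, so the PSF is piston-invariant bit for bit.

Rendering (`render_psf()`) max-normalizes counts to [0, 1], optionally
inverts to dark-on-light (ink-like, matching hand drawings), and can
resample to a target angular half-width so stimuli with different fields of
view can be compared at equal visual angles.

## Feature consensus and Yule's Q

Raters judge each image against a fixed catalog of 13 declarative feature
statements on a 5-point Likert scale.  For each image and descriptor, the
fraction of raters answering Agree or Strongly Agree (4–5) is computed, and
the binary consensus bit is 1 when that fraction **strictly** exceeds 50% —
an exact 50/50 split codes 0.  The association between the drawn and
computed consensus vectors of an image pair is Yule's
$Q = (ad - bc)/(ad + bc)$ on the 2 × 2 cross-table; sensitivity metrics
(Phi, Cohen's kappa, mutual information in bits) are computed on the same
table, and their inter-metric Pearson correlations are reported across
pairs.

Degenerate tables are handled by a signed-limit convention: $bc = 0$ with
$ad > 0$ reports $Q = +1$ (with a warning) and symmetrically $-1$; when both
products vanish $Q$ is undefined and reported as `NA` at the study level.
This preserves the ±1 interpretation rather than blurring it with a 0.5-cell
correction.  Mutual information uses $\log_2$; the base is a documented
choice.  The per-pair significance of $Q$ is a large-sample z-test on the
log odds ratio with Haldane–Anscombe 0.5-cell correction (applied to the
test only, never to the reported $Q$); the original analysis does not name
its test, so this is the package's own documented choice.

## Nonmetric MDS

Group-mean similarity matrices (1–10 scale) are converted to dissimilarities
by reverse scaling, $d_{ij} = \min(s) + \max(s) - s_{ij}$, with the min/max
taken over the cells of the matrix being converted (per-block, another
documented choice).  Note the formula maps "identical" to the observed
minimum, not to zero, and is an involution under fixed bounds.

`smacof_nonmetric()` alternates:

1. **Monotone regression.** Configuration distances are isotonically
   regressed (pool-adjacent-violators, `pava()`) onto the rank order of the
   dissimilarities — primary tie handling, ties may be untied — and the
   disparities are renormalized so $\sum \hat d^2 = \sum \rho^2$.
2. **Guttman transform.** The majorizing coordinate update with unit
   weights.

Iteration stops when the decrease of Kruskal stress-1,
$\sigma_1 = \sqrt{\sum_{i<j} (\hat d_{ij} - \rho_{ij})^2 / \sum_{i<j} \rho_{ij}^2}$,
falls below `tol` (default 1e-6, max 300 passes).  Stress is asserted
nonincreasing over iterations, and the conventional interpretation bands
(> 0.20 poor, 0.10–0.20 fair, ≤ 0.10 excellent) annotate the dimension scan.
Self-pairs are excluded from fitting (self-dissimilarity is structurally
zero); cross-block (drawn-vs-geometric) matrices are treated as inter-item
dissimilarities among the 15 *pairs* — the 15-point embedding — after
averaging the two collection orders; the diagonal self-pair ratings are
reported descriptively only.

Robustness tooling mirrors standard practice: `stress_dimension_scan()`
(best of classical + random starts per dimensionality),
`random_start_study()`, `permutation_test()` (the $n(n-1)/2$ off-diagonal
values jointly permuted, $p = (1 + \#\{\sigma_{perm} \le \sigma_{obs}\}) /
(n_{perm} + 1)$), and `bootstrap_regions()` (raters resampled with
replacement; each replicate Procrustes-aligned to the full-data solution;
95% ellipsoids from the per-item covariance at the $\chi^2_{0.95}$ radius).

**Local minima.** Nonmetric MDS has genuine local minima: even a 4-item
perfect-metric instance can trap an occasional random start at stress ≈ 0.17
while most starts reach the exact fit.  The package therefore treats "all
random starts converge" as false by design; the multistart wrapper
(`smacof_best()`) keeps the best solution and records every start's stress.

## Procrustes congruence

`procrustes_align()` solves
$\min_{s, Q, t} \sum_i \| x_i - (s Q y_i + t) \|^2$ in closed form via the
SVD of the cross-covariance of the centred configurations; reflections are
allowed by default because MDS solutions are reflection-invariant.  The
congruence coefficient is Tucker-style, computed on aligned, centred
coordinates: $c = \sum_i \langle x_i, y_i' \rangle / \sqrt{\sum_i \|x_i\|^2
\sum_i \|y_i'\|^2}$; the original report cites external references without a
formula, so this definition is the package's documented choice.
`configuration_correlation()` is deliberately distance-based (Pearson r
between vectorized inter-point distance matrices), making it
alignment-invariant by construction; whether the original correlations were
coordinate- or distance-based is unstated, and the choice is calibrated on
synthetic data only.

## Exact matching null

Matching $n$ drawn to $n$ computed images one-to-one at random, the number
of correct matches follows the rencontres distribution
$P(K = k) = \binom{n}{k}\, !(n-k) / n!$ with $!m$ the derangement number.
Since $15!$ and $!15$ exceed 32-bit range (and $!30$ the exact range of
doubles), the package carries its own arbitrary-precision integers; floats
appear only at presentation.  Useful exact facts asserted by the tests:
$\sum_k P(K = k) = 1$ and $E[K] = 1$ hold as integer identities;
$P(K = n-1) = 0$; and at $n = 15$, $P(0)$ and $P(1)$ both round to 0.37
while $P(K \ge 6) \approx 5.9 \times 10^{-4} < 0.001$.  The exact mode at
$n = 15$ is $k = 1$, because $!n = n\,!(n{-}1) + (-1)^n$ makes
$P(1) - P(0) = 1/15!$ — the familiar "0 and 1 equally likely" statement is
true only at printed precision.  Direct evaluation of the formula gives
$1.01 \times 10^{-7}$ for 10/15 and $9.12 \times 10^{-6}$ for 8/15 correct
matches; published values of order $10^{-6}$ and $7 \times 10^{-5}$ for
those outcomes are inconsistent with the formula itself, which is treated as
authoritative here.

## The synthetic world

`simulation_config()` states the emulated study once:

| parameter | default | meaning |
|---|---|---|
| `n_images` | 15 | PSF image pairs entering Phase 2 |
| `n_raters` | 13 | analysis N of the rating tasks |
| `pupil_mean`, `pupil_sd` | 5.82, 1.05 mm | right-eye pupil diameters, truncated to 2–9 mm |
| `reliability` | 0.9 | P(rater endorses a truly present feature) |
| `fidelity` | 0.9 | P(a drawing preserves each feature bit) |
| `similarity_noise_sd` | 0.75 | rater noise on the 1–10 scale |
| `d2g_inflation` | 2 | cross-block noise multiplier |
| `d2g_mid`, `d2g_shrink` | 6, 0.6 | cross-block shrink toward mid-scale |
| `planted_dim` | 3 | dimensionality of the planted configuration |

Likert responses come from a thresholded-latent (cumulative) ordinal model:
latent endorsement $\pm 1$ plus Gaussian noise with $\sigma =
1/\Phi^{-1}(\text{reliability})$, cut at $(-1.5, -0.5, 0, 0.5)$, so that
P(response ≥ 4 | feature present) equals the reliability exactly.  This is
the simplest model consistent with "fraction agreeing" semantics.

Similarity ratings are a convex decreasing map of planted inter-point
distance onto 1–10 (quadratic decay, so unrelated pairs sit near the bottom
of the scale as human raters use it), plus noise; within-type self-pairs sit
at 10 with shrunken noise, and the cross block gets inflated noise and
mid-scale shrinkage, reproducing the qualitative signature that cross-type
judgements are harder and use the middle of the scale.  Each generator draws
from a seed-offset RNG stream so that, e.g., feature truth and truth flips
are independent even under a shared base seed.

Surrogate "drawings" are raster operations on the computed PSF — threshold
at an intensity quantile, keep the largest connected features, jitter their
outlines — not stroke simulation; they are sufficient to exercise the
matching and similarity machinery, and are labelled synthetic wherever they
appear.  The matcher (`ncc_match()`) compares thresholded ink-support shapes
by normalized cross-correlation, because drawings are binary ink while
renders are graded intensity.

**What a green test establishes.** The generators emulate the *statistical
structure* of a two-phase study (planted configuration, ordinal noise,
block-wise noise inflation), not the visual appearance of real hand
drawings, pupil-size-dependent aberration structure, or rater idiosyncrasy.
Green end-to-end tests establish that the pipeline recovers planted
structure under the stated noise model — stress < 0.1 at 3D, congruence
≥ 0.9 with the planted configuration, matching significance at 10/15 — and
nothing about any particular participant's data, which were never deposited.

## Known limitations

* Geometric optics only: near-diffraction-limited eyes (PSFs dominated by
  diffraction) are outside the model's validity.
* Monocular, distance-viewing only; binocular combination and near viewing
  are not modelled.
* The PGM/PNG writers are presentation outputs; only the PGM + sidecar path
  is lossless and round-trip tested.
* Congruence and correlation definitions are package choices where the
  original analysis was underspecified (see above); comparisons against
  published coefficient values should bear that in mind.
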