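---
title: "Models and methods behind exmquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind exmquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exmquant)
```

# Scope

Expansion microscopy physically magnifies a specimen by embedding it in a
swellable gel, so that a conventional fluorescence microscope resolves
structures that would otherwise require single-molecule localization.
Iterative protocols reach roughly 16-fold expansion, at which point
quantification carries the full analysis burden: every measurement made in
the expanded frame must be converted back to true scale, and every claim of
molecular organization (8-fold pore symmetry, 9-fold centriole symmetry,
~58 nm dot periodicity along ciliary doublets) must be extracted from
images numerically. `exmquant` implements those quantification stages, plus
seeded synthetic generators that emulate each imaging target so the whole
pipeline is testable without microscope data.

All internal lengths are nanometres; NCS values are micrometres. Images
carry a mandatory pixel size; the physical centre of pixel `[i, j]`
(1-based) is `((j - 0.5) * ps, (i - 0.5) * ps)`. Because no TIFF-capable R
package is available in the supported dependency set, images are stored as
plain-text matrices with a JSON sidecar holding the calibration; the
read/write contract (pixel size honoured, explicit override with a
warning, atomic writes) is what a TIFF backend would provide.

# Corner counting on nuclear pores

A top-viewed nuclear pore labelled on its ring subunits appears as up to
`s = 8` corners on a ~107 nm circle. The algorithm works on a point cloud:
the crop's supra-threshold pixels (Otsu by default), centred at their
intensity-weighted centroid. Three steps follow.

1. **Trimming.** Exactly `ceiling(0.9 n)` points nearest the centre are
   kept, discarding radial outliers. The centre is *not* recomputed after
   trimming: recomputation would couple the outlier definition to its own
   output, and with the centroid fixed the step is a pure filter. Ties at
   the cut radius resolve by insertion order, which makes the operation
   deterministic; note that in the exactly noise-free limit all radii tie
   and the tie-break can then drop whole corners, so degenerate synthetic
   inputs should be analysed with `keep_frac = 1`.
2. **Orientation.** Point angles are folded modulo `2*pi/s` and averaged
   on the circle: `theta* = atan2(sum sin(s*a), sum cos(s*a)) / s`,
   reduced to `[0, 2*pi/s)`. This closed form is the exact minimizer of
   the circular loss `sum(1 - cos(s(a - theta)))`. A grid search over the
   same loss (default resolution 1e-3 rad) is shipped as an audit path and
   agrees with the closed form to grid resolution; a squared-wrapped-loss
   variant (`objective = "squared"`) is also available — its minimizer
   drifts from the circular mean by up to ~0.01 rad at realistic angular
   dispersion, which is why it is not the default. If the folded resultant
   vanishes (perfectly balanced angles) the orientation is flagged
   undefined and `theta* = 0` is used with a warning.
3. **Sectors and activation.** Borders sit at `theta* - pi/s + 2*pi*k/s`,
   half-open so a border point falls in the lower sector. A sector is
   *activated* when it holds strictly more than `activation_frac` (default
   0.05) of the kept points. The default sits well below the uniform share
   `1/8 = 0.125` and above localization spill at the default simulation
   noise; it is the most influential knob of the whole stage and is
   exposed everywhere.

The per-cohort histogram of activated corners is summarized by an
unweighted least-squares Gaussian fit (`A exp(-(k - mu)^2 / 2 sigma^2)`),
with `R^2` reported; degenerate histograms (fewer than three occupied
bins) return an undefined-fit flag rather than an error.

**A caveat the tests encode.** Detection output is close to, but not
exactly, a binomial thinning of the labelled corners: the activation
threshold is proportional to the total kept points, so a fully labelled
pore (more points, higher threshold) loses corners slightly more often
than a sparsely labelled one. At the default settings the detected-corner
distribution sits within ~0.06 total-variation distance of
`Binomial(8, p_eff)` with `p_eff` equal to the labelling probability up to
Monte-Carlo error. The property test asserts that closeness honestly
instead of a chi-square pass that the mechanism above genuinely violates
at n = 1000.

# Calibration, NCS and the linkage model

Expansion factors come from molecular rulers — structures of trusted size:
the NUP96 ring (107 nm), the *Toxoplasma* conoid apical diameter (380 nm),
the *Chlamydomonas* centriole proximal diameter (225 nm) and the retinal
basal body (230 nm, read at 50% of maximal intensity). `expansion_factor()`
divides the measured expanded dimension by the reference;
`correct_measurement()` is its exact inverse. Values carry full precision
internally; rounding to one decimal happens only at the reporting layer.

Ring diameters support both field conventions: `peak_to_peak` (twice the
radius of the angular-averaged radial profile maximum, parabolically
refined) and `half_max` (twice the outer radius at half the radial
maximum). The `half_max` reading of a blurred ring is always at least the
`peak_to_peak` reading.

The nucleus cross-section statistic `NCS = sqrt(area) / E` is invariant to
the gel expansion `E` because segmented area scales with `E^2`.
Segmentation is Otsu binarization, 4-connected component labelling (a
run-based union-find that handles megapixel masks in plain R), hole
filling, a minimum-area filter, and border exclusion by default — a
border-truncated nucleus has a biased area.

The antibody linkage model: a primary+secondary stack displaces the
fluorophore by `L ~ 15` nm per side. Labelled pre-expansion the linkage
expands with the specimen, so the corrected apparent diameter of a
`d`-nm tubule is `d + 2L` at any expansion. Labelled post-expansion the
linkage is added in the *expanded* frame, and correction divides it away:
`d + 2L/E`, monotonically approaching the bare diameter as `E` grows. For
a 25 nm microtubule with 15 nm linkage at `E = 16` this gives
`25 + 30/16 = 26.875` nm. The published-scale figure truncates to one
decimal (26.8); the model function returns full precision and the
reporting layer truncates.

# Profiles and periodicity

Line profiles are extracted by bilinear sampling with optional transverse
averaging. FWHM subtracts a flanking-minimum baseline by default (a raw
zero-baseline mode exists) and interpolates the half-max crossings
linearly; on a sampled Gaussian it recovers `2.3548 sigma` to better than
1% at ≥ 10 samples per sigma. Peak finding filters local maxima by
topographic prominence (as a fraction of the dynamic range) and a minimum
mutual separation, then refines positions with a 3-point parabola. Two
Gaussians of common sigma merge into a single maximum when their
separation falls to `2 sigma`; that analytic limit is both tested and used
as the principled value for separation filters (filtering wider than the
merge limit suppresses resolvable peaks — the packaged benchmark recipes
use exactly `2 sigma`).

The polar transform resamples an image onto an (angle, radius) grid about
a given centre (defaults: 360 angular bins, 1-pixel radial bins, angle 0
along +x, counterclockwise) and averages a radial band into an angular
profile. Angular offsets between channels come from circular
cross-correlation with parabolic sub-bin refinement; for an s-fold
periodic signal the answer is only defined modulo `2*pi/s`, which the
documentation flags rather than hides. Fiber angles use a total
least-squares line fit (first principal component), making the angle
invariant under uniform scaling and hence under expansion.

Periodicity along linear structures is assessed two ways, as in practice:
a one-sided FFT power spectrum (mean removed, optional Hann window,
Parseval-normalized so that the unwindowed one-sided power sums to the
detrended mean square) with the dominant period taken from a 30–120 nm
search band bracketing the ~58 nm ciliary spacing; and direct dot-interval
statistics, pooling consecutive differences across structures, with
sub-2-dot structures contributing zero intervals but still counted. The
peak-over-median-in-band "periodicity score" gets its significance from a
permutation null (sample shuffling), substituting a quantitative test for
the visual layer-line judgement.

# The synthetic world

Each generator states the world it emulates; defaults are the published
cohort conditions where those exist, and otherwise values a microscopist
would call realistic, chosen once:

* **NPC top views** — 8 corners on a 107 nm ring; per-corner labelling
  probability 0.8 (the labelling efficiency that puts the corner-histogram
  mode at 7); Poisson(20) points per labelled corner (no published spot
  count exists, so this is an assumption — Poisson matches
  fluorophore-number variability and stresses the activation threshold);
  5 nm localization jitter (likewise an assumption, consistent with the
  corrected-frame blur); random in-plane rotation.
* **Side views** — two Gaussian peaks 64 nm apart (sigma 15 nm) with a
  9.5 nm cohort SD on the separation.
* **Dot chains** — 58 nm period, 15 nm jitter, optional dropout;
  rendering blur 6.5 nm, the corrected-frame PSF of a widefield image at
  16x expansion (250 nm FWHM / 16 / 2.355). An early default of 8 nm made
  ~5% of jittered dot pairs unresolvable, contradicting the emulated
  observation that essentially all dots are countable (34 ± 3 of ~34
  sites); the PSF-derived value replaced it and the remaining ~1 nm
  interval-mean inflation from rare merges is accepted as the physics of
  resolution-limited detection.
* **Nucleus masks** — ellipses with sqrt(area) drawn
  `N(16.7 E, (2 E)^2)` µm (truncated positive by resampling, keeping the
  stated mean unbiased), axis ratio uniform on [0.7, 1], placed by
  rejection on bounding-circle overlap away from the field border.
* **Rings** — n Gaussian units on a circle of physical diameter
  `d * E`; large n approximates the continuous rings used for diameter
  calibration (the benchmark uses 8 units with 100 nm physical blur, the
  widefield PSF at the expanded scale).
* **Striped profiles** — evenly spaced Gaussian stripes with optional
  jitter and additive noise (cristae-like).

Everything is deterministic given the seed, to the bit.

What a green test does *not* establish: the generators render ideal
Gaussian spots with no camera noise model, no background gradients, no
depth-dependent distortion, no anisotropic expansion, and no segmentation
confounders (touching nuclei, intensity inhomogeneity). Recovery of a
stated mean from this world validates the algorithms' correctness, not
their robustness to real-microscope pathology.

# Numerical choices

* Threshold specifications: Otsu (256-bin between-class variance,
  first-bin tie-break across flat valleys), fraction-of-max, or absolute.
* Sub-sample refinement everywhere is the 3-point parabola; refinement is
  skipped at boundaries or non-concave stencils.
* Wrapped angular differences use `((a - b + pi) mod 2pi) - pi` mapped to
  `(-pi, pi]`, with the `-pi` boundary folded to `+pi`.
* `trim_outliers` keeps exactly `ceiling(keep_frac * n)` points; ties by
  insertion order.
* Histogram Gaussian fits run `nls` from moment-based starts and flag
  non-convergence instead of erroring.
* The striped/chain renderers sample at 1–2 nm steps; profile positions
  are validated strictly increasing and uniform.

# Benchmarks

`benchmark_target(id, seed)` regenerates each reference quantity from
scratch (ids `t1`–`t11`; see `?benchmark_target`), and
`scripts/acceptance.R --seed N --out path` writes the stochastic-cohort
subset as JSON. The deterministic ids are pure arithmetic on published
cohort means (conoid 5.3 µm and 8.5 µm against the 380 nm ruler; the
25 + 30/16 linkage computation; the 383.9/204 centriole length/diameter
ratio); the stochastic ids simulate their stated cohorts and re-measure
them end to end. The test suite asserts each at the 3-standard-error band
of its stated cohort dispersion.

# Known limitations

* No automated particle picking is required anywhere: crops, line specs
  and fiber point sets are inputs (an optional blob pre-pass would be an
  extension, and curved-structure tracing is out of scope).
* The 2D FFT of image regions is reduced to 1D along the structure axis;
  no layer-line extraction from 2D transforms.
* No distortion-field estimation or per-pixel expansion maps; one scalar
  expansion factor per calibration.
* Pure-R segmentation is adequate to a few megapixels; beyond that a
  compiled backend would be warranted.
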