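# exmquant

Quantification toolkit for (iterative) expansion microscopy. Expansion
microscopy physically magnifies specimens ~4–16× inside a swellable gel;
at those factors the microscope's job is easy and the measurement
pipeline's job is hard. `exmquant` implements the measurement side for R:

* **Nuclear-pore corner counting** — a cropped top-view pore becomes a
  point cloud (supra-threshold pixels, intensity-weighted centroid); the
  furthest 10% of points are trimmed, the 8-fold orientation θ\* is the
  circular mean of the angles folded modulo 2π/8, points are binned into 8
  sectors with borders at θ\* − π/8 + 2πk/8, and a sector counts as an
  activated corner when it holds more than a set fraction (default 5%) of
  the points. Cohort histograms of activated corners get a least-squares
  Gaussian fit with R².
* **Expansion-factor calibration** — measured expanded dimensions divided
  by molecular-ruler references (NUP96 ring 107 nm, conoid apical 380 nm,
  *Chlamydomonas* centriole 225 nm, retinal basal body 230 nm at half
  max); `correct_measurement()` maps expanded measurements back to true
  scale. Ring diameters by radial-profile peak or outer half-max.
* **Nucleus cross-section (NCS)** — Otsu binarization, connected-component
  labelling, hole filling and border exclusion give areas in µm²;
  NCS = √area / gel-expansion is expansion-invariant.
* **Antibody linkage model** — apparent tubule diameter d + 2L
  (pre-expansion labelling) or d + 2L/E (post-expansion), L ≈ 15 nm per
  antibody stack side.
* **Profiles** — line profiles (bilinear, width-averaged), FWHM with
  baseline subtraction, prominence-filtered peak finding with parabolic
  refinement, two-peak separations, polar transforms with angular
  profiles, channel angular offsets by circular cross-correlation,
  total-least-squares fiber angles.
* **Periodicity** — Parseval-normalized FFT power spectra, dominant period
  in a 30–120 nm band with a permutation-null periodicity score, and
  pooled dot-interval statistics.
* **Synthetic generators** — seeded, ground-truth-returning simulators of
  every imaging target above (NPC point clouds and renders, side-view
  double peaks, periodic dot chains, ring images, nucleus mask cohorts,
  striped profiles), so each analysis stage is testable end to end.

Units: nm everywhere internally (NCS in µm). Images are matrices with a
mandatory physical pixel size (`exm_image`), stored on disk as plain-text
CSV with a JSON calibration sidecar.

## Worked example

Simulate 500 nuclear pores with 80% per-corner labelling efficiency, run
the corner-counting pipeline, and calibrate a measurement set:

```r
library(exmquant)

prm <- npc_sim_params(ring_diameter = 107, p_label = 0.8,
                      points_per_corner = 20, loc_noise_sd = 5, seed = 7L)
cohort <- gen_npc_cohort(prm, 500)
counts <- vapply(Filter(function(g) !is.null(g$cloud), cohort),
                 function(g) count_npc_corners(g$cloud)$active_corners,
                 integer(1))
hist <- fit_gaussian_histogram(corner_histogram(counts))
hist$counts
#>   0   1   2   3   4   5   6   7   8
#>   0   0   2   7  23  75 138 161  94
hist$mode
#> [1] 7
```

The mode at 7 of 8 corners is the signature of incomplete labelling
(Binomial(8, 0.8) peaks at 7); the Gaussian regression gives
µ = 6.66, σ = 1.33, R² = 1.00.

```r
cal <- expansion_factor(1672, "nup96")   # expanded NUP96 ring in nm
cal
#> <calibration> nup96 ruler (107 nm): expanded 1672 nm -> expansion factor 15.6 x
round(correct_measurement(1371, cal), 1) # expanded inner-ring diameter
#> [1] 87.7
linkage_apparent_diameter(25, 15, 16, "post_expansion")
#> [1] 26.875
```

A 25 nm microtubule labelled *after* 16× expansion should appear 26.9 nm
wide once corrected — the linkage error shrinks by 1/E, which is the
resolution argument for post-expansion labelling.

```r
ch <- gen_periodic_chain(chain_sim_params(period = 58, n_dots = 34,
                                          jitter_sd = 15, seed = 1))
dominant_period(fft_spectrum(ch$profile))$period_nm
#> [1] 57.9
dot_intervals(find_peaks(ch$profile, 0.05, 15))
#> <periodicity> 33 intervals over 1 structures: mean 58.26 nm, sd 19.46 nm
```

## Command line

```sh
exec/exmquant simulate chain --param-file cfg.json --seed 3 --out out/
exec/exmquant npc-count --in out/npc_points.csv --out out/
exec/exmquant calibrate --ruler conoid --expanded-nm 5300 --out out/
exec/exmquant reproduce t4 --out out/
```

Every command writes a JSON report echoing its parameters and seed; same
seed, same bytes.

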