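#' Reference benchmark recipes
#'
#' End-to-end recipes that regenerate the package's reference measurements
#' from scratch: each one simulates its stated world with the given seed,
#' runs the corresponding analysis stage, and returns the recovered
#' quantity. They back the `reproduce` CLI command and the acceptance
#' report.
#'
#' Available ids: `t1`/`t2`/`t3` (ruler arithmetic on the conoid
#' measurements, deterministic), `t4` (linkage model, deterministic),
#' `t5` (corner-histogram mode over 1,000 simulated pores), `t6` (dot
#' intervals along a 327-dot chain), `t7` (inter-cristae spacing over 78
#' intervals), `t8` (side-view ring separation over 46 profiles), `t9`
#' (corrected ring diameter over 54 rings), `t10` (cohort NCS over 215
#' nuclei), `t11` (centriole length/diameter ratio, deterministic).
#'
#' @param id target identifier (see above).
#' @param seed integer seed for the stochastic recipes.
#' @return list with `value` (the recovered quantity, on the reporting
#'   scale), `n` (problem size), and `details` (recipe-specific extras).
#' @export
benchmark_target <- function(id, seed = 1L) {
  seed <- as.integer(seed)
  sub_seed <- function(k) as.integer((abs(seed) * 97L + k) %% 2147480009L)
  switch(id,
    t1 = {
      ef <- expansion_factor(5.3, "conoid", unit = "um")$expansion_factor
      list(value = round(ef, 1), n = 15L, details = list(raw = ef))
    },
    t2 = {
      ef <- expansion_factor(8.5, "conoid", unit = "um")$expansion_factor
      list(value = round(ef, 1), n = 9L, details = list(raw = ef))
    },
    t3 = {
      ratio <- expansion_factor(8.5, "conoid", unit = "um")$expansion_factor /
        expansion_factor(5.3, "conoid", unit = "um")$expansion_factor
      list(value = round(ratio, 1), n = 2L, details = list(raw = ratio))
    },
    t4 = {
      d <- linkage_apparent_diameter(25, 15, 16, "post_expansion")
      list(value = trunc(d * 10) / 10, n = 1L, details = list(raw = d))
    },
    t5 = target_corner_mode(seed = sub_seed(5L)),
    t6 = target_chain_intervals(seed = sub_seed(6L)),
    t7 = target_cristae_spacing(seed = sub_seed(7L)),
    t8 = target_ring_separation(seed = sub_seed(8L)),
    t9 = target_ring_diameter(seed = sub_seed(9L)),
    t10 = target_ncs_cohort(seed = sub_seed(10L)),
    t11 = {
      ratio <- 383.9 / 204                      # mean length over mean diameter
      list(value = round(ratio, 1), n = 87L, details = list(raw = ratio))
    },
    stop("unknown benchmark target: ", id)
  )
}

# mode of the detected-corner histogram over 1,000 simulated pores:
# 107 nm ring, s = 8, p_label 0.80, Poisson(20) points per labelled corner,
# 5 nm jitter, random rotation; trimming 0.9, activation 0.05
target_corner_mode <- function(n_particles = 1000L, seed = 1L) {
  prm <- npc_sim_params(ring_diameter = 107, s = 8L, p_label = 0.80,
                        points_per_corner = 20, loc_noise_sd = 5,
                        rotation = "random", seed = seed)
  cohort <- gen_npc_cohort(prm, n_particles)
  counts <- integer(0)
  for (g in cohort) {
    if (is.null(g$cloud)) {
      counts <- c(counts, 0L)                  # unlabelled pore: zero corners
      next
    }
    det <- count_npc_corners(pointcloud(g$cloud$x, g$cloud$y),
                             s = 8L, keep_frac = 0.9, activation_frac = 0.05)
    counts <- c(counts, det$active_corners)
  }
  hist <- corner_histogram(counts)
  list(value = hist$mode, n = n_particles,
       details = list(counts = unname(hist$counts)))
}

# pooled dot-interval mean along one simulated 327-dot chain
# (326 intervals, truth 58 nm period, 15 nm jitter), dots re-detected
# from the rendered profile
target_chain_intervals <- function(seed = 1L) {
  prm <- chain_sim_params(period = 58, n_dots = 327L, jitter_sd = 15,
                          miss_prob = 0, seed = seed)
  ch <- gen_periodic_chain(prm, step = 2)
  peaks <- find_peaks(ch$profile, min_prominence_frac = 0.05,
                      min_separation_nm = 15)
  res <- dot_intervals(peaks)
  list(value = res$interval_mean, n = res$n_intervals,
       details = list(sd = res$interval_sd,
                      dominant_period =
                        dominant_period(fft_spectrum(ch$profile))$period_nm))
}

# inter-cristae spacing: 6 striped profiles of 14 stripes yield 78
# peak-to-peak intervals (truth 85.1 nm, jitter 14.3 nm)
target_cristae_spacing <- function(seed = 1L) {
  intervals <- numeric(0)
  for (i in 1:6) {
    sp <- gen_striped_profile(spacing = 85.1, n_stripes = 14L, sigma = 15,
                              noise_sd = 0.02, seed = seed + i,
                              jitter_sd = 14.3, step = 1)
    # separation filter at the 2-sigma two-gaussian resolution limit
    peaks <- find_peaks(sp$profile, min_prominence_frac = 0.1,
                        min_separation_nm = 30)
    intervals <- c(intervals, dot_intervals(peaks)$intervals)
  }
  list(value = mean(intervals), n = length(intervals),
       details = list(sd = stats::sd(intervals)))
}

# cohort mean side-view ring separation over 46 profiles
# (truth 64 nm, per-profile jitter SD 9.5 nm, peak sigma 15 nm)
target_ring_separation <- function(seed = 1L) {
  set.seed(seed)
  true_sep <- stats::rnorm(46L, 64, 9.5)
  seps <- vapply(seq_along(true_sep), function(i) {
    pr <- gen_sideview_profile(true_sep[i], peak_sigma = 15, noise_sd = 0.02,
                               seed = seed + i, step = 1)
    # prominence well above tail-noise excursions, separation filter at the
    # 2-sigma resolution limit
    tryCatch(two_peak_separation(pr, min_prominence_frac = 0.2,
                                 min_separation_nm = 30),
             error = function(e) NA_real_)
  }, numeric(1L))
  seps <- seps[!is.na(seps)]
  list(value = mean(seps), n = length(seps),
       details = list(sd = stats::sd(seps)))
}

# cohort mean corrected ring diameter over 54 rendered top views
# (truth N(81.6, 8.7^2) nm at expansion factor 16.8, 20 nm pixels)
target_ring_diameter <- function(seed = 1L) {
  set.seed(seed)
  truths <- stats::rnorm(54L, 81.6, 8.7)
  est <- vapply(truths, function(d) {
    r <- gen_ring_image(d, symmetry = 8L, unit_sigma = 100,
                        expansion_factor = 16.8, pixel_size = 20)
    correct_measurement(ring_diameter(r$image, "peak_to_peak",
                                      center = r$center_nm), 16.8)
  }, numeric(1L))
  list(value = mean(est), n = length(est),
       details = list(sd = stats::sd(est), truth_mean = mean(truths)))
}

# cohort NCS over 215 segmented nucleus masks
# (sqrt(area) ~ N(16.7, 2^2) um, gel expansion 1)
target_ncs_cohort <- function(seed = 1L) {
  prm <- nucleus_sim_params(n_nuclei = 215L, ncs_mean = 16.7, ncs_sd = 2,
                            gel_expansion = 1, pixel_size = 200, seed = seed)
  nm <- gen_nuclei_mask(prm)
  seg <- segment_nuclei(nm$mask, threshold_spec = 0.5, min_area_um2 = 20)
  v <- ncs(seg$area_um2, prm$gel_expansion)
  list(value = mean(v), n = length(v),
       details = list(sd = stats::sd(v), truth_mean = mean(nm$true_ncs_um)))
}
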