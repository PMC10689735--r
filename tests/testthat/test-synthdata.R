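test_that("all generators are deterministic given a seed", {
  p <- npc_sim_params(seed = 11L)
  expect_identical(gen_npc_cohort(p, 5), gen_npc_cohort(p, 5))

  cp <- chain_sim_params(jitter_sd = 10, miss_prob = 0.1, seed = 11L)
  expect_identical(gen_periodic_chain(cp), gen_periodic_chain(cp))

  np <- nucleus_sim_params(n_nuclei = 4L, seed = 11L)
  expect_identical(gen_nuclei_mask(np), gen_nuclei_mask(np))

  expect_identical(gen_striped_profile(80, 5, 10, noise_sd = 0.05, seed = 11L),
                   gen_striped_profile(80, 5, 10, noise_sd = 0.05, seed = 11L))

  expect_identical(gen_sideview_profile(64, 15, noise_sd = 0.05, seed = 11L),
                   gen_sideview_profile(64, 15, noise_sd = 0.05, seed = 11L))
})

test_that("NPC point clouds obey the labelling model in limiting cases", {
  # p_label = 1, no noise: every point sits exactly on an ideal corner angle
  g <- gen_npc_pointcloud(npc_sim_params(p_label = 1, loc_noise_sd = 0,
                                         points_per_corner = 50,
                                         rotation = 0.2, seed = 3L))
  expect_true(all(g$labeled))
  folded <- (point_angles(g$cloud) - 0.2) %% (pi / 4)
  expect_true(all(pmin(folded, pi / 4 - folded) < 1e-9))
  expect_equal(point_radii(g$cloud), rep(107 / 2, g$cloud$n), tolerance = 1e-12)

  # p_label = 0: empty cloud
  g0 <- gen_npc_pointcloud(npc_sim_params(p_label = 0, seed = 3L))
  expect_null(g0$cloud)
  expect_false(any(g0$labeled))
})

test_that("labelled-corner counts follow Binomial(s, p_label)", {
  n_part <- 10000L
  p <- 0.8
  cohort <- gen_npc_cohort(npc_sim_params(p_label = p, points_per_corner = 0,
                                          seed = 101L), n_part)
  k <- vapply(cohort, function(g) sum(g$labeled), integer(1L))
  pmf <- dbinom(0:8, 8, p)                       # closed-form oracle
  obs_frac <- tabulate(k + 1L, nbins = 9L) / n_part
  mc_se <- sqrt(pmf * (1 - pmf) / n_part)
  expect_true(all(abs(obs_frac - pmf) <= 3 * mc_se + 1e-12))
  # chi-square GOF, alpha = 0.01 (pool tiny expected bins)
  pool <- pmf * n_part >= 5
  chi <- sum((obs_frac[pool] * n_part - pmf[pool] * n_part)^2 /
               (pmf[pool] * n_part))
  expect_lt(chi, qchisq(0.99, sum(pool) - 1L))
})

test_that("render_image is normalized, linear and translation-equivariant", {
  img1 <- one_spot_image(97.5, 97.5)            # exactly on a pixel centre
  ctr <- which(unclass(img1) == max(img1), arr.ind = TRUE)
  expect_equal(as.integer(ctr), c(20L, 20L))

  # linearity: two identical points = 2x one point
  img2 <- render_image(pointcloud(c(97.5, 97.5), c(97.5, 97.5),
                                  center = c(97.5, 97.5)),
                       5, 10, 200)
  expect_equal(unclass(img2), 2 * unclass(img1), tolerance = 1e-12)

  # integrated intensity proportional to point count (integration oracle)
  set.seed(42)
  n_pts <- 7L
  cl <- pointcloud(runif(n_pts, 80, 120), runif(n_pts, 80, 120),
                   center = c(100, 100))
  imgN <- render_image(cl, 5, 10, 200)
  expect_equal(sum(imgN) / sum(img1), n_pts, tolerance = 1e-3)

  # translation equivariance to pixel resolution
  shifted <- render_image(transform_cloud(cl, dx = 25, dy = -15), 5, 10, 200)
  am0 <- which(unclass(imgN) == max(imgN), arr.ind = TRUE)[1L, ]
  am1 <- which(unclass(shifted) == max(shifted), arr.ind = TRUE)[1L, ]
  expect_equal(as.integer(am1 - am0), as.integer(c(-15, 25) / 5))

  # points outside the field are an error naming the coordinate
  expect_error(render_image(pointcloud(500, 10, center = c(500, 10)), 5, 10, 200),
               "outside")
})

test_that("side-view profiles place two peaks at the stated separation", {
  pr <- gen_sideview_profile(64, peak_sigma = 9.5, noise_sd = 0, step = 1)
  pk <- find_peaks(pr, 0.2)
  expect_length(pk, 2L)
  expect_equal(diff(pk), 64, tolerance = 1)

  # separation 0 collapses to a single peak
  pr0 <- gen_sideview_profile(0, peak_sigma = 10)
  expect_length(find_peaks(pr0, 0.2), 1L)

  # analytic-peak oracle: well-separated peaks recovered to sub-sample accuracy
  pr100 <- gen_sideview_profile(100, peak_sigma = 10, noise_sd = 0, step = 1)
  expect_equal(two_peak_separation(pr100), 100, tolerance = 0.5)
})

test_that("periodic chains follow the dot model", {
  ch <- gen_periodic_chain(chain_sim_params(period = 58, n_dots = 34L,
                                            jitter_sd = 0, miss_prob = 0,
                                            seed = 1L), render = FALSE)
  expect_equal(diff(ch$positions), rep(58, 33), tolerance = 1e-12)

  ch_none <- gen_periodic_chain(chain_sim_params(miss_prob = 1, seed = 1L))
  expect_length(ch_none$positions, 0L)
  expect_null(ch_none$profile)

  # CLT bound on the interval mean of the generated positions
  ch_j <- gen_periodic_chain(chain_sim_params(period = 58, n_dots = 327L,
                                              jitter_sd = 15, seed = 5L),
                             render = FALSE)
  m <- mean(diff(ch_j$positions))
  expect_lt(abs(m - 58), 3 * 15 / sqrt(326))
})

test_that("nucleus masks reproduce their stated geometry", {
  # one circle: segmented area matches pi r^2 up to boundary pixels
  p1 <- nucleus_sim_params(n_nuclei = 1L, ncs_mean = 10, ncs_sd = 0,
                           ellipticity_range = c(1, 1), pixel_size = 100,
                           seed = 2L)
  nm <- gen_nuclei_mask(p1, field_um = 30)
  seg <- segment_nuclei(nm$mask, threshold_spec = 0.5, min_area_um2 = 1)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$area_um2, 100, tolerance = 0.02)   # sqrt(area) = 10 um

  # ncs_sd = 0: all recovered NCS equal within discretization tolerance
  p0 <- nucleus_sim_params(n_nuclei = 6L, ncs_mean = 12, ncs_sd = 0,
                           pixel_size = 150, seed = 3L)
  nm0 <- gen_nuclei_mask(p0)
  seg0 <- segment_nuclei(nm0$mask, threshold_spec = 0.5, min_area_um2 = 1)
  v <- ncs(seg0$area_um2, 1)
  expect_equal(nrow(seg0), 6L)
  expect_lt(diff(range(v)), 0.05)

  # too-small field errors
  expect_error(gen_nuclei_mask(nucleus_sim_params(n_nuclei = 10L, seed = 4L),
                               field_um = 25, max_attempts = 50L),
               "field too small")
})

test_that("ring images have the stated diameter and symmetry", {
  # n = 2: a diametric profile shows two peaks d * EF apart
  r2 <- gen_ring_image(100, symmetry = 2L, unit_sigma = 15,
                       expansion_factor = 3, pixel_size = 5)
  mid_px <- r2$center_nm[2L] / pixel_size(r2$image)
  prof <- extract_line_profile(r2$image, c(0, mid_px),
                               c(ncol(r2$image), mid_px))
  expect_equal(two_peak_separation(prof), 300, tolerance = 2)

  # 9-fold ring: polar transform shows 9 angular peaks 40 degrees apart
  r9 <- gen_ring_image(300, symmetry = 9L, unit_sigma = 25, pixel_size = 10,
                       rotation = 0.2)
  pol <- polar_transform(r9$image, r9$center_nm, radial_band = c(120, 180))
  pk <- find_peaks(line_profile(pol$angle_bins, pol$angular_profile,
                                meta = list()), 0.3)
  expect_length(pk, 9L)
  expect_equal(diff(pk), rep(2 * pi / 9, 8), tolerance = 0.02)
})

test_that("striped profiles behave like rendered chains", {
  sp <- gen_striped_profile(85.1, 10, sigma = 15, noise_sd = 0, seed = 1L,
                            step = 1)
  pk <- find_peaks(sp$profile, 0.1, min_separation_nm = 30)
  expect_length(pk, 10L)
  expect_equal(diff(pk), rep(85.1, 9), tolerance = 1)

  # a single stripe yields no interval
  sp1 <- gen_striped_profile(85.1, 1, sigma = 15, seed = 1L)
  res <- dot_intervals(find_peaks(sp1$profile, 0.1))
  expect_equal(res$n_intervals, 0L)
  expect_equal(unname(res$dots_per_structure), 1L)

  # analytic merge condition: two gaussians closer than 2 sigma fuse into
  # one peak, so overlapping stripes yield fewer intervals
  sp_merge <- gen_striped_profile(30, 2, sigma = 20, seed = 1L)
  expect_length(find_peaks(sp_merge$profile, 0.1), 1L)
})
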