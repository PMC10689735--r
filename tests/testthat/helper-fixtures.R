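# shared fixture builders; everything is generated in code at test time

# ideal s-fold ring cloud: n_per points exactly at each corner angle
make_ring_cloud <- function(s = 8L, radius = 53.5, rotation = 0, n_per = 5L,
                            center = c(0, 0), jitter_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ang <- rep(rotation + 2 * pi * (0:(s - 1L)) / s, each = n_per)
  x <- center[1L] + radius * cos(ang)
  y <- center[2L] + radius * sin(ang)
  if (jitter_sd > 0) {
    x <- x + rnorm(length(x), 0, jitter_sd)
    y <- y + rnorm(length(y), 0, jitter_sd)
  }
  pointcloud(x, y, center = center)
}

# render a gaussian spot image with a single point, for linearity oracles
one_spot_image <- function(x_nm, y_nm, pixel_size = 5, spot_sigma = 10,
                           field = 200) {
  render_image(pointcloud(x_nm, y_nm, center = c(x_nm, y_nm)),
               pixel_size, spot_sigma, field)
}

# run the full corner-counting pipeline over a simulated cohort and
# return the vector of active-corner counts (particles with no labelled
# corner are skipped, as an empty crop would be upstream)
detect_cohort_corners <- function(params, n_particles) {
  cohort <- gen_npc_cohort(params, n_particles)
  counts <- integer(0)
  for (g in cohort) {
    if (is.null(g$cloud)) next
    det <- count_npc_corners(pointcloud(g$cloud$x, g$cloud$y))
    counts <- c(counts, det$active_corners)
  }
  counts
}
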