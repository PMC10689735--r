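#' Simulation parameters for top-view NPC particles
#'
#' Describes the generative model for an 8-fold-symmetric nuclear-pore
#' top view: `s` corners on a ring of true (corrected) diameter
#' `ring_diameter`, each corner independently labelled with probability
#' `p_label`; a labelled corner contributes `Poisson(points_per_corner)`
#' localizations at its ideal position, each displaced by isotropic
#' Gaussian jitter of SD `loc_noise_sd`. Physical (expanded-frame) sizes
#' are the true sizes times `expansion_factor`.
#'
#' @param ring_diameter true ring diameter in nm (default 107, the NUP96
#'   reference).
#' @param s symmetry order, integer >= 2 (default 8).
#' @param p_label per-corner labelling probability in `[0, 1]`.
#' @param points_per_corner Poisson mean of localizations per labelled
#'   corner.
#' @param loc_noise_sd localization jitter SD in nm (corrected frame).
#' @param rotation in-plane particle rotation in radians, or `"random"`.
#' @param expansion_factor dimensionless gel expansion (1 = native frame).
#' @param pixel_size rendering pixel size in nm.
#' @param spot_sigma rendering blur SD in nm.
#' @param seed integer RNG seed.
#' @return validated parameter list of class `npc_sim_params`.
#' @export
npc_sim_params <- function(ring_diameter = 107, s = 8L, p_label = 0.8,
                           points_per_corner = 20, loc_noise_sd = 5,
                           rotation = "random", expansion_factor = 1,
                           pixel_size = 5, spot_sigma = 5, seed = 1L) {
  stopifnot(ring_diameter > 0, s >= 2, p_label >= 0, p_label <= 1,
            points_per_corner >= 0, loc_noise_sd >= 0,
            expansion_factor > 0, pixel_size > 0, spot_sigma >= 0)
  structure(list(ring_diameter = ring_diameter, s = as.integer(s),
                 p_label = p_label, points_per_corner = points_per_corner,
                 loc_noise_sd = loc_noise_sd, rotation = rotation,
                 expansion_factor = expansion_factor,
                 pixel_size = pixel_size, spot_sigma = spot_sigma,
                 seed = as.integer(seed)),
            class = "npc_sim_params")
}

#' Simulate one NPC top-view point cloud with ground truth
#'
#' Points are generated in the corrected (true-size) frame and then scaled
#' by `expansion_factor`, centred at `center`. The returned cloud keeps
#' the true centre (the generator knows it); analyses that must not peek
#' re-derive the centre themselves.
#'
#' @param params an [npc_sim_params()] object.
#' @param center particle centre `(x, y)` in nm (default origin).
#' @return list with `cloud` (an `exm_pointcloud`, or NULL when no corner
#'   is labelled), `labeled` (logical length-s ground-truth mask),
#'   `rotation` (realized rotation, radians), `params`.
#' @export
gen_npc_pointcloud <- function(params, center = c(0, 0)) {
  stopifnot(inherits(params, "npc_sim_params"))
  set.seed(params$seed)
  gen_npc_pointcloud_impl(params, center)
}

# RNG-stream variant used internally to draw many particles in one stream.
gen_npc_pointcloud_impl <- function(params, center = c(0, 0)) {
  s <- params$s
  rot <- params$rotation
  if (identical(rot, "random")) rot <- stats::runif(1L, 0, 2 * pi)
  labeled <- stats::runif(s) < params$p_label
  radius <- params$ring_diameter / 2 * params$expansion_factor
  xs <- numeric(0); ys <- numeric(0)
  for (k in which(labeled)) {
    n_pts <- stats::rpois(1L, params$points_per_corner)
    if (n_pts == 0L) next
    ang <- rot + 2 * pi * (k - 1L) / s
    jit_sd <- params$loc_noise_sd * params$expansion_factor
    xs <- c(xs, radius * cos(ang) + stats::rnorm(n_pts, 0, jit_sd))
    ys <- c(ys, radius * sin(ang) + stats::rnorm(n_pts, 0, jit_sd))
  }
  cloud <- if (length(xs) > 0L) {
    pointcloud(xs + center[1L], ys + center[2L], center = center)
  } else NULL
  list(cloud = cloud, labeled = labeled, rotation = rot %% (2 * pi),
       params = params)
}

#' Simulate a cohort of NPC particles
#'
#' Draws `n_particles` independent particles from one seeded RNG stream.
#'
#' @param params an [npc_sim_params()] object (its `seed` seeds the whole
#'   cohort).
#' @param n_particles number of particles.
#' @return list of per-particle results as in [gen_npc_pointcloud()].
#' @export
gen_npc_cohort <- function(params, n_particles) {
  stopifnot(inherits(params, "npc_sim_params"), n_particles >= 1)
  set.seed(params$seed)
  lapply(seq_len(n_particles), function(i) gen_npc_pointcloud_impl(params))
}

#' Render a point cloud as a Gaussian-spot image
#'
#' Each point becomes a normalized 2D Gaussian of SD `spot_sigma` (nm), so
#' the integrated intensity is proportional to the point count. Points
#' must lie inside the field.
#'
#' @param cloud an `exm_pointcloud` (coordinates in nm, field frame with
#'   origin at the image corner).
#' @param pixel_size nm per pixel.
#' @param spot_sigma Gaussian SD in nm.
#' @param field_size field edge in nm (scalar for square, or `c(x, y)`);
#'   image is `field_size / pixel_size` pixels.
#' @return an `exm_image`.
#' @export
render_image <- function(cloud, pixel_size, spot_sigma, field_size) {
  if (length(field_size) == 1L) field_size <- c(field_size, field_size)
  ncol_px <- as.integer(round(field_size[1L] / pixel_size))
  nrow_px <- as.integer(round(field_size[2L] / pixel_size))
  bad <- which(cloud$x < 0 | cloud$x > field_size[1L] |
               cloud$y < 0 | cloud$y > field_size[2L])
  if (length(bad) > 0L) {
    stop(sprintf("point (%.2f, %.2f) nm lies outside the %g x %g nm field",
                 cloud$x[bad[1L]], cloud$y[bad[1L]],
                 field_size[1L], field_size[2L]))
  }
  img <- matrix(0, nrow_px, ncol_px)
  xc <- (seq_len(ncol_px) - 0.5) * pixel_size
  yc <- (seq_len(nrow_px) - 0.5) * pixel_size
  half_win <- 5 * spot_sigma
  norm_const <- pixel_size^2 / (2 * pi * spot_sigma^2)
  for (i in seq_len(cloud$n)) {
    px <- cloud$x[i]; py <- cloud$y[i]
    jj <- which(xc >= px - half_win & xc <= px + half_win)
    ii <- which(yc >= py - half_win & yc <= py + half_win)
    if (length(ii) == 0L || length(jj) == 0L) next
    gx <- exp(-(xc[jj] - px)^2 / (2 * spot_sigma^2))
    gy <- exp(-(yc[ii] - py)^2 / (2 * spot_sigma^2))
    img[ii, jj] <- img[ii, jj] + norm_const * outer(gy, gx)
  }
  exm_image(img, pixel_size)
}

#' Simulate a side-view two-ring intensity profile
#'
#' Two Gaussian peaks of SD `peak_sigma` centred at +/- `separation`/2
#' about the profile midpoint, plus optional additive Gaussian noise —
#' the appearance of a nuclear pore seen from the side, where the
#' cytoplasmic and nucleoplasmic rings form two parallel intensity bands.
#'
#' @param separation true peak separation in nm (0 gives a single peak).
#' @param peak_sigma Gaussian SD of each peak in nm.
#' @param noise_sd additive noise SD (intensity units; peak height 1).
#' @param seed integer seed (used only when `noise_sd > 0`).
#' @param step sample spacing in nm.
#' @param length_nm total profile length in nm (default auto: separation
#'   plus 8 sigma margin each side).
#' @return a `line_profile` (see [line_profile()]).
#' @export
gen_sideview_profile <- function(separation, peak_sigma, noise_sd = 0,
                                 seed = 1L, step = 1,
                                 length_nm = separation + 16 * peak_sigma) {
  stopifnot(separation >= 0, peak_sigma > 0, step > 0)
  pos <- seq(0, length_nm, by = step)
  mid <- length_nm / 2
  y <- exp(-(pos - (mid - separation / 2))^2 / (2 * peak_sigma^2)) +
       exp(-(pos - (mid + separation / 2))^2 / (2 * peak_sigma^2))
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  line_profile(pos, y)
}

#' Simulation parameters for a periodic dot chain
#'
#' Emulates a periodically decorated linear structure (e.g. a ciliary
#' microtubule doublet carrying evenly spaced protein dots): dot `k` sits
#' at `k * period` plus Gaussian jitter, and is independently missed with
#' probability `miss_prob`.
#'
#' @param period true dot spacing in nm.
#' @param n_dots number of dot sites, >= 2.
#' @param jitter_sd positional jitter SD in nm.
#' @param miss_prob per-dot drop probability in `[0, 1]`.
#' @param dot_sigma rendering blur SD in nm, corrected frame. Default 6.5,
#'   the corrected-frame width of a widefield point-spread function at
#'   16x expansion (~250 nm FWHM / 16 / 2.355).
#' @param seed integer seed.
#' @return validated parameter list of class `chain_sim_params`.
#' @export
chain_sim_params <- function(period = 58, n_dots = 34L, jitter_sd = 15,
                             miss_prob = 0, dot_sigma = 6.5, seed = 1L) {
  stopifnot(period > 0, n_dots >= 2, jitter_sd >= 0,
            miss_prob >= 0, miss_prob <= 1, dot_sigma > 0)
  structure(list(period = period, n_dots = as.integer(n_dots),
                 jitter_sd = jitter_sd, miss_prob = miss_prob,
                 dot_sigma = dot_sigma, seed = as.integer(seed)),
            class = "chain_sim_params")
}

#' Simulate a periodic dot chain and its rendered profile
#'
#' @param params a [chain_sim_params()] object.
#' @param step rendered profile sample spacing in nm (default 2).
#' @param render logical; set FALSE to skip rendering (positions only).
#' @return list with `positions` (sorted dot positions, nm; may be empty),
#'   `profile` (a `line_profile` or NULL), `params`.
#' @export
gen_periodic_chain <- function(params, step = 2, render = TRUE) {
  stopifnot(inherits(params, "chain_sim_params"))
  set.seed(params$seed)
  sites <- seq_len(params$n_dots) * params$period
  pos <- sites + stats::rnorm(params$n_dots, 0, params$jitter_sd)
  kept <- stats::runif(params$n_dots) >= params$miss_prob
  pos <- sort(pos[kept])
  profile <- NULL
  if (render && length(pos) > 0L) {
    margin <- 6 * params$dot_sigma
    grid <- seq(min(pos) - margin, max(pos) + margin, by = step)
    y <- rep(0, length(grid))
    for (p in pos) y <- y + exp(-(grid - p)^2 / (2 * params$dot_sigma^2))
    profile <- line_profile(grid, y)
  }
  list(positions = pos, profile = profile, params = params)
}

#' Simulation parameters for a cohort of nucleus masks
#'
#' The emulated statistic is the nucleus cross-section NCS =
#' sqrt(area) / gel_expansion: nuclei are ellipses whose sqrt(area), in
#' the expanded frame, is drawn from
#' `N(ncs_mean * gel_expansion, (ncs_sd * gel_expansion)^2)` truncated
#' positive (negative draws are resampled so the stated mean stays
#' unbiased for realistic parameters).
#'
#' @param n_nuclei number of nuclei, >= 1.
#' @param ncs_mean target NCS mean in micrometres.
#' @param ncs_sd NCS SD in micrometres.
#' @param ellipticity_range `c(a, b)` with `0 < a <= b <= 1`: the minor/
#'   major axis ratio is uniform on this interval.
#' @param gel_expansion dimensionless gel expansion factor.
#' @param pixel_size nm per pixel of the rendered mask.
#' @param seed integer seed.
#' @return validated parameter list of class `nucleus_sim_params`.
#' @export
nucleus_sim_params <- function(n_nuclei = 215L, ncs_mean = 16.7, ncs_sd = 2,
                               ellipticity_range = c(0.7, 1),
                               gel_expansion = 1, pixel_size = 200,
                               seed = 1L) {
  stopifnot(n_nuclei >= 1, ncs_mean > 0, ncs_sd >= 0,
            ellipticity_range[1L] > 0,
            ellipticity_range[1L] <= ellipticity_range[2L],
            ellipticity_range[2L] <= 1,
            gel_expansion > 0, pixel_size > 0)
  structure(list(n_nuclei = as.integer(n_nuclei), ncs_mean = ncs_mean,
                 ncs_sd = ncs_sd, ellipticity_range = ellipticity_range,
                 gel_expansion = gel_expansion, pixel_size = pixel_size,
                 seed = as.integer(seed)),
            class = "nucleus_sim_params")
}

#' Simulate a field of non-overlapping elliptical nucleus masks
#'
#' Nuclei are placed uniformly at random with rejection on bounding-circle
#' overlap (and on touching the field border, so segmentation's border
#' exclusion never removes a simulated nucleus). The default field is
#' sized for roughly 30% packing.
#'
#' @param params a [nucleus_sim_params()] object.
#' @param field_um field edge in micrometres (default auto from n and
#'   sizes).
#' @param max_attempts resampling attempts per nucleus before giving up.
#' @return list with `mask` (an `exm_image` label image: 0 background,
#'   1..n per nucleus), `true_areas_um2` (expanded-frame areas of the
#'   generating ellipses), `true_ncs_um`, `params`.
#' @export
gen_nuclei_mask <- function(params, field_um = NULL, max_attempts = 2000L) {
  stopifnot(inherits(params, "nucleus_sim_params"))
  set.seed(params$seed)
  n <- params$n_nuclei
  e <- params$gel_expansion
  # truncated-positive normal by resampling
  sqrt_area <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1L, params$ncs_mean * e, params$ncs_sd * e)
      if (v > 0) break
    }
    sqrt_area[i] <- v
  }
  areas <- sqrt_area^2                       # um^2, expanded frame
  ratio <- stats::runif(n, params$ellipticity_range[1L],
                        params$ellipticity_range[2L])
  # area = pi * a * b with b = ratio * a
  a_um <- sqrt(areas / (pi * ratio))
  b_um <- ratio * a_um
  phi <- stats::runif(n, 0, pi)

  r_bound <- a_um                            # bounding circle = major semi-axis
  if (is.null(field_um)) {
    field_um <- sqrt(sum(pi * r_bound^2) / 0.30)
  }
  cx <- numeric(n); cy <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      px <- stats::runif(1L, r_bound[i], field_um - r_bound[i])
      py <- stats::runif(1L, r_bound[i], field_um - r_bound[i])
      if (i == 1L ||
          all((px - cx[seq_len(i - 1L)])^2 + (py - cy[seq_len(i - 1L)])^2 >
              (r_bound[i] + r_bound[seq_len(i - 1L)] + 0.5)^2)) {
        cx[i] <- px; cy[i] <- py; ok <- TRUE; break
      }
    }
    if (!ok) stop("field too small: could not place nucleus ", i,
                  " after ", max_attempts, " attempts")
  }

  ps_um <- params$pixel_size / 1000
  n_px <- as.integer(ceiling(field_um / ps_um))
  mask <- matrix(0L, n_px, n_px)
  xc <- (seq_len(n_px) - 0.5) * ps_um
  for (i in seq_len(n)) {
    # rasterize within the bounding box of the ellipse
    jj <- which(xc >= cx[i] - a_um[i] & xc <= cx[i] + a_um[i])
    ii <- which(xc >= cy[i] - a_um[i] & xc <= cy[i] + a_um[i])
    dx <- xc[jj] - cx[i]; dy <- xc[ii] - cy[i]
    cphi <- cos(phi[i]); sphi <- sin(phi[i])
    u <- outer(dy, dx, function(Y, X) (X * cphi + Y * sphi) / a_um[i])
    v <- outer(dy, dx, function(Y, X) (-X * sphi + Y * cphi) / b_um[i])
    inside <- u^2 + v^2 <= 1
    sub <- mask[ii, jj]
    sub[inside] <- i
    mask[ii, jj] <- sub
  }
  list(mask = exm_image(mask, params$pixel_size),
       true_areas_um2 = areas,
       true_ncs_um = sqrt_area / e,
       centers_um = cbind(x = cx, y = cy),
       params = params)
}

#' Simulate a ring image with n-fold symmetry
#'
#' `symmetry` Gaussian units evenly spaced on a circle of physical
#' diameter `diameter * expansion_factor`, rendered at `pixel_size`.
#' Large `symmetry` approximates a continuous ring. Used to emulate
#' top-view pore rings, centriole 9-fold views, and similar annular
#' targets.
#'
#' @param diameter true (corrected) ring diameter in nm.
#' @param symmetry number of units on the ring, >= 2.
#' @param unit_sigma Gaussian SD of each unit in nm (physical frame).
#' @param expansion_factor dimensionless.
#' @param pixel_size nm per pixel.
#' @param seed integer seed (reserved for optional noise).
#' @param noise_sd additive Gaussian image noise SD (0 = none).
#' @param rotation ring rotation in radians.
#' @param field_size field edge in nm (default: ring diameter + 8 sigma
#'   margin).
#' @return list with `image` (an `exm_image`), `center_nm` (`c(x, y)`),
#'   `physical_diameter_nm`.
#' @export
gen_ring_image <- function(diameter, symmetry = 8L, unit_sigma = 40,
                           expansion_factor = 1, pixel_size = 20,
                           seed = 1L, noise_sd = 0, rotation = 0,
                           field_size = NULL) {
  stopifnot(diameter > 0, symmetry >= 2, unit_sigma > 0,
            expansion_factor > 0, pixel_size > 0)
  phys_d <- diameter * expansion_factor
  if (is.null(field_size)) field_size <- phys_d + 16 * unit_sigma
  center <- c(field_size, field_size) / 2
  ang <- rotation + 2 * pi * (seq_len(symmetry) - 1L) / symmetry
  cloud <- pointcloud(center[1L] + phys_d / 2 * cos(ang),
                      center[2L] + phys_d / 2 * sin(ang),
                      center = center)
  img <- render_image(cloud, pixel_size, unit_sigma, field_size)
  if (noise_sd > 0) {
    set.seed(seed)
    img <- exm_image(unclass(img) +
                       matrix(stats::rnorm(length(img), 0, noise_sd),
                              nrow(img), ncol(img)),
                     pixel_size)
  }
  list(image = img, center_nm = center, physical_diameter_nm = phys_d)
}

#' Simulate a striped (multi-band) intensity profile
#'
#' Evenly spaced Gaussian stripes with optional positional jitter and
#' additive noise, emulating e.g. a line profile across stacked
#' mitochondrial cristae.
#'
#' @param spacing true stripe spacing in nm.
#' @param n_stripes number of stripes, >= 1.
#' @param sigma stripe Gaussian SD in nm.
#' @param noise_sd additive intensity noise SD (stripe height 1).
#' @param seed integer seed.
#' @param jitter_sd per-stripe positional jitter SD in nm (default 0).
#' @param step sample spacing in nm.
#' @return list with `positions` (true stripe centres, nm, sorted) and
#'   `profile` (a `line_profile`).
#' @export
gen_striped_profile <- function(spacing, n_stripes, sigma, noise_sd = 0,
                                seed = 1L, jitter_sd = 0, step = 2) {
  stopifnot(spacing > 0, n_stripes >= 1, sigma > 0, step > 0)
  set.seed(seed)
  centers <- seq_len(n_stripes) * spacing
  if (jitter_sd > 0) centers <- centers + stats::rnorm(n_stripes, 0, jitter_sd)
  centers <- sort(centers)
  margin <- 6 * sigma
  grid <- seq(min(centers) - margin, max(centers) + margin, by = step)
  y <- rep(0, length(grid))
  for (p in centers) y <- y + exp(-(grid - p)^2 / (2 * sigma^2))
  if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
  list(positions = centers, profile = line_profile(grid, y))
}
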