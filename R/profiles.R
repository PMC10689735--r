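#' Uniformly sampled 1D intensity profile
#'
#' @param positions strictly increasing, uniformly spaced positions in nm.
#' @param intensities intensities (arbitrary units), same length.
#' @param meta optional named list of source metadata (line endpoints,
#'   averaging width, ...).
#' @return object of class `line_profile` with `positions`, `intensities`,
#'   `step`, `meta`.
#' @export
line_profile <- function(positions, intensities, meta = list()) {
  if (length(positions) != length(intensities)) stop("length mismatch")
  if (length(positions) < 2L) stop("profile needs >= 2 samples")
  d <- diff(positions)
  if (any(d <= 0)) stop("positions must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * stats::median(d)) {
    stop("positions must be uniformly spaced")
  }
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities),
                 step = stats::median(d), meta = meta),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples, %.3g nm step, span %.4g nm\n",
              length(x$positions), x$step, diff(range(x$positions))))
  invisible(x)
}

# bilinear image interpolation at physical (x, y) nm; outside -> 0
bilinear_at <- function(image, x_nm, y_nm) {
  ps <- pixel_size(image)
  m <- unclass(image)
  # fractional pixel indices (1-based, pixel centre of [i,j] at (j-.5, i-.5)*ps)
  fj <- x_nm / ps + 0.5
  fi <- y_nm / ps + 0.5
  j0 <- floor(fj); i0 <- floor(fi)
  tj <- fj - j0; ti <- fi - i0
  val <- function(i, j) {
    ok <- i >= 1 & i <= nrow(m) & j >= 1 & j <= ncol(m)
    out <- numeric(length(i))
    out[ok] <- m[cbind(i[ok], j[ok])]
    out
  }
  (1 - ti) * (1 - tj) * val(i0, j0) + (1 - ti) * tj * val(i0, j0 + 1) +
    ti * (1 - tj) * val(i0 + 1, j0) + ti * tj * val(i0 + 1, j0 + 1)
}

#' Extract an intensity profile along a line segment
#'
#' Bilinear sampling along the segment from `p0` to `p1`, optionally
#' averaged transversally over `width_px` parallel lines (1 px apart),
#' the standard "plot profile" operation.
#'
#' @param image an `exm_image`.
#' @param p0,p1 endpoints in pixel units `c(x_px, y_px)` (0-based corner
#'   frame, i.e. the centre of pixel `[1,1]` is `(0.5, 0.5)`).
#' @param width_px transverse averaging width in pixels (odd integer).
#' @return a `line_profile` with positions in nm starting at 0.
#' @export
extract_line_profile <- function(image, p0, p1, width_px = 1L) {
  ps <- pixel_size(image)
  for (p in list(p0, p1)) {
    if (p[1L] < 0 || p[1L] > ncol(image) || p[2L] < 0 || p[2L] > nrow(image)) {
      stop("endpoint (", p[1L], ", ", p[2L], ") px lies outside the image")
    }
  }
  d <- p1 - p0
  len_px <- sqrt(sum(d^2))
  if (len_px == 0) stop("degenerate line: identical endpoints")
  n_samp <- max(2L, as.integer(ceiling(len_px)) + 1L)
  t_seq <- seq(0, 1, length.out = n_samp)
  u <- d / len_px                      # unit tangent
  v <- c(-u[2L], u[1L])                # unit normal
  offsets <- seq_len(width_px) - (width_px + 1) / 2
  acc <- numeric(n_samp)
  for (o in offsets) {
    xs <- (p0[1L] + t_seq * d[1L] + o * v[1L]) * ps
    ys <- (p0[2L] + t_seq * d[2L] + o * v[2L]) * ps
    acc <- acc + bilinear_at(image, xs, ys)
  }
  line_profile(t_seq * len_px * ps, acc / width_px,
               meta = list(p0 = p0, p1 = p1, width_px = width_px))
}

# 3-point parabolic vertex refinement around index i (interior)
parabolic_refine <- function(x, y, i) {
  if (i <= 1L || i >= length(y)) return(x[i])
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (denom >= 0) return(x[i])
  delta <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  x[i] + delta * (x[2L] - x[1L])
}

#' Full width at half maximum of a single-peaked profile
#'
#' Locates the global maximum, subtracts a baseline (by default the higher
#' of the two flanking local minima), and linearly interpolates the
#' half-maximum crossings on each side. Used as the apparent-diameter
#' estimator for blurred tubular structures.
#'
#' @param profile a `line_profile`.
#' @param baseline `"local_min"` (default) or `"raw"` (zero baseline).
#' @return FWHM in nm.
#' @export
fwhm <- function(profile, baseline = c("local_min", "raw")) {
  baseline <- match.arg(baseline)
  y <- profile$intensities
  x <- profile$positions
  i_max <- which.max(y)
  if (i_max == 1L || i_max == length(y)) {
    stop("peak at profile boundary: FWHM undefined")
  }
  base <- 0
  if (baseline == "local_min") {
    base <- max(min(y[seq_len(i_max)]), min(y[i_max:length(y)]))
  }
  half <- base + (y[i_max] - base) / 2
  left <- NA_real_
  for (i in seq(i_max, 2L)) {
    if (y[i - 1L] <= half && y[i] > half) {
      left <- x[i - 1L] + (half - y[i - 1L]) / (y[i] - y[i - 1L]) * (x[i] - x[i - 1L])
      break
    }
  }
  right <- NA_real_
  for (i in seq(i_max, length(y) - 1L)) {
    if (y[i + 1L] <= half && y[i] > half) {
      right <- x[i] + (y[i] - half) / (y[i] - y[i + 1L]) * (x[i + 1L] - x[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) {
    stop("half-maximum crossing missing on one side: FWHM undefined")
  }
  right - left
}

#' Find peaks in a 1D profile
#'
#' Local maxima filtered by prominence (relative to the profile's dynamic
#' range) and by a minimum mutual separation; surviving peak positions are
#' refined to sub-sample precision with a 3-point parabola.
#'
#' @param profile a `line_profile`.
#' @param min_prominence_frac minimum topographic prominence as a fraction
#'   of `max - min` intensity (default 0.1).
#' @param min_separation_nm minimum distance between reported peaks; the
#'   more prominent peak wins (default 0).
#' @return numeric vector of peak positions in nm (possibly empty), sorted
#'   ascending.
#' @export
find_peaks <- function(profile, min_prominence_frac = 0.1,
                       min_separation_nm = 0) {
  y <- profile$intensities
  x <- profile$positions
  n <- length(y)
  if (n < 3L) return(numeric(0))
  cand <- which(y[2:(n - 1L)] > y[1:(n - 2L)] &
                y[2:(n - 1L)] >= y[3:n]) + 1L
  if (length(cand) == 0L) return(numeric(0))

  rng <- max(y) - min(y)
  if (rng == 0) return(numeric(0))
  # topographic prominence: peak height minus the higher of the two valley
  # floors encountered before reaching a higher peak (or the profile edge)
  prom <- vapply(cand, function(i) {
    lv <- y[i]
    j <- i
    left_min <- y[i]
    while (j > 1L && y[j] <= lv) { j <- j - 1L; left_min <- min(left_min, y[j]) }
    if (y[j] <= lv) left_min <- min(y[seq_len(i)])
    j <- i
    right_min <- y[i]
    while (j < n && y[j] <= lv) { j <- j + 1L; right_min <- min(right_min, y[j]) }
    if (y[j] <= lv) right_min <- min(y[i:n])
    lv - max(left_min, right_min)
  }, numeric(1L))
  keep <- cand[prom >= min_prominence_frac * rng]
  prom <- prom[prom >= min_prominence_frac * rng]
  if (length(keep) == 0L) return(numeric(0))

  if (min_separation_nm > 0 && length(keep) > 1L) {
    ord <- order(prom, decreasing = TRUE)
    chosen <- integer(0)
    for (i in ord) {
      if (all(abs(x[keep[i]] - x[keep[chosen]]) >= min_separation_nm)) {
        chosen <- c(chosen, i)
      }
    }
    keep <- keep[sort(chosen)]
  }
  sort(vapply(keep, function(i) parabolic_refine(x, y, i), numeric(1L)))
}

#' Separation between exactly two peaks
#'
#' @param profile a `line_profile`.
#' @param min_prominence_frac,min_separation_nm passed to [find_peaks()].
#' @return distance in nm between the two refined peak positions; errors
#'   if the peak count differs from two.
#' @export
two_peak_separation <- function(profile, min_prominence_frac = 0.1,
                                min_separation_nm = 0) {
  pk <- find_peaks(profile, min_prominence_frac, min_separation_nm)
  if (length(pk) != 2L) {
    stop("expected exactly 2 peaks, found ", length(pk))
  }
  diff(pk)
}

#' Polar transform of an image about a centre
#'
#' Resamples the image onto an (angle, radius) grid by bilinear
#' interpolation and reduces it to an angular profile by averaging over a
#' radial band — the standard readout for angular symmetry and angular
#' offsets between channels of ring-shaped organelles. Angle 0 points
#' along +x and increases counterclockwise.
#'
#' @param image an `exm_image`.
#' @param center centre in nm `c(x, y)`.
#' @param n_angle_bins number of angular bins over `[0, 2*pi)` (default
#'   360).
#' @param radial_band `c(r_min, r_max)` in nm for the angular profile
#'   (default: 0 to the largest inscribed radius).
#' @param radial_step radial sampling step in nm (default one pixel).
#' @return object of class `polar_profile` with `angle_bins` (bin-centre
#'   angles), `radius_bins`, `intensity` (n_angle x n_radius matrix), and
#'   `angular_profile`.
#' @export
polar_transform <- function(image, center, n_angle_bins = 360L,
                            radial_band = NULL, radial_step = NULL) {
  ps <- pixel_size(image)
  if (is.null(radial_step)) radial_step <- ps
  max_r <- min(center[1L], center[2L],
               ncol(image) * ps - center[1L], nrow(image) * ps - center[2L])
  if (max_r <= 0) stop("center lies outside the image")
  if (is.null(radial_band)) radial_band <- c(0, max_r)
  if (radial_band[2L] > max_r + 1e-9) {
    stop("radial band exceeds image bounds (max usable radius ",
         signif(max_r, 6), " nm)")
  }
  radii <- seq(radial_band[1L], radial_band[2L], by = radial_step)
  if (length(radii) < 2L) radii <- radial_band
  angles <- (seq_len(n_angle_bins) - 0.5) * 2 * pi / n_angle_bins
  pol <- matrix(0, n_angle_bins, length(radii))
  for (ri in seq_along(radii)) {
    pol[, ri] <- bilinear_at(image,
                             center[1L] + radii[ri] * cos(angles),
                             center[2L] + radii[ri] * sin(angles))
  }
  structure(list(angle_bins = angles, radius_bins = radii,
                 intensity = pol, angular_profile = rowMeans(pol)),
            class = "polar_profile")
}

#' Angular offset between two angular profiles
#'
#' Circular cross-correlation of the two angular profiles; the argmax lag
#' (sub-bin refined by a 3-point parabola) is the rotation taking profile
#' A onto profile B. For an s-fold periodic signal the offset is only
#' defined modulo `2*pi/s`; callers comparing symmetric channels should
#' interpret it accordingly.
#'
#' @param profileA,profileB either `polar_profile` objects or plain
#'   numeric angular profiles with identical binning.
#' @return offset in radians in `(-pi, pi]`.
#' @export
angular_offset <- function(profileA, profileB) {
  a <- if (inherits(profileA, "polar_profile")) profileA$angular_profile else profileA
  b <- if (inherits(profileB, "polar_profile")) profileB$angular_profile else profileB
  if (length(a) != length(b)) stop("profiles have different binning")
  n <- length(a)
  a <- a - mean(a); b <- b - mean(b)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("flat angular profile: offset undefined")
  }
  # circular cross-correlation via FFT: c[k] = sum_j a[j] b[j + k]
  cc <- Re(stats::fft(Conj(stats::fft(a)) * stats::fft(b), inverse = TRUE)) / n
  k_best <- which.max(cc)
  lags <- seq_len(n) - 1L
  # parabolic refinement with circular neighbours
  ym <- cc[(k_best - 2L) %% n + 1L]
  y0 <- cc[k_best]
  yp <- cc[k_best %% n + 1L]
  denom <- ym - 2 * y0 + yp
  delta <- if (denom < 0) 0.5 * (ym - yp) / denom else 0
  lag <- (lags[k_best] + delta) * 2 * pi / n
  wrapped_angle_diff(lag, 0)
}

#' Mean signed radial offset between paired channel positions
#'
#' For paired per-structure positions of two channels along a radial (or
#' transverse) profile, reports mean(B - A), its SD and n. Negative values
#' point toward the lumen under the package-wide convention that profiles
#' run outward.
#'
#' @param positionsA,positionsB paired positions in nm (equal length).
#' @return list with `mean_nm`, `sd_nm`, `se_nm`, `n`.
#' @export
radial_offset <- function(positionsA, positionsB) {
  if (length(positionsA) != length(positionsB)) {
    stop("unpaired inputs: ", length(positionsA), " vs ", length(positionsB))
  }
  if (length(positionsA) == 0L) stop("no pairs")
  d <- positionsB - positionsA
  list(mean_nm = mean(d),
       sd_nm = if (length(d) > 1L) stats::sd(d) else 0,
       se_nm = if (length(d) > 1L) stats::sd(d) / sqrt(length(d)) else 0,
       n = length(d))
}

#' Angle of a fiber relative to a base axis
#'
#' Total-least-squares (first principal component) line fit through the
#' fiber points; returns the unsigned acute angle to `base_axis` in
#' degrees. Invariant under uniform scaling, hence independent of the
#' expansion factor.
#'
#' @param fiber_points two-column matrix or data.frame of (x, y) points,
#'   >= 2 distinct points.
#' @param base_axis reference direction `c(x, y)` (default the x-axis).
#' @return angle in degrees in `[0, 90]`.
#' @export
fiber_angle <- function(fiber_points, base_axis = c(1, 0)) {
  pts <- as.matrix(fiber_points)
  if (nrow(pts) < 2L) stop("need >= 2 points")
  centred <- sweep(pts, 2L, colMeans(pts))
  if (all(abs(centred) < 1e-12)) stop("collapsed points: direction undefined")
  v <- svd(centred, nu = 0, nv = 1)$v[, 1L]
  cosang <- abs(sum(v * base_axis)) / sqrt(sum(base_axis^2))
  acos(pmin(1, cosang)) * 180 / pi
}
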