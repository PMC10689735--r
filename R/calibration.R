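#' Molecular-ruler specification
#'
#' A molecular ruler is a structure with a trusted ground-truth dimension
#' against which the expansion factor is calibrated: the expanded, measured
#' dimension divided by the reference dimension gives the expansion
#' factor.
#'
#' @param name ruler name.
#' @param reference_dim ground-truth dimension in nm, > 0.
#' @param dimension_kind `"diameter"`, `"length"` or `"separation"`.
#' @param measurement_convention `"peak_to_peak"` or `"half_max"` (how the
#'   expanded dimension is read off an intensity profile).
#' @return object of class `ruler_spec`.
#' @export
ruler_spec <- function(name, reference_dim,
                       dimension_kind = c("diameter", "length", "separation"),
                       measurement_convention = c("peak_to_peak", "half_max")) {
  stopifnot(is.numeric(reference_dim), reference_dim > 0)
  structure(list(name = name, reference_dim = reference_dim,
                 dimension_kind = match.arg(dimension_kind),
                 measurement_convention = match.arg(measurement_convention)),
            class = "ruler_spec")
}

#' Built-in ruler registry
#'
#' Named presets for the four standard rulers: the NUP96 nucleoporin ring
#' (107 nm diameter), the Toxoplasma conoid apical diameter (380 nm), the
#' Chlamydomonas centriole proximal diameter (225 nm), and the mammalian
#' retina basal-body proximal diameter (230 nm, read at 50% of maximal
#' intensity).
#'
#' @param name one of `"nup96"`, `"conoid"`, `"cr-bb"`, `"retina-bb"`, or
#'   `"custom:<nm>"` for an ad-hoc diameter ruler.
#' @return a `ruler_spec`.
#' @export
get_ruler <- function(name) {
  registry <- list(
    "nup96"     = ruler_spec("nup96", 107, "diameter", "peak_to_peak"),
    "conoid"    = ruler_spec("conoid", 380, "diameter", "peak_to_peak"),
    "cr-bb"     = ruler_spec("cr-bb", 225, "diameter", "peak_to_peak"),
    "retina-bb" = ruler_spec("retina-bb", 230, "diameter", "half_max"))
  if (name %in% names(registry)) return(registry[[name]])
  if (startsWith(name, "custom:")) {
    d <- as.numeric(sub("^custom:", "", name))
    if (!is.finite(d) || d <= 0) stop("bad custom ruler: ", name)
    return(ruler_spec(name, d, "diameter", "peak_to_peak"))
  }
  stop("unknown ruler: ", name, " (known: nup96, conoid, cr-bb, retina-bb, custom:<nm>)")
}

# unit helper: value + unit -> nm
to_nm <- function(value, unit = c("nm", "um")) {
  unit <- match.arg(unit)
  if (unit == "um") value * 1000 else value
}

#' Expansion factor from an expanded measurement and a ruler
#'
#' @param expanded_dim measured expanded dimension; nm unless `unit` says
#'   otherwise.
#' @param ruler a `ruler_spec` (or a registry name accepted by
#'   [get_ruler()]).
#' @param unit `"nm"` (default) or `"um"` for `expanded_dim`.
#' @param n_measured number of measurements behind `expanded_dim`
#'   (metadata).
#' @return object of class `calibration_result` with `expansion_factor`,
#'   `ruler`, `expanded_measurement_nm`, `n_measured`.
#' @export
expansion_factor <- function(expanded_dim, ruler, unit = "nm", n_measured = 1L) {
  if (is.character(ruler)) ruler <- get_ruler(ruler)
  stopifnot(inherits(ruler, "ruler_spec"))
  expanded_nm <- to_nm(expanded_dim, unit)
  if (!is.numeric(expanded_nm) || expanded_nm <= 0) {
    stop("expanded_dim must be positive")
  }
  structure(list(expansion_factor = expanded_nm / ruler$reference_dim,
                 ruler = ruler, expanded_measurement_nm = expanded_nm,
                 n_measured = as.integer(n_measured)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration> %s ruler (%g nm): expanded %.4g nm -> expansion factor %.1f x\n",
              x$ruler$name, x$ruler$reference_dim,
              x$expanded_measurement_nm, x$expansion_factor))
  invisible(x)
}

#' Correct an expanded measurement back to true scale
#'
#' Exact inverse of the calibration: `corrected = expanded / EF`.
#'
#' @param expanded_value expanded measurement in nm (vectorized).
#' @param calibration a `calibration_result`, or a bare positive number
#'   used directly as the expansion factor.
#' @return corrected value(s) in nm.
#' @export
correct_measurement <- function(expanded_value, calibration) {
  ef <- if (inherits(calibration, "calibration_result")) {
    calibration$expansion_factor
  } else {
    calibration
  }
  if (!is.numeric(ef) || ef <= 0) stop("expansion factor must be > 0")
  expanded_value / ef
}

#' Nucleus cross-section statistic
#'
#' NCS = sqrt(segmented nucleus area) divided by the gel expansion factor;
#' because area scales with the square of the expansion, NCS is invariant
#' to it, making nucleus sizes comparable across gels.
#'
#' @param area nucleus area in square micrometres (expanded frame;
#'   vectorized).
#' @param gel_expansion dimensionless gel expansion factor, > 0.
#' @return NCS in micrometres.
#' @export
ncs <- function(area, gel_expansion) {
  if (any(area < 0)) stop("area must be >= 0")
  if (gel_expansion <= 0) stop("gel_expansion must be > 0")
  sqrt(area) / gel_expansion
}

#' Antibody linkage-error model for apparent tubule diameters
#'
#' An antibody stack displaces the fluorophore from the epitope by
#' `linkage` nm on each side. Labelled pre-expansion, the full linkage
#' expands with the specimen, so the corrected apparent diameter is
#' `d_true + 2 * linkage` independent of the expansion factor. Labelled
#' post-expansion, the linkage is added in the expanded frame and shrinks
#' by 1/E upon correction: `d_true + 2 * linkage / E`.
#'
#' @param d_true unlabelled structure diameter in nm (e.g. 25 for a
#'   microtubule).
#' @param linkage displacement per side in nm (~15 for primary +
#'   secondary antibodies).
#' @param expansion_factor dimensionless, >= 1 (ignored for
#'   pre-expansion labelling).
#' @param labeling_mode `"pre_expansion"` or `"post_expansion"`.
#' @return corrected apparent diameter in nm.
#' @export
linkage_apparent_diameter <- function(d_true, linkage, expansion_factor = 1,
                                      labeling_mode = c("pre_expansion",
                                                        "post_expansion")) {
  labeling_mode <- match.arg(labeling_mode)
  stopifnot(d_true > 0, linkage >= 0, expansion_factor >= 1)
  if (labeling_mode == "pre_expansion") {
    d_true + 2 * linkage
  } else {
    d_true + 2 * linkage / expansion_factor
  }
}

#' Ring diameter from an image or radial profile
#'
#' Computes the radial intensity profile about the ring centre and reads
#' the diameter under one of two conventions: `peak_to_peak` (twice the
#' radius of the radial-profile maximum, sub-bin refined) or `half_max`
#' (twice the outer radius at 50% of the radial maximum, by linear
#' interpolation — the convention used for basal-body rulers).
#'
#' @param image an `exm_image` of an approximately centred ring, or a
#'   `line_profile` taken as the radial profile directly.
#' @param convention `"peak_to_peak"` (default) or `"half_max"`.
#' @param center ring centre in nm; default = intensity centroid.
#' @param radial_step radial bin width in nm (default one pixel).
#' @return diameter in nm (expanded frame; pass through
#'   [correct_measurement()] for true scale).
#' @export
ring_diameter <- function(image, convention = c("peak_to_peak", "half_max"),
                          center = NULL, radial_step = NULL) {
  convention <- match.arg(convention)
  if (inherits(image, "line_profile")) {
    radii <- image$positions
    prof <- image$intensities
  } else {
    ps <- pixel_size(image)
    if (is.null(radial_step)) radial_step <- ps
    if (is.null(center)) {
      ctr <- pixel_centers(image)
      w <- unclass(image)
      w <- w - min(w)
      tot <- sum(w)
      center <- c(sum(colSums(w) * ctr$x_nm), sum(rowSums(w) * ctr$y_nm)) / tot
    }
    pol <- polar_transform(image, center, n_angle_bins = 360L,
                           radial_step = radial_step)
    radii <- pol$radius_bins
    prof <- colMeans(pol$intensity)
  }
  i_max <- which.max(prof)
  if (i_max == 1L || i_max == length(prof)) {
    stop("no discernible ring: radial profile is monotone")
  }
  if (convention == "peak_to_peak") {
    2 * parabolic_refine(radii, prof, i_max)
  } else {
    half <- prof[i_max] / 2
    outer_r <- NA_real_
    for (i in seq(i_max, length(prof) - 1L)) {
      if (prof[i + 1L] <= half && prof[i] > half) {
        outer_r <- radii[i] + (prof[i] - half) / (prof[i] - prof[i + 1L]) *
          (radii[i + 1L] - radii[i])
        break
      }
    }
    if (is.na(outer_r)) stop("radial profile never falls to half maximum")
    2 * outer_r
  }
}
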