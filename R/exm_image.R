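#' 2D image with a physical pixel size
#'
#' An `exm_image` is a numeric matrix of intensities together with the
#' physical pixel size in nanometres. All downstream measurements are
#' reported in nm, so the pixel size is mandatory: an image without one
#' cannot be measured.
#'
#' Coordinate convention (used everywhere in the package): the physical
#' x coordinate runs along matrix columns and y along rows, and the centre
#' of pixel `[i, j]` (1-based) sits at `((j - 0.5) * pixel_size_nm,
#' (i - 0.5) * pixel_size_nm)`. Equivalently, with 0-based indices the
#' centre of pixel i is at `(i + 0.5) * pixel_size_nm`.
#'
#' @param data numeric matrix (rows = y, columns = x).
#' @param pixel_size_nm physical size of one pixel in nm; must be > 0.
#' @return an object of class `exm_image`.
#' @export
exm_image <- function(data, pixel_size_nm) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric matrix")
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0) {
    stop("`pixel_size_nm` must be a single positive number (nm units are load-bearing)")
  }
  structure(data, pixel_size_nm = as.numeric(pixel_size_nm), class = "exm_image")
}

#' @export
print.exm_image <- function(x, ...) {
  cat(sprintf("<exm_image> %d x %d pixels, pixel size %.4g nm (%.3g x %.3g nm field)\n",
              nrow(x), ncol(x), pixel_size(x),
              ncol(x) * pixel_size(x), nrow(x) * pixel_size(x)))
  invisible(x)
}

#' Pixel size of an image in nm
#' @param image an `exm_image`.
#' @return pixel size in nm.
#' @export
pixel_size <- function(image) {
  ps <- attr(image, "pixel_size_nm")
  if (is.null(ps)) stop("image carries no pixel size; use exm_image()")
  ps
}

#' Physical coordinates of all pixel centres
#'
#' @param image an `exm_image`.
#' @return list with vectors `x_nm` (length ncol) and `y_nm` (length nrow).
#' @export
pixel_centers <- function(image) {
  ps <- pixel_size(image)
  list(x_nm = (seq_len(ncol(image)) - 0.5) * ps,
       y_nm = (seq_len(nrow(image)) - 0.5) * ps)
}

#' Maximum-intensity projection of an image stack
#'
#' Collapses a list of equally sized single-plane images (a z-stack) into
#' one plane by taking the per-pixel maximum, the standard projection
#' applied to confocal stacks before 2D particle analysis.
#'
#' @param stack list of `exm_image` objects (or plain matrices) with equal
#'   dimensions and pixel size.
#' @return an `exm_image`.
#' @export
max_z_project <- function(stack) {
  if (!is.list(stack) || length(stack) == 0L) stop("`stack` must be a nonempty list")
  ps <- pixel_size(stack[[1L]])
  dims <- dim(stack[[1L]])
  out <- matrix(-Inf, dims[1L], dims[2L])
  for (plane in stack) {
    if (!identical(dim(plane), dims)) stop("stack planes differ in size")
    out <- pmax(out, unclass(plane))
  }
  exm_image(out, ps)
}

#' Otsu's threshold for a grey-level image
#'
#' Histogram-based between-class variance maximization, used as the
#' default binarization for particle and nucleus segmentation.
#'
#' @param image numeric matrix or `exm_image`.
#' @param n_bins number of histogram bins (default 256).
#' @return threshold on the intensity scale of `image`; pixels strictly
#'   above it are foreground.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  v <- as.numeric(image)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("image has no finite pixels")
  rng <- range(v)
  if (rng[1L] == rng[2L]) return(rng[1L])
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), nbins = n_bins)
  mids <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  w <- cumsum(h)
  m <- cumsum(h * mids)
  total_w <- w[n_bins]
  total_m <- m[n_bins]
  # between-class variance for every cut point
  w0 <- w[-n_bins]
  w1 <- total_w - w0
  mu0 <- m[-n_bins] / w0
  mu1 <- (total_m - m[-n_bins]) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  breaks[which.max(bcv) + 1L]
}

#' Resolve a threshold specification against an image
#'
#' Accepted forms: `"otsu"`, `list(frac = x)` or `"frac:x"` (fraction of
#' the maximum intensity), `list(abs = v)` or `"abs:v"` (absolute value),
#' or a bare number (absolute).
#'
#' @param image numeric matrix or `exm_image`.
#' @param threshold_spec see description.
#' @return a single numeric threshold; pixels strictly above it are kept.
#' @export
resolve_threshold <- function(image, threshold_spec = "otsu") {
  if (is.numeric(threshold_spec) && length(threshold_spec) == 1L) {
    return(as.numeric(threshold_spec))
  }
  if (is.list(threshold_spec)) {
    if (!is.null(threshold_spec$frac)) {
      return(threshold_spec$frac * max(image))
    }
    if (!is.null(threshold_spec$abs)) return(as.numeric(threshold_spec$abs))
    stop("threshold list must carry $frac or $abs")
  }
  if (is.character(threshold_spec) && length(threshold_spec) == 1L) {
    if (threshold_spec == "otsu") return(otsu_threshold(image))
    if (startsWith(threshold_spec, "frac:")) {
      return(as.numeric(sub("^frac:", "", threshold_spec)) * max(image))
    }
    if (startsWith(threshold_spec, "abs:")) {
      return(as.numeric(sub("^abs:", "", threshold_spec)))
    }
  }
  stop("unrecognized threshold_spec: ", deparse(threshold_spec))
}
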