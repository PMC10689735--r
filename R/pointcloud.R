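#' Planar point cloud with a defined centre
#'
#' Container for the thresholded-pixel (or simulated) point set analysed by
#' the corner-counting algorithm. Coordinates are physical, in nm. The
#' centre is fixed at construction — by default the (optionally
#' intensity-weighted) centroid of the points — and is deliberately NOT
#' recomputed by later trimming, so that outlier removal cannot feed back
#' into the definition of "far from the centre". `R` is the distance from
#' the centre to the furthest retained point.
#'
#' @param x,y numeric vectors of coordinates in nm.
#' @param center optional `c(x, y)` in nm; default: centroid weighted by
#'   `weights`.
#' @param weights optional nonnegative weights (e.g. pixel intensities)
#'   used only for the default centroid.
#' @return object of class `exm_pointcloud` with elements `x`, `y`,
#'   `center`, `R`, `n`.
#' @export
pointcloud <- function(x, y, center = NULL, weights = NULL) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) == 0L) stop("empty point cloud")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite coordinates")
  if (is.null(center)) {
    if (is.null(weights)) weights <- rep(1, length(x))
    if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
    center <- c(sum(x * weights), sum(y * weights)) / sum(weights)
  }
  if (length(center) != 2L || !all(is.finite(center))) stop("center must be (x, y)")
  cl <- structure(list(x = as.numeric(x), y = as.numeric(y),
                       center = as.numeric(center), n = length(x)),
                  class = "exm_pointcloud")
  cl$R <- max(point_radii(cl))
  cl
}

#' @export
print.exm_pointcloud <- function(x, ...) {
  cat(sprintf("<exm_pointcloud> %d points, center (%.2f, %.2f) nm, R = %.2f nm\n",
              x$n, x$center[1L], x$center[2L], x$R))
  invisible(x)
}

#' Distances of each point from the cloud centre
#' @param cloud an `exm_pointcloud`.
#' @return numeric vector of radii in nm.
#' @export
point_radii <- function(cloud) {
  sqrt((cloud$x - cloud$center[1L])^2 + (cloud$y - cloud$center[2L])^2)
}

#' Polar angles of each point about the cloud centre
#' @param cloud an `exm_pointcloud`.
#' @return angles in radians in (-pi, pi], measured from +x counterclockwise.
#' @export
point_angles <- function(cloud) {
  atan2(cloud$y - cloud$center[2L], cloud$x - cloud$center[1L])
}

#' Rigidly transform a point cloud
#'
#' Rotation by `theta` about the centre followed by translation; the
#' centre moves with the cloud. Used mainly by invariance tests.
#'
#' @param cloud an `exm_pointcloud`.
#' @param dx,dy translation in nm.
#' @param theta rotation in radians about the cloud centre.
#' @return transformed `exm_pointcloud`.
#' @export
transform_cloud <- function(cloud, dx = 0, dy = 0, theta = 0) {
  xr <- cloud$x - cloud$center[1L]
  yr <- cloud$y - cloud$center[2L]
  ct <- cos(theta); st <- sin(theta)
  pointcloud(cloud$center[1L] + ct * xr - st * yr + dx,
             cloud$center[2L] + st * xr + ct * yr + dy,
             center = cloud$center + c(dx, dy))
}
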