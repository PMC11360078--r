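#' Ray from the camera through the grape
#'
#' The distorted peak a translucent berry forms in a ToF/LiDAR scan is
#' symmetric about the line from the camera through the berry's location,
#' not about the global Z axis.  This constructs that line as an
#' origin + unit-direction ray.
#'
#' @param grape_center (x, y, z) mm, the berry's location.
#' @param camera_origin (x, y, z) mm; the camera centre, normally the
#'   origin.
#' @return A \code{ray} object: list with \code{origin} and unit
#'   \code{direction} (positive z component).
#' @examples
#' central_ray(c(-85, 0, 255))   # off-axis berry, left of centre
#' @export
central_ray <- function(grape_center, camera_origin = c(0, 0, 0)) {
  stopifnot(length(grape_center) == 3L, length(camera_origin) == 3L)
  d <- as.numeric(grape_center) - as.numeric(camera_origin)
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) stop("grape_center coincides with camera_origin")
  if (d[3L] <= 0)
    stop("grape must lie in front of the camera (z beyond camera origin)")
  structure(list(origin = as.numeric(camera_origin), direction = d / nrm),
            class = "ray")
}

#' @export
print.ray <- function(x, ...) {
  cat(sprintf("<ray: origin (%.2f, %.2f, %.2f) mm, direction (%.4f, %.4f, %.4f)>\n",
              x$origin[1L], x$origin[2L], x$origin[3L],
              x$direction[1L], x$direction[2L], x$direction[3L]))
  invisible(x)
}

# per-point distance s along the ray and angle theta off the ray
.ray_coords <- function(pc, ray) {
  p <- sweep(pc$points, 2L, ray$origin)
  s <- as.vector(p %*% ray$direction)
  r <- sqrt(pmax(rowSums(p * p) - s^2, 0))
  theta <- atan2(r, s)
  list(s = s, theta = theta, radial = r)
}

#' Locate the apex (tip) of a scan peak
#'
#' The uncoated berry appears as a peak whose tip points toward the
#' camera; the coated reference shows the true front surface.  In both
#' cases the apex is the closest approach of the cloud along the ray:
#' points within an angular window around the ray are projected onto it
#' and the apex distance is the mean of the lowest-q quantile of those
#' projections (at least \code{min_support} points).  A low-quantile mean
#' rather than the single minimum keeps the estimate robust to residual
#' noise.
#'
#' @param pc a \code{\link{point_cloud}}.
#' @param ray a \code{\link{central_ray}} (projection and window axis).
#' @param q quantile in (0, 1] of the windowed points used for the tip
#'   mean; default 0.01.
#' @param angular_window half-angle in radians of the cone around the ray
#'   within which points are considered; default \code{Inf} (all points).
#' @param min_support minimum number of points averaged (capped at the
#'   window population); default 5.
#' @return An \code{apex_estimate}: list with \code{s} (distance along
#'   the ray, mm), \code{position} (centroid of the used points, mm),
#'   \code{support} (points averaged) and \code{method}.
#' @export
detect_apex <- function(pc, ray, q = 0.01, angular_window = Inf,
                        min_support = 5L) {
  stopifnot(inherits(pc, "point_cloud"), inherits(ray, "ray"))
  if (!(q > 0 && q <= 1)) stop("q must be in (0, 1]")
  rc <- .ray_coords(pc, ray)
  inw <- which(rc$theta <= angular_window)
  m <- length(inw)
  if (m == 0L)
    stop(sprintf("no points within the %.4f rad angular window", angular_window))
  n_use <- min(m, max(ceiling(q * m), min_support))
  # ties in s broken by original index: order() is stable on the index tiebreak
  o <- inw[order(rc$s[inw], inw)[seq_len(n_use)]]
  structure(list(s = mean(rc$s[o]),
                 position = colMeans(pc$points[o, , drop = FALSE]),
                 support = n_use,
                 method = "min_projection_quantile"),
            class = "apex_estimate")
}

#' @export
print.apex_estimate <- function(x, ...) {
  cat(sprintf("<apex: s = %.3f mm at (%.2f, %.2f, %.2f), support %d, %s>\n",
              x$s, x$position[1L], x$position[2L], x$position[3L],
              x$support, x$method))
  invisible(x)
}

#' Distance bias between coated and uncoated scans
#'
#' The core maturity measurement: how much farther the uncoated berry's
#' peak tip appears than the coated (opaque-reference) surface.  The bias
#' is \eqn{y = s_{coated} - s_{uncoated}}, so \eqn{y < 0} when the
#' uncoated tip appears farther from the camera — the usual case for a
#' translucent berry, and the sign convention of the fitted maturity
#' lines.
#'
#' Two projection conventions are supported:
#' \describe{
#'   \item{\code{along_ray}}{apex distances are measured along the
#'     camera-to-grape line (the peak's symmetry axis); recommended,
#'     especially for berries off the optical axis.}
#'   \item{\code{z_axis}}{apex distances are measured along global +Z;
#'     matches a plain depth-map reading but foreshortens off-axis.}
#' }
#' In both conventions candidate points are windowed in a cone around the
#' central ray before the apex is extracted.
#'
#' @param coated reference \code{\link{point_cloud}} (opaque coating).
#' @param uncoated same-berry \code{\link{point_cloud}} without coating.
#' @param ray optional \code{\link{central_ray}}; defaults to the ray
#'   through the coated scan's centroid (the coated scan carries the
#'   undistorted geometry).
#' @param method \code{"along_ray"} (default) or \code{"z_axis"}.
#' @param t day index attached to the measurement (integer >= 1, or NA).
#' @param q,min_support apex estimator settings, see
#'   \code{\link{detect_apex}}.
#' @param angular_window cone half-angle in radians; default 1.2 times
#'   the coated scan's angular radius about the ray.
#' @return A \code{bias_measurement}: list with \code{t}, \code{y} (mm),
#'   \code{method}, \code{apex_coated}, \code{apex_uncoated}.
#' @export
distance_bias <- function(coated, uncoated, ray = NULL,
                          method = c("along_ray", "z_axis"),
                          t = NA_integer_, q = 0.01,
                          angular_window = NULL, min_support = 5L) {
  method <- match.arg(method)
  stopifnot(inherits(coated, "point_cloud"), inherits(uncoated, "point_cloud"))
  if (npoints(coated) == 0L || npoints(uncoated) == 0L)
    stop("both clouds must be non-empty")
  if (is.null(ray)) ray <- central_ray(colMeans(coated$points))
  if (is.null(angular_window)) {
    rc <- .ray_coords(coated, ray)
    angular_window <- 1.2 * max(rc$theta)
  }
  window_cloud <- function(pc) {
    inw <- .ray_coords(pc, ray)$theta <= angular_window
    if (!any(inw))
      stop("no points within the angular window around the central ray")
    point_cloud(pc$points[inw, , drop = FALSE], meta = pc$meta)
  }
  wc <- window_cloud(coated)
  wu <- window_cloud(uncoated)
  proj <- if (method == "z_axis")
    structure(list(origin = ray$origin, direction = c(0, 0, 1)),
              class = "ray") else ray
  ac <- detect_apex(wc, proj, q = q, min_support = min_support)
  au <- detect_apex(wu, proj, q = q, min_support = min_support)
  structure(list(t = t, y = ac$s - au$s, method = method,
                 apex_coated = ac, apex_uncoated = au),
            class = "bias_measurement")
}

#' @export
print.bias_measurement <- function(x, ...) {
  cat(sprintf(
    "<bias_measurement: day %s, y = %.3f mm (magnitude %.3f), method %s>\n",
    format(x$t), x$y, abs(x$y), x$method))
  invisible(x)
}

#' Cross-section through a scan
#'
#' A thin slab slice through the cloud in the X or Y direction, as used
#' to visualize the peak profile.  For \code{axis = "X"} the slice runs
#' along X (points with y within \code{tolerance} of \code{center});
#' for \code{axis = "Y"} it runs along Y.
#'
#' @param pc a \code{\link{point_cloud}}.
#' @param axis \code{"X"} or \code{"Y"}: the direction the section runs.
#' @param center slab centre on the off-axis coordinate, mm.
#' @param tolerance slab half-width, mm (> 0).
#' @return A \code{cross_section}: list with \code{axis},
#'   \code{tolerance}, and \code{samples}, a 2-column matrix of
#'   (coordinate, z) pairs sorted by coordinate.
#' @export
cross_section <- function(pc, axis = c("X", "Y"), center = 0, tolerance) {
  axis <- match.arg(axis)
  stopifnot(inherits(pc, "point_cloud"))
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be positive")
  p <- pc$points
  along <- if (axis == "X") 1L else 2L
  off <- if (axis == "X") 2L else 1L
  keep <- abs(p[, off] - center) <= tolerance
  sub <- p[keep, , drop = FALSE]
  sub <- sub[order(sub[, along]), , drop = FALSE]
  samples <- cbind(coordinate = sub[, along], z = sub[, 3L])
  structure(list(axis = axis, center = center, tolerance = tolerance,
                 samples = samples),
            class = "cross_section")
}

#' @export
plot.cross_section <- function(x, ...) {
  plot(x$samples[, 1L], x$samples[, 2L],
       xlab = sprintf("%s (mm)", tolower(x$axis)), ylab = "z (mm)",
       main = sprintf("%s-axis cross-section", x$axis), ...)
  invisible(x)
}

#' Shape of the scan peak
#'
#' Summarizes the distorted peak: tip distance (closest approach along
#' the ray), base distance (a high quantile of the point ranges from the
#' camera — the base is what stays at a roughly constant distance from
#' the camera as the berry ages), the peak height (base - tip; what
#' flattens with age), and the full width of the peak at half its
#' height, read off the radial profile about the ray.  Tip and base are
#' directly comparable: at the tip the ray projection and the camera
#' range coincide.
#'
#' @param pc a \code{\link{point_cloud}} with at least 10 points in the
#'   window.
#' @param ray a \code{\link{central_ray}}.
#' @param q apex quantile (see \code{\link{detect_apex}}).
#' @param base_quantile quantile of camera range taken as the base;
#'   default 0.95 (robust far distance of the peak region).
#' @param angular_window cone half-angle, radians; default \code{Inf}.
#' @param nbins radial bins for the width profile.
#' @return A \code{peak_shape}: list with \code{tip_s}, \code{base_s},
#'   \code{height}, \code{width_at_half_height} (all mm;
#'   width is \code{NA} for an essentially flat cloud).
#' @export
peak_shape <- function(pc, ray, q = 0.01, base_quantile = 0.95,
                       angular_window = Inf, nbins = 24L) {
  stopifnot(inherits(pc, "point_cloud"), inherits(ray, "ray"))
  rc <- .ray_coords(pc, ray)
  inw <- rc$theta <= angular_window
  if (sum(inw) < 10L)
    stop(sprintf("peak_shape needs >= 10 points in the window, got %d",
                 sum(inw)))
  sub <- point_cloud(pc$points[inw, , drop = FALSE], meta = pc$meta)
  s <- rc$s[inw]
  radial <- rc$radial[inw]
  range_s <- sqrt(s^2 + radial^2)   # distance from the camera
  tip <- detect_apex(sub, ray, q = q)
  base_s <- as.numeric(quantile(range_s, base_quantile, names = FALSE))
  height <- max(base_s - tip$s, 0)
  width <- NA_real_
  if (height > 1e-6) {
    half <- tip$s + height / 2
    brk <- seq(0, max(radial) * (1 + 1e-9), length.out = nbins + 1L)
    bin <- cut(radial, brk, include.lowest = TRUE, labels = FALSE)
    prof_s <- tapply(s, bin, mean)
    prof_r <- tapply(radial, bin, mean)
    keep <- !is.na(prof_s)
    prof_s <- as.numeric(prof_s[keep]); prof_r <- as.numeric(prof_r[keep])
    above <- which(prof_s >= half)
    if (length(above)) {
      i <- above[1L]
      if (i == 1L) width <- 2 * prof_r[1L]
      else {
        # linear interpolation between the straddling bins
        f <- (half - prof_s[i - 1L]) / (prof_s[i] - prof_s[i - 1L])
        width <- 2 * (prof_r[i - 1L] + f * (prof_r[i] - prof_r[i - 1L]))
      }
    }
  }
  structure(list(tip_s = tip$s, base_s = base_s, height = height,
                 width_at_half_height = width, apex = tip),
            class = "peak_shape")
}

#' @export
print.peak_shape <- function(x, ...) {
  cat(sprintf(
    "<peak_shape: tip %.3f mm, base %.3f mm, height %.3f mm, FWHM %s mm>\n",
    x$tip_s, x$base_s, x$height,
    if (is.na(x$width_at_half_height)) "NA"
    else sprintf("%.2f", x$width_at_half_height)))
  invisible(x)
}
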