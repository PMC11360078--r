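#' Point cloud in the camera frame
#'
#' A point cloud is an ordered set of 3D points in millimetres, expressed
#' in the camera frame: camera at the origin, +Z along the optical axis
#' (away from the camera), X to the camera's right, Y up.  Order is
#' significant and preserved by every operation and I/O round trip.
#'
#' @param points numeric matrix or data frame with 3 columns (x, y, z in
#'   mm).  All coordinates must be finite and every z strictly positive
#'   (in front of the camera).
#' @param meta named list of free-form metadata strings (day, coated flag,
#'   source file, ...).
#' @return An object of class \code{point_cloud}: a list with elements
#'   \code{points} (n x 3 numeric matrix, columns x/y/z) and \code{meta}.
#' @examples
#' pc <- point_cloud(cbind(x = 0, y = 0, z = 360))
#' npoints(pc)
#' @export
point_cloud <- function(points, meta = list()) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (is.null(points) || length(points) == 0L)
    points <- matrix(numeric(0), ncol = 3L)
  if (!is.matrix(points) || ncol(points) != 3L)
    stop("'points' must be an n x 3 matrix of (x, y, z) in mm")
  storage.mode(points) <- "double"
  if (nrow(points) > 0L) {
    if (!all(is.finite(points)))
      stop("point cloud contains non-finite coordinates")
    if (any(points[, 3L] <= 0))
      stop("all points must lie in front of the camera (z > 0)")
  }
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points, meta = meta), class = "point_cloud")
}

#' Number of points in a cloud
#' @param pc a \code{point_cloud}.
#' @return integer point count.
#' @export
npoints <- function(pc) {
  stopifnot(inherits(pc, "point_cloud"))
  nrow(pc$points)
}

#' @export
print.point_cloud <- function(x, ...) {
  n <- nrow(x$points)
  cat(sprintf("<point_cloud: %d points>\n", n))
  if (n > 0L) {
    rng <- apply(x$points, 2L, range)
    cat(sprintf("  x: [%.2f, %.2f] mm  y: [%.2f, %.2f] mm  z: [%.2f, %.2f] mm\n",
                rng[1L, 1L], rng[2L, 1L], rng[1L, 2L], rng[2L, 2L],
                rng[1L, 3L], rng[2L, 3L]))
  }
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, as.character)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.point_cloud <- function(x, ...) x$points

#' Axis-aligned crop bounds
#'
#' @param xmin,xmax,ymin,ymax,zmin,zmax bounds in mm; min must be strictly
#'   below max on every axis.
#' @return A \code{crop_bounds} object.
#' @export
crop_bounds <- function(xmin, xmax, ymin, ymax, zmin, zmax) {
  b <- c(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
         zmin = zmin, zmax = zmax)
  if (!all(is.finite(b))) stop("crop bounds must be finite")
  if (xmin >= xmax || ymin >= ymax || zmin >= zmax)
    stop("crop bounds require min < max on every axis")
  structure(as.list(b), class = "crop_bounds")
}

#' Crop a point cloud to an axis-aligned box
#'
#' Keeps exactly the points inside the closed box (boundary points are
#' kept), preserving input order.  Used to isolate the berry's surface
#' from the holder and background.
#'
#' @param pc a \code{point_cloud}.
#' @param bounds a \code{\link{crop_bounds}} object.
#' @return The cropped \code{point_cloud} (possibly empty).
#' @export
crop_box <- function(pc, bounds) {
  stopifnot(inherits(pc, "point_cloud"), inherits(bounds, "crop_bounds"))
  p <- pc$points
  keep <- p[, 1L] >= bounds$xmin & p[, 1L] <= bounds$xmax &
          p[, 2L] >= bounds$ymin & p[, 2L] <= bounds$ymax &
          p[, 3L] >= bounds$zmin & p[, 3L] <= bounds$zmax
  point_cloud(p[keep, , drop = FALSE], meta = pc$meta)
}
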