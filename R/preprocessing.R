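#' Mean distance to the K nearest neighbours
#'
#' For every point, the exact mean Euclidean distance to its \code{k}
#' nearest other points (the point itself is excluded).  Computed by
#' chunked brute force, so results are exact, deterministic and
#' independent of point order.
#'
#' @param pc a \code{\link{point_cloud}} with more than \code{k} points.
#' @param k number of neighbours (>= 1).
#' @param chunk rows per block of the pairwise-distance computation
#'   (memory/speed trade-off; does not affect the result).
#' @return Numeric vector of per-point mean neighbour distances (mm),
#'   aligned with the input order.
#' @export
knn_mean_distance <- function(pc, k, chunk = 512L) {
  stopifnot(inherits(pc, "point_cloud"))
  X <- pc$points
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (n <= k)
    stop(sprintf("need more points than neighbours: k = %d, points = %d",
                 k, n))
  sq <- rowSums(X * X)
  out <- numeric(n)
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    idx <- lo:hi
    # squared cross distances, clipped at zero for fp safety
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(X[idx, , drop = FALSE], X)
    d2[d2 < 0] <- 0
    d2[cbind(seq_along(idx), idx)] <- Inf   # exclude self
    out[idx] <- apply(d2, 1L, function(r)
      mean(sqrt(sort(r, partial = k)[seq_len(k)])))
  }
  out
}

#' K-nearest-neighbour outlier filter
#'
#' Removes isolated speckle by the average-neighbour-distance rule: a
#' point is kept iff its mean distance to its \code{k} nearest neighbours
#' does not exceed a threshold.  Two threshold conventions are provided:
#' \describe{
#'   \item{\code{absolute}}{\code{threshold} is a distance in mm.}
#'   \item{\code{statistical}}{\code{threshold} is a multiplier m; the
#'     cut-off is mean + m * sd of the per-point mean neighbour distances
#'     over the whole cloud (the usual statistical-outlier-removal rule
#'     for depth-sensor clouds).}
#' }
#' Point order is preserved; the returned mask is aligned with the input.
#'
#' @param pc a \code{\link{point_cloud}} with more than \code{k} points.
#' @param k number of neighbours; default 20.
#' @param mode \code{"statistical"} (default) or \code{"absolute"}.
#' @param threshold multiplier m (statistical mode, default 2.0) or
#'   absolute distance in mm; must be positive.
#' @return A list with \code{cloud} (the filtered \code{point_cloud}),
#'   \code{kept} (logical mask over the input points), and
#'   \code{mean_knn_dist} (the per-point statistic, mm).
#' @examples
#' pts <- rbind(expand.grid(x = 0:2, y = 0:2, z = 100), c(50, 50, 200))
#' f <- knn_outlier_filter(point_cloud(pts), k = 3, mode = "absolute",
#'                         threshold = 5)
#' which(!f$kept)  # the lone far point
#' @export
knn_outlier_filter <- function(pc, k = 20L,
                               mode = c("statistical", "absolute"),
                               threshold = 2.0) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number")
  d <- knn_mean_distance(pc, k)
  cut <- if (mode == "absolute") threshold
         else mean(d) + threshold * sd(d)
  kept <- d <= cut
  list(cloud = point_cloud(pc$points[kept, , drop = FALSE], meta = pc$meta),
       kept = kept,
       mean_knn_dist = d)
}
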