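#' Configuration of a synthetic scan scene
#'
#' Parameterizes a coated/uncoated synthetic scan series for one berry
#' (or control sphere).  The defaults mirror the measurement conditions
#' the analysis is designed for: a 9.525 mm-radius target with its front
#' surface 360 mm directly in front of the camera, a linear bias schedule
#' \eqn{y(t) = slope \cdot t + intercept} with slope -0.62 mm/day and
#' intercept -8.9 mm (bias magnitude growing from ~9.5 mm to ~16.3 mm
#' over 12 days), a peak base fixed 20 mm behind the true surface,
#' 0.5 mm Gaussian depth noise and 2\% speckle outliers.  Off-axis
#' berries are configured by moving \code{grape_center} (e.g.
#' \code{c(-85, 0, 255)}).
#'
#' The uncoated peak model is phenomenological: a rotationally symmetric
#' Gaussian radial profile about the camera-to-grape ray whose base stays
#' fixed while the tip retreats with age.  \code{peak_width} sets the
#' Gaussian angular width as a fraction of the target's angular radius;
#' the default 1.5 gives the broad, flattened peak (wider than the berry
#' itself) that ToF/LiDAR scans of translucent fruit show.
#'
#' @param sphere_radius target radius, mm (> 0).
#' @param grape_center (x, y, z) mm; centre of the target sphere.
#' @param bias_slope,bias_intercept bias schedule, mm/day and mm
#'   (typically negative: the berry appears ever farther).
#' @param base_offset fixed distance of the peak base behind the true
#'   front surface, mm; must exceed the largest |y(t)| simulated.
#' @param peak_width Gaussian angular width of the peak, as a fraction of
#'   the target's angular radius.
#' @param angular_samples grid rays per axis (>= 8); the scan grid spans
#'   1.3 angular radii around the central ray.
#' @param noise_sigma Gaussian depth-noise SD along each ray, mm (>= 0).
#' @param outlier_fraction fraction of returns replaced by speckle, in
#'   [0, 1).
#' @param outlier_range speckle half-range around the target centre, mm.
#' @param outlier_clearance minimum distance of a speckle point from the
#'   noiseless surface, mm; speckle is rejection-sampled to keep this
#'   clearance so that injected outliers are genuinely isolated points,
#'   not surface points in disguise.
#' @param seed integer; every generated scan is a pure function of the
#'   config (including the seed) and the day.
#' @return A \code{scene_config} object (validated list).
#' @export
scene_config <- function(sphere_radius = 9.525,
                         grape_center = c(0, 0, 369.525),
                         bias_slope = -0.62,
                         bias_intercept = -8.9,
                         base_offset = 20,
                         peak_width = 1.5,
                         angular_samples = 48L,
                         noise_sigma = 0.5,
                         outlier_fraction = 0.02,
                         outlier_range = 30,
                         outlier_clearance = 10,
                         seed = 1L) {
  if (sphere_radius <= 0) stop("sphere_radius must be positive")
  if (length(grape_center) != 3L || !all(is.finite(grape_center)))
    stop("grape_center must be a finite (x, y, z)")
  if (grape_center[3L] <= sphere_radius)
    stop("grape_center.z must exceed sphere_radius (target in front of camera)")
  if (angular_samples < 8L) stop("angular_samples must be >= 8")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    stop("outlier_fraction must be in [0, 1)")
  if (base_offset <= 0) stop("base_offset must be positive")
  if (peak_width <= 0) stop("peak_width must be positive")
  if (outlier_clearance < 0) stop("outlier_clearance must be >= 0")
  if (outlier_fraction > 0 && outlier_clearance >= outlier_range)
    stop("outlier_clearance must be smaller than outlier_range")
  structure(list(sphere_radius = sphere_radius,
                 grape_center = as.numeric(grape_center),
                 bias_slope = bias_slope,
                 bias_intercept = bias_intercept,
                 base_offset = base_offset,
                 peak_width = peak_width,
                 angular_samples = as.integer(angular_samples),
                 noise_sigma = noise_sigma,
                 outlier_fraction = outlier_fraction,
                 outlier_range = outlier_range,
                 outlier_clearance = outlier_clearance,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  d <- sqrt(sum(x$grape_center^2))
  cat(sprintf("<scene_config: r = %.3f mm at (%.1f, %.1f, %.1f), front %.1f mm>\n",
              x$sphere_radius, x$grape_center[1L], x$grape_center[2L],
              x$grape_center[3L], d - x$sphere_radius))
  cat(sprintf("  bias y(t) = %.3g*t + %.3g mm; base offset %.1f mm; peak width %.2f\n",
              x$bias_slope, x$bias_intercept, x$base_offset, x$peak_width))
  cat(sprintf("  grid %d^2, noise %.2f mm, outliers %.1f%% within %.0f mm, seed %d\n",
              x$angular_samples, x$noise_sigma, 100 * x$outlier_fraction,
              x$outlier_range, x$seed))
  invisible(x)
}

#' Programmed bias schedule of a scene
#' @param cfg a \code{\link{scene_config}}.
#' @param t day(s).
#' @return Programmed bias y(t) in mm.
#' @export
bias_schedule <- function(cfg, t) {
  stopifnot(inherits(cfg, "scene_config"))
  cfg$bias_slope * t + cfg$bias_intercept
}

# deterministic per-day seed derived from the config seed (kept < 2^31)
per_day_seed <- function(seed, t) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(t)) %% 2147483647)
}

# orthonormal basis (e1, e2) perpendicular to unit vector u
.ray_basis <- function(u) {
  ref <- if (abs(u[3L]) < 0.999) c(0, 0, 1) else c(1, 0, 0)
  e1 <- c(u[2L] * ref[3L] - u[3L] * ref[2L],
          u[3L] * ref[1L] - u[1L] * ref[3L],
          u[1L] * ref[2L] - u[2L] * ref[1L])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2L] * e1[3L] - u[3L] * e1[2L],
          u[3L] * e1[1L] - u[1L] * e1[3L],
          u[1L] * e1[2L] - u[2L] * e1[1L])
  list(e1 = e1, e2 = e2)
}

# regular angular grid of unit ray directions around the central ray,
# spanning 1.3 x the target's angular radius; returns directions and the
# angle of each ray from the central ray
.ray_grid <- function(cfg) {
  c0 <- cfg$grape_center
  d <- sqrt(sum(c0^2))
  u <- c0 / d
  theta_g <- asin(cfg$sphere_radius / d)
  b <- .ray_basis(u)
  a <- seq(-1.3 * theta_g, 1.3 * theta_g, length.out = cfg$angular_samples)
  g <- expand.grid(alpha = a, beta = a)
  dirs <- outer(rep(1, nrow(g)), u) +
    outer(tan(g$alpha), b$e1) + outer(tan(g$beta), b$e2)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  theta <- acos(pmin(1, as.vector(dirs %*% u)))
  list(dirs = dirs, theta = theta, u = u, d = d, theta_g = theta_g)
}

# add along-ray Gaussian noise and speckle outliers; seeded, order-stable.
# speckle is rejection-sampled to keep cfg$outlier_clearance mm away from
# the noiseless surface so injected outliers are genuinely isolated.
.apply_noise <- function(s, dirs, cfg, seed) {
  n <- length(s)
  surface <- dirs * s
  with_seed(seed, {
    s_noisy <- if (cfg$noise_sigma > 0) s + rnorm(n, 0, cfg$noise_sigma)
               else s
    pts <- dirs * s_noisy
    n_out <- floor(cfg$outlier_fraction * n)
    if (n_out > 0L) {
      idx <- sample.int(n, n_out)
      ctr <- cfg$grape_center
      draw <- function(m)
        cbind(stats::runif(m, ctr[1L] - cfg$outlier_range,
                           ctr[1L] + cfg$outlier_range),
              stats::runif(m, ctr[2L] - cfg$outlier_range,
                           ctr[2L] + cfg$outlier_range),
              stats::runif(m, max(ctr[3L] - cfg$outlier_range, 1e-3),
                           ctr[3L] + cfg$outlier_range))
      spk <- draw(n_out)
      cl2 <- cfg$outlier_clearance^2
      min_d2 <- function(p) min(colSums((t(surface) - p)^2))
      for (tries in seq_len(200L)) {
        bad <- which(vapply(seq_len(nrow(spk)),
                            function(i) min_d2(spk[i, ]) < cl2,
                            logical(1L)))
        if (!length(bad)) break
        spk[bad, ] <- draw(length(bad))
      }
      pts[idx, ] <- spk
    }
    pts
  })
}

#' Synthetic coated (opaque-reference) scan
#'
#' Ray-casts a regular angular grid from the camera against the target
#' sphere and keeps first intersections: the rounded front surface an
#' opaque coating exposes, with no scattering distortion.  Gaussian depth
#' noise is added along each ray and a fraction of returns is replaced by
#' uniform speckle around the target.
#'
#' @param cfg a \code{\link{scene_config}}.
#' @param seed RNG seed for this scan; defaults to a deterministic
#'   derivation from \code{cfg$seed} (day slot 0).
#' @return List with \code{cloud} (a \code{\link{point_cloud}}) and
#'   \code{truth}: the exact front-surface distance \code{s_surf}
#'   (= centre distance - radius, mm along the central ray), apex
#'   position, and a config echo.
#' @export
make_coated_scan <- function(cfg, seed = per_day_seed(cfg$seed, 0)) {
  stopifnot(inherits(cfg, "scene_config"))
  g <- .ray_grid(cfg)
  # first intersection of s*dir with the sphere |p - c| = r
  vc <- as.vector(g$dirs %*% cfg$grape_center)
  disc <- vc^2 - (g$d^2 - cfg$sphere_radius^2)
  hit <- disc >= 0
  s <- vc[hit] - sqrt(disc[hit])
  pts <- .apply_noise(s, g$dirs[hit, , drop = FALSE], cfg, seed)
  truth <- list(kind = "coated",
                s_surf = g$d - cfg$sphere_radius,
                apex_position = (g$d - cfg$sphere_radius) * g$u,
                theta_grape = g$theta_g,
                config = cfg)
  list(cloud = point_cloud(pts, meta = list(coated = "TRUE",
                                            source = "synthetic")),
       truth = truth)
}

#' Synthetic uncoated (distorted) scan
#'
#' Emulates the scattering-distorted scan of a translucent berry on day
#' \code{t}: a peak that is rotationally symmetric about the
#' camera-to-grape ray, whose base sits a fixed \code{base_offset} behind
#' the true front surface and whose tip lies at
#' \eqn{s_{tip} = s_{surf} - y(t)} (programmed bias \eqn{y(t)} negative
#' means the tip appears farther than the true surface).  A grid ray at
#' angle \eqn{\theta} from the central ray returns distance
#' \deqn{s(\theta) = s_{base} - (s_{base} - s_{tip})
#'   \exp(-\theta^2 / (2 (w \theta_{grape})^2)),}
#' so the tip retreats with age while the base stays fixed.  Noise and
#' speckle as in \code{\link{make_coated_scan}}.
#'
#' @param cfg a \code{\link{scene_config}}.
#' @param t day index; the programmed bias is
#'   \code{\link{bias_schedule}(cfg, t)}.
#' @param seed RNG seed; defaults to a per-day derivation from
#'   \code{cfg$seed}.
#' @return List with \code{cloud} and \code{truth} (programmed \code{y},
#'   \code{s_tip}, \code{s_base}, apex position, config echo).
#' @export
make_uncoated_scan <- function(cfg, t, seed = per_day_seed(cfg$seed, t)) {
  stopifnot(inherits(cfg, "scene_config"))
  y <- bias_schedule(cfg, t)
  if (abs(y) > cfg$base_offset)
    stop(sprintf(
      "programmed |bias| %.2f mm exceeds base_offset %.2f mm on day %s (tip would pass the base)",
      abs(y), cfg$base_offset, format(t)))
  g <- .ray_grid(cfg)
  s_surf <- g$d - cfg$sphere_radius
  s_base <- s_surf + cfg$base_offset
  s_tip <- s_surf - y
  hit <- g$theta <= g$theta_g
  th <- g$theta[hit]
  w <- cfg$peak_width * g$theta_g
  s <- s_base - (s_base - s_tip) * exp(-th^2 / (2 * w^2))
  pts <- .apply_noise(s, g$dirs[hit, , drop = FALSE], cfg, seed)
  truth <- list(kind = "uncoated", t = t, y = y,
                s_surf = s_surf, s_tip = s_tip, s_base = s_base,
                apex_position = s_tip * g$u,
                theta_grape = g$theta_g,
                config = cfg)
  list(cloud = point_cloud(pts, meta = list(coated = "FALSE",
                                            day = as.character(t),
                                            source = "synthetic")),
       truth = truth)
}

#' Synthetic multi-day scan series
#'
#' One coated reference scan (taken on the first day) plus one uncoated
#' scan per day, with per-day seeds derived deterministically from the
#' config seed.
#'
#' @param cfg a \code{\link{scene_config}}.
#' @param days increasing vector of day indices (default 1:12).
#' @return A \code{scan_series}: list of entries, each a list with
#'   \code{t}, \code{coated} (logical), \code{cloud}, \code{truth}.  The
#'   coated entry comes first.
#' @export
make_scan_series <- function(cfg, days = 1:12) {
  stopifnot(inherits(cfg, "scene_config"))
  if (length(days) == 0L) stop("days must be non-empty")
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  coated <- make_coated_scan(cfg)
  entries <- vector("list", length(days) + 1L)
  entries[[1L]] <- list(t = days[1L], coated = TRUE,
                        cloud = coated$cloud, truth = coated$truth)
  for (i in seq_along(days)) {
    u <- make_uncoated_scan(cfg, days[i])
    entries[[i + 1L]] <- list(t = days[i], coated = FALSE,
                              cloud = u$cloud, truth = u$truth)
  }
  structure(entries, class = "scan_series", config = cfg)
}

#' Write a scan series to disk with a manifest
#'
#' Writes each scan as an ASCII PLY under \code{dir} and returns the
#' manifest data frame \code{\link{run_pipeline}} consumes.
#'
#' @param series a \code{\link{make_scan_series}} result.
#' @param dir output directory (created if needed).
#' @param label grape label used in file names and the manifest.
#' @return Data frame with columns \code{path}, \code{day},
#'   \code{coated}, \code{label}.
#' @export
write_scan_series <- function(series, dir, label = "grape1") {
  stopifnot(inherits(series, "scan_series"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(series, function(e) {
    fn <- file.path(dir, sprintf("%s_day%02d_%s.ply", label, e$t,
                                 if (e$coated) "coated" else "uncoated"))
    write_point_cloud(e$cloud, fn, format = "ply")
    data.frame(path = fn, day = e$t, coated = e$coated, label = label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Synthetic daily weight series
#'
#' Linear percentage weight loss: \eqn{W_t = W_o (1 - rate/100 (t-1))}
#' plus Gaussian noise of \code{noise_sigma} percent of \eqn{W_o}.
#'
#' @param Wo Day-1 weight in grams (> 0).
#' @param rate loss rate in percent per day (default 0.98, a typical
#'   post-harvest table-grape value).
#' @param days number of days (>= 2).
#' @param noise_sigma noise SD in percent of \code{Wo}.
#' @param seed RNG seed.
#' @return Data frame with columns \code{t} (1..days) and \code{W}
#'   (grams).
#' @export
make_weight_series <- function(Wo, rate = 0.98, days = 12L,
                               noise_sigma = 0, seed = 1L) {
  if (Wo <= 0) stop("Wo must be positive")
  if (days < 2L) stop("need at least 2 days")
  if (rate * (days - 1L) >= 100)
    stop(sprintf(
      "rate %.3g %%/day over %d days drives the weight non-positive", rate,
      days))
  t <- seq_len(days)
  W <- Wo * (1 - rate / 100 * (t - 1))
  if (noise_sigma > 0)
    W <- with_seed(seed, W + rnorm(days, 0, noise_sigma / 100 * Wo))
  if (any(W <= 0)) stop("noise drove a weight non-positive; reduce noise_sigma")
  data.frame(t = t, W = W)
}
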