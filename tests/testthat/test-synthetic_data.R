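test_that("noiseless coated scans lie exactly on the configured sphere", {
  # odd grid so a ray lies exactly on the optical axis
  cfg <- noiseless_cfg(angular_samples = 49L)
  sc <- make_coated_scan(cfg)
  expect_equal(min(sc$cloud$points[, "z"]), 360, tolerance = 1e-6)
  resid <- abs(sqrt(rowSums(sweep(sc$cloud$points, 2,
                                  cfg$grape_center)^2)) - cfg$sphere_radius)
  expect_lt(max(resid), 1e-6)
  expect_equal(sc$truth$s_surf, 360)
})

test_that("generators are pure functions of config, day and seed", {
  cfg <- scene_config(seed = 7)
  a <- make_coated_scan(cfg); b <- make_coated_scan(cfg)
  expect_identical(a$cloud$points, b$cloud$points)
  u1 <- make_uncoated_scan(cfg, 4); u2 <- make_uncoated_scan(cfg, 4)
  expect_identical(u1$cloud$points, u2$cloud$points)
  # different days draw different noise
  expect_false(identical(make_uncoated_scan(cfg, 5)$cloud$points,
                         u1$cloud$points))
  # the generator does not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(make_coated_scan(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("the uncoated on-axis tip realizes the programmed bias exactly", {
  # odd grid so a ray lies exactly on the central axis (theta = 0)
  cfg <- noiseless_cfg(angular_samples = 49L)
  u <- make_uncoated_scan(cfg, 1)   # y(1) = -9.52 under the default schedule
  expect_equal(u$truth$y, -9.52)
  s <- sqrt(rowSums(u$cloud$points^2))
  expect_equal(min(s), 360 + 9.52, tolerance = 1e-6)

  # zero bias: the tip coincides with the true surface apex
  cfg0 <- noiseless_cfg(angular_samples = 49L, bias_slope = 0,
                        bias_intercept = 0)
  u0 <- make_uncoated_scan(cfg0, 1)
  expect_equal(min(sqrt(rowSums(u0$cloud$points^2))), 360, tolerance = 1e-6)
  expect_equal(u0$truth$s_tip, u0$truth$s_surf)
})

test_that("the uncoated peak is rotationally symmetric about the central ray", {
  ctr <- c(-85, 0, 255)
  cfg <- noiseless_cfg(grape_center = ctr)
  u <- make_uncoated_scan(cfg, 3)
  ray <- central_ray(ctr)
  p <- u$cloud$points
  # per-point range along its own camera ray, and angle off the central ray
  s <- sqrt(rowSums(p^2))
  theta <- acos(pmin(1, as.vector(p %*% ray$direction) / s))
  # (a) s follows the programmed radial profile for every point
  w <- cfg$peak_width * u$truth$theta_grape
  s_model <- u$truth$s_base -
    (u$truth$s_base - u$truth$s_tip) * exp(-theta^2 / (2 * w^2))
  expect_lt(max(abs(s - s_model)), 1e-9)
  # (b) reflecting across a plane containing the ray leaves the binned
  # s(theta) profile unchanged
  e2 <- c(0, 1, 0)  # perpendicular to both the ray and the x-offset
  refl <- p - 2 * outer(as.vector(p %*% e2), e2)
  s_r <- sqrt(rowSums(refl^2))
  theta_r <- acos(pmin(1, as.vector(refl %*% ray$direction) / s_r))
  bins <- seq(0, max(theta) + 1e-9, length.out = 13L)
  prof <- function(th, ss) as.numeric(
    tapply(ss, cut(th, bins, include.lowest = TRUE), mean))
  expect_equal(prof(theta, s), prof(theta_r, s_r), tolerance = 1e-9)
})

test_that("scan series: one coated reference plus one scan per day", {
  cfg <- noiseless_cfg()
  ser <- make_scan_series(cfg, 1:12)
  expect_length(ser, 13L)
  expect_true(ser[[1]]$coated)
  expect_false(any(vapply(ser[-1], `[[`, TRUE, "coated")))
  ys <- vapply(ser[-1], function(e) e$truth$y, 0)
  expect_equal(ys, -0.62 * (1:12) - 8.9, tolerance = 1e-12)
  # per-day seeds are stable across runs
  ser2 <- make_scan_series(cfg, 1:12)
  expect_identical(ser[[5]]$cloud$points, ser2[[5]]$cloud$points)
  expect_error(make_scan_series(cfg, c(3, 2)), "increasing")
})

test_that("a bias schedule steeper than the base offset is rejected", {
  cfg <- noiseless_cfg(base_offset = 10)   # |y(12)| = 16.34 > 10
  expect_error(make_uncoated_scan(cfg, 12), "base_offset")
})

test_that("peak height decreases with age while the base stays fixed", {
  cfg <- noiseless_cfg(peak_width = 0.3, angular_samples = 160L)
  ray <- central_ray(cfg$grape_center)
  shapes <- lapply(c(1, 4, 8, 12), function(t)
    peak_shape(make_uncoated_scan(cfg, t)$cloud, ray, q = 0.001))
  h <- vapply(shapes, `[[`, 0, "height")
  truth_h <- vapply(c(1, 4, 8, 12), function(t)
    cfg$base_offset + bias_schedule(cfg, t), 0)
  expect_lt(max(abs(h - truth_h)), 0.1)
  expect_true(all(diff(h) < 0))
  b <- vapply(shapes, `[[`, 0, "base_s")
  expect_lt(max(abs(b - (360 + cfg$base_offset))), 0.15)
})

test_that("default speckle is isolated and the KNN filter removes it", {
  removed_frac <- surface_lost <- numeric(4)
  for (s in 1:4) {
    cfg <- scene_config(seed = s)
    u <- make_uncoated_scan(cfg, 5)
    twin <- make_uncoated_scan(scene_config(seed = s, outlier_fraction = 0), 5)
    moved <- rowSums((u$cloud$points - twin$cloud$points)^2) > 1e-12
    f <- knn_outlier_filter(u$cloud)
    removed_frac[s] <- sum(!f$kept[moved]) / sum(moved)
    surface_lost[s] <- sum(!f$kept[!moved]) / sum(!moved)
  }
  expect_true(all(removed_frac >= 0.95))
  expect_true(all(surface_lost <= 0.01))
})

test_that("weight series follow the linear loss model", {
  s <- make_weight_series(10, rate = 0.98, days = 12)
  expect_equal(s$W, 10 * (1 - 0.0098 * (0:11)), tolerance = 1e-12)
  s0 <- make_weight_series(5, rate = 0, days = 6)
  expect_true(all(s0$W == 5))
  sn <- make_weight_series(10, rate = 0.98, days = 12, noise_sigma = 0.1,
                           seed = 4)
  expect_identical(sn, make_weight_series(10, rate = 0.98, days = 12,
                                          noise_sigma = 0.1, seed = 4))
})
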