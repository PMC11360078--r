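test_that("central_ray points from the camera through the grape", {
  r <- central_ray(c(0, 0, 255))
  expect_equal(r$direction, c(0, 0, 1))

  for (ctr in list(c(-85, 0, 255), c(93, 0, 255))) {
    r <- central_ray(ctr)
    expect_equal(sqrt(sum(r$direction^2)), 1, tolerance = 1e-12)
    expect_equal(r$direction, ctr / sqrt(sum(ctr^2)), tolerance = 1e-12)
    expect_gt(r$direction[3], 0)
  }
  expect_error(central_ray(c(0, 0, 0)), "coincides")
  expect_error(central_ray(c(0, 0, -10)), "in front")
})

test_that("apex of a noiseless coated sphere matches the closed form d - r", {
  geoms <- list(c(0, 0, 369.525),        # front surface at 360 mm, on-axis
                c(-85, 0, 255), c(93, 0, 255),  # off-axis berries
                c(0, 0, 239.525))        # control sphere, front at 230 mm
  for (ctr in geoms) {
    cfg <- noiseless_cfg(grape_center = ctr)
    sc <- make_coated_scan(cfg)
    ap <- detect_apex(sc$cloud, central_ray(ctr), q = 0.01)
    d <- sqrt(sum(ctr^2))
    expect_lt(abs(ap$s - (d - cfg$sphere_radius)), 0.05)
  }
})

test_that("apex handles a single point and honors the angular window", {
  pc <- point_cloud(cbind(0, 0, 240))
  ap <- detect_apex(pc, central_ray(c(0, 0, 240)))
  expect_equal(ap$s, 240)
  expect_equal(ap$support, 1L)
  expect_error(
    detect_apex(point_cloud(cbind(100, 0, 100)), central_ray(c(0, 0, 1)),
                angular_window = 0.01),
    "angular window")
})

test_that("apex finds a programmed uncoated peak tip", {
  # tip programmed at s* = 372: front surface 360 mm, constant bias -12 mm
  cfg <- noiseless_cfg(bias_slope = 0, bias_intercept = -12)
  u <- make_uncoated_scan(cfg, t = 1)
  expect_equal(u$truth$s_tip, 372)
  ap <- detect_apex(u$cloud, central_ray(cfg$grape_center), q = 0.01)
  expect_lt(abs(ap$s - 372), 0.05)
})

test_that("distance bias is zero on self-comparison and antisymmetric", {
  cfg <- noiseless_cfg()
  sc <- make_coated_scan(cfg)$cloud
  un <- make_uncoated_scan(cfg, 3)$cloud
  for (m in c("along_ray", "z_axis")) {
    expect_equal(distance_bias(sc, sc, method = m)$y, 0)
    ab <- distance_bias(sc, un, method = m)$y
    ba <- distance_bias(un, sc, method = m)$y
    expect_equal(ab, -ba, tolerance = 1e-9)
  }
})

test_that("noiseless programmed bias is recovered by both conventions on-axis", {
  # day-1 bias of the y = -0.62 t - 8.9 schedule
  cfg <- noiseless_cfg()
  sc <- make_coated_scan(cfg)$cloud
  un <- make_uncoated_scan(cfg, 1)
  expect_equal(un$truth$y, -9.52)
  for (m in c("along_ray", "z_axis")) {
    b <- distance_bias(sc, un$cloud, method = m, t = 1)
    expect_lt(abs(b$y - (-9.52)), 0.05)
  }
})

test_that("along-ray bias is recovered off-axis; Z-axis foreshortens", {
  ctr <- c(-85, 0, 255)
  cfg <- noiseless_cfg(grape_center = ctr, bias_slope = 0,
                       bias_intercept = -10)
  sc <- make_coated_scan(cfg)$cloud
  un <- make_uncoated_scan(cfg, 1)$cloud
  b_ar <- distance_bias(sc, un, method = "along_ray")
  expect_lt(abs(b_ar$y - (-10)), 0.1)
  b_z <- distance_bias(sc, un, method = "z_axis")
  cos_off <- 255 / sqrt(sum(ctr^2))
  expect_gt(abs(b_z$y - (-10)), 10 * (1 - cos_off) * 0.9)
})

test_that("along-ray bias is invariant to the off-axis angle", {
  base <- NULL
  for (ctr in list(c(0, 0, 255), c(-85, 0, 255), c(93, 0, 255))) {
    cfg <- noiseless_cfg(grape_center = ctr, bias_slope = 0,
                         bias_intercept = -10)
    y <- distance_bias(make_coated_scan(cfg)$cloud,
                       make_uncoated_scan(cfg, 1)$cloud,
                       method = "along_ray")$y
    if (is.null(base)) base <- y
    expect_lt(abs(y - base), 0.1)
  }
})

test_that("cross sections match brute-force membership and sorting", {
  pc <- random_cloud(500, seed = 21)
  cs <- cross_section(pc, axis = "X", center = 5, tolerance = 20)
  sub <- pc$points[abs(pc$points[, "y"] - 5) <= 20, , drop = FALSE]
  sub <- sub[order(sub[, "x"]), , drop = FALSE]
  expect_equal(unname(cs$samples),
               unname(sub[, c("x", "z"), drop = FALSE]))

  wide <- cross_section(pc, axis = "Y", center = 0, tolerance = 1e6)
  expect_equal(nrow(wide$samples), 500L)
  expect_true(!is.unsorted(wide$samples[, "coordinate"]))
  none <- cross_section(pc, axis = "Y", center = 1e5, tolerance = 1)
  expect_equal(nrow(none$samples), 0L)
})

test_that("peak shape recovers programmed height and orders days correctly", {
  # narrow peak on a dense grid: the scan sees the full tip-to-base sweep
  # and the tip estimator resolves the sharp apex
  cfg <- noiseless_cfg(bias_slope = 0, bias_intercept = -12,
                       peak_width = 0.3, angular_samples = 160L)
  u <- make_uncoated_scan(cfg, 1)
  ray <- central_ray(cfg$grape_center)
  ps <- peak_shape(u$cloud, ray, q = 0.001)  # sharp tip: tight quantile
  expect_equal(u$truth$s_base - u$truth$s_tip, 8)
  expect_lt(abs(ps$height - 8), 0.1)
  expect_gt(ps$width_at_half_height, 0)

  # height strictly decreases with age under a negative-slope schedule
  cfg2 <- noiseless_cfg(peak_width = 0.3)
  h <- vapply(c(1, 5, 9), function(t)
    peak_shape(make_uncoated_scan(cfg2, t)$cloud, ray)$height, 0)
  expect_true(all(diff(h) < 0))

  # flat plane perpendicular to the ray (small angular extent, as inside
  # a berry window): height ~ 0 and no half-height width
  g <- as.matrix(expand.grid(x = seq(-5, 5, 1), y = seq(-5, 5, 1)))
  plane <- point_cloud(cbind(g, z = 500))
  psf <- peak_shape(plane, central_ray(c(0, 0, 500)))
  expect_lt(psf$height, 0.1)

  expect_error(peak_shape(point_cloud(cbind(0, 0, 100)), ray), ">= 10")
})
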