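# shared fixtures: small random clouds and noiseless scene configs

random_cloud <- function(n, seed, span = 100) {
  set.seed(seed)
  point_cloud(cbind(x = runif(n, -span, span),
                    y = runif(n, -span, span),
                    z = runif(n, 10, 10 + 2 * span)))
}

noiseless_cfg <- function(...) {
  scene_config(noise_sigma = 0, outlier_fraction = 0, ...)
}

# independent O(N^2) oracle for the KNN filter: full pairwise distance
# matrix, full sorts, no chunking — a separate code path from the package
oracle_knn_mask <- function(pc, k, mode, threshold) {
  D <- as.matrix(dist(pc$points))
  diag(D) <- Inf
  d <- apply(D, 1L, function(r) mean(sort(r)[seq_len(k)]))
  cut <- if (mode == "absolute") threshold else mean(d) + threshold * sd(d)
  unname(d <= cut)
}

# per-day bias recovery over a synthetic series; returns data.frame of
# programmed and measured biases
measure_series <- function(cfg, days, method) {
  ser <- make_scan_series(cfg, days)
  ref <- ser[[1L]]$cloud
  ray <- central_ray(colMeans(ref$points))
  do.call(rbind, lapply(ser[-1L], function(e) {
    b <- distance_bias(ref, e$cloud, ray = ray, method = method, t = e$t)
    data.frame(t = e$t, y_true = e$truth$y, y_est = b$y)
  }))
}
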