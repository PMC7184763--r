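# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 2000 oriented samples of a radius-10 sphere
sphere_cloud <- function(n = 2000, radius = 10, seed = 7) {
  with_seed_test(seed, {
    u <- matrix(stats::rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    point_cloud(radius * u, normals = u)
  })
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# small camera used across tests
test_camera <- function() intrinsics(400, 400, 160, 120, width = 320, height = 240)

# analytic calibration correspondences on the default mat:
# 15 views (3 elevations x 5 azimuths), true fx=800/fy=790, optional noise,
# outliers and distortion
calib_fixture <- function(noise_px = 0, outlier_frac = 0, k1 = 0.05,
                          seed = 1, fx = 800, fy = 790, distance = 150) {
  target <- calibration_target()
  K <- intrinsics(fx, fy, 322, 238)
  rig <- turntable_rig(3, 5, c(12, 18, 24), distance, c(0, 0, 0))
  poses <- rig_poses(rig)
  corr <- with_seed_test(seed, lapply(poses, function(e) {
    uv <- project(cbind(target$points$x_cm, target$points$y_cm, 0), K, e)
    uv <- radial_correct(uv, K, k1)
    if (noise_px > 0)
      uv <- uv + matrix(stats::rnorm(length(uv), 0, noise_px), ncol = 2)
    df <- data.frame(id = target$points$id, u = uv[, 1], v = uv[, 2])
    if (outlier_frac > 0) {
      n_out <- round(outlier_frac * nrow(df))
      ii <- sample(nrow(df), n_out)
      df$u[ii] <- df$u[ii] + stats::runif(n_out, 25, 80) *
        sample(c(-1, 1), n_out, TRUE)
      df$v[ii] <- df$v[ii] + stats::runif(n_out, 25, 80) *
        sample(c(-1, 1), n_out, TRUE)
      attr(df, "outliers") <- ii
    }
    df
  }))
  list(target = target, intr = K, poses = poses, corr = corr, k1 = k1)
}

# one rendered plant + segmentation masks + reconstruction, cached
render_fixture <- function() {
  cached("render_fixture", function() {
    plant <- make_plant_cloud(plant_spec(seed = 11), 8000)
    K <- test_camera()
    rig <- turntable_rig()
    rs <- render_views(plant$cloud, rig, K, n_dots = 1500, seed = 3)
    masks <- lapply(rs$images, segment_blue_screen)
    cameras <- list(intr = K, views = rs$poses)
    cloud <- build_cloud(rs$images, masks, cameras, ground_truth_detector(rs))
    list(plant = plant, K = K, rig = rig, rs = rs, masks = masks,
         cameras = cameras, cloud = cloud)
  })
}

# brute-force min-area rectangle: area minimum over a 0.01-degree angle grid
brute_rect_area <- function(pts, step_deg = 0.01) {
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  th <- seq(0, 90 - step_deg, by = step_deg) * pi / 180
  ct <- cos(th); st <- sin(th)
  u <- hull %*% rbind(ct, st)
  v <- hull %*% rbind(-st, ct)
  du <- apply(u, 2, max) - apply(u, 2, min)
  dv <- apply(v, 2, max) - apply(v, 2, min)
  min(du * dv)
}
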