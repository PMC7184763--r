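two_view_cameras <- function() {
  K <- intrinsics(500, 500, 320, 240)
  rig <- turntable_rig(1, 12, 15, 100, c(0, 0, 10))
  list(intr = K, views = rig_poses(rig))
}

make_matches <- function(cams, n = 50, seed = 1) {
  with_seed_test(seed, {
    X <- cbind(stats::runif(n, -15, 15), stats::runif(n, -15, 15),
               stats::runif(n, 0, 35))
    uv1 <- project(X, cams$intr, cams$views[[1]])
    uv2 <- project(X, cams$intr, cams$views[[2]])
    list(X = X,
         df = data.frame(view_a = 1, view_b = 2, ua = uv1[, 1], va = uv1[, 2],
                         ub = uv2[, 1], vb = uv2[, 2], score = 1))
  })
}

test_that("epipolar filter keeps true matches and rejects shuffled ones", {
  cams <- two_view_cameras()
  mm <- make_matches(cams)
  kept <- epipolar_filter(mm$df, cams, threshold = 1)
  expect_equal(nrow(kept), 50)
  bad <- mm$df[sample(50, 20), ]
  bad[, c("ub", "vb")] <- bad[sample(20), c("ub", "vb")] +
    matrix(stats::runif(40, 15, 60), ncol = 2)
  mixed <- rbind(mm$df, bad)
  kept2 <- epipolar_filter(mixed, cams, threshold = 1)
  expect_equal(nrow(kept2), 50)
  expect_equal(sort(kept2$ua), sort(mm$df$ua))
})

test_that("uncalibrated RANSAC mode needs 8 matches and finds the inliers", {
  cams <- two_view_cameras()
  mm <- make_matches(cams, n = 60, seed = 5)
  expect_error(epipolar_filter(mm$df[1:5, ], cameras = NULL),
               "insufficient matches")
  with_seed_test(6, {
    bad <- mm$df[1:15, ]
    bad[, c("ub", "vb")] <- bad[, c("ub", "vb")] +
      matrix(stats::runif(30, 20, 80), ncol = 2)
    mixed <- rbind(mm$df, bad)
    kept <- epipolar_filter(mixed, cameras = NULL, threshold = 1, seed = 42)
    expect_gte(nrow(kept), 55)
    expect_lte(nrow(kept), 62)
  })
})

test_that("DLT triangulation round-trips exact projections", {
  cams <- two_view_cameras()
  X <- c(1, 2, 3)
  uv1 <- project(X, cams$intr, cams$views[[1]])
  uv2 <- project(X, cams$intr, cams$views[[2]])
  m <- list(view_a = 1, view_b = 2, ua = uv1[1], va = uv1[2],
            ub = uv2[1], vb = uv2[2])
  tr <- triangulate(m, cams)
  expect_equal(tr$point, X, tolerance = 1e-9)
  expect_lt(tr$reproj_error, 1e-9)
  expect_true(tr$in_front)
  expect_error(triangulate(list(view_a = 1, view_b = 1), cams), "differ")
})

test_that("triangulation under pixel noise keeps sub-voxel median error", {
  K <- intrinsics(800, 800, 320, 240, width = 640, height = 480)
  rig <- turntable_rig()
  cams <- list(intr = K, views = rig_poses(rig))
  errs <- with_seed_test(31, {
    X <- cbind(stats::runif(200, -15, 15), stats::runif(200, -15, 15),
               stats::runif(200, 10, 50))
    unlist(lapply(seq_len(nrow(X)), function(i) {
      # two stops apart: a 48-degree baseline within the ring
      uv1 <- project(X[i, ], K, cams$views[[1]]) + stats::rnorm(2, 0, 0.5)
      uv2 <- project(X[i, ], K, cams$views[[3]]) + stats::rnorm(2, 0, 0.5)
      tr <- triangulate(list(view_a = 1, view_b = 3, ua = uv1[1], va = uv1[2],
                             ub = uv2[1], vb = uv2[2]), cams)
      sqrt(sum((tr$point - X[i, ])^2))
    }))
  })
  expect_lt(stats::median(errs), 0.2)
})

test_that("cloud building reconstructs the rendered plant surface", {
  fx <- render_fixture()
  cloud <- fx$cloud
  expect_gt(nrow(cloud$positions), 500)
  # one-sided Hausdorff distance to ground-truth surface samples
  G <- t(fx$plant$cloud$positions)
  d <- vapply(seq_len(nrow(cloud$positions)), function(i)
    min(colSums((G - cloud$positions[i, ])^2)), numeric(1))
  expect_lt(sqrt(max(d)), 0.3)
  # every output point reprojects into the foreground mask of >= 2 views
  sel <- seq(1, nrow(cloud$positions), length.out = 50)
  nviews <- vapply(sel, function(i) {
    hits <- 0
    for (v in seq_along(fx$cameras$views)) {
      uv <- project(cloud$positions[i, ], fx$cameras$intr,
                    fx$cameras$views[[v]])
      px <- round(uv[1]); py <- round(uv[2])
      if (px >= 0 && px < ncol(fx$masks[[v]]) &&
          py >= 0 && py < nrow(fx$masks[[v]]) &&
          fx$masks[[v]][py + 1, px + 1]) hits <- hits + 1
    }
    hits
  }, numeric(1))
  expect_true(all(nviews >= 2))
  # all-background masks are rejected
  expect_error(
    build_cloud(fx$rs$images, lapply(fx$masks, function(m) m & FALSE),
                fx$cameras, ground_truth_detector(fx$rs)),
    "no plant pixels")
  # zero merge tolerance keeps every triangulated point
  raw <- build_cloud(fx$rs$images, fx$masks, fx$cameras,
                     ground_truth_detector(fx$rs), merge_voxel_cm = 0)
  merged <- build_cloud(fx$rs$images, fx$masks, fx$cameras,
                        ground_truth_detector(fx$rs), merge_voxel_cm = 0.1)
  expect_gte(nrow(raw$positions), nrow(merged$positions))
})

test_that("cloud construction is deterministic for a fixed detector", {
  fx <- render_fixture()
  c1 <- build_cloud(fx$rs$images, fx$masks, fx$cameras,
                    ground_truth_detector(fx$rs))
  expect_identical(c1$positions, fx$cloud$positions)
})
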