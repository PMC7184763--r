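test_that("rendered target dots are re-detected and identified sub-pixel", {
  target <- calibration_target()
  K <- intrinsics(600, 600, 320, 240, width = 640, height = 480)
  rig <- turntable_rig(1, 15, 20, 120, c(0, 0, 0))
  poses <- rig_poses(rig)
  k1 <- 0.05
  imgs <- render_target_views(target, poses[c(1, 6, 11)], K, k1 = k1)
  for (i in seq_along(imgs)) {
    v <- c(1, 6, 11)[i]
    det <- detect_target_points(imgs[[i]], target)
    expect_equal(nrow(det), 60)
    wp <- target$points[match(det$id, target$points$id), ]
    pred <- radial_correct(project(cbind(wp$x_cm, wp$y_cm, 0), K, poses[[v]]),
                           K, k1)
    err <- sqrt(rowSums((pred - cbind(det$u, det$v))^2))
    expect_lt(max(err), 0.5)
  }
  # occlusion: 10 dots missing, no spurious identifications
  occ <- render_target_views(target, poses[1], K, k1 = k1,
                             omit_ids = 1:10)[[1]]
  det <- detect_target_points(occ, target)
  expect_gte(nrow(det), 50)
  expect_false(any(det$id %in% 1:10))
  blank <- array(255, c(480, 640, 3))
  expect_error(detect_target_points(blank, target), "target not found")
})

clean_calibration <- function() {
  cached("clean_calibration", function() {
    fx <- calib_fixture()
    list(fx = fx,
         cal = suppressWarnings(calibrate_ransac(fx$corr, fx$target)))
  })
}

test_that("calibration recovers intrinsics exactly from clean views", {
  fx <- clean_calibration()$fx
  cal <- clean_calibration()$cal
  expect_lt(abs(cal$intr$fx - 800) / 800, 0.001)
  expect_lt(abs(cal$intr$fy - 790) / 790, 0.001)
  expect_lt(abs(cal$k1 - fx$k1), 0.001)
  expect_lt(cal$mean_reproj_error, 1e-6)
  expect_error(calibrate_ransac(fx$corr[1:2], fx$target),
               "insufficient views")
})

test_that("calibration flags gross outliers and still recovers fx", {
  fx <- calib_fixture(outlier_frac = 0.2, seed = 2)
  cal <- suppressWarnings(calibrate_ransac(fx$corr, fx$target))
  expect_lt(abs(cal$intr$fx - 800) / 800, 0.005)
  for (v in seq_along(fx$corr)) {
    out_idx <- attr(fx$corr[[v]], "outliers")
    expect_true(all(!cal$inliers[[v]][out_idx]))
    expect_true(all(cal$inliers[[v]][-out_idx]))
  }
})

test_that("k1 recovery under half-pixel noise stays within ten percent", {
  # the mat must fill the field of view for k1 to be observable
  for (k1 in c(0.05, 0.15)) {
    fx <- calib_fixture(noise_px = 0.5, k1 = k1, seed = 4, distance = 55)
    cal <- suppressWarnings(
      calibrate_ransac(fx$corr, fx$target, ransac_config(threshold = 6)))
    expect_lt(abs(cal$k1 - k1) / k1, 0.1)
  }
})

test_that("RANSAC calibration is bit-reproducible under a fixed seed", {
  fx <- calib_fixture(noise_px = 0.5, outlier_frac = 0.1, seed = 3)
  cal1 <- suppressWarnings(calibrate_ransac(fx$corr, fx$target))
  cal2 <- suppressWarnings(calibrate_ransac(fx$corr, fx$target))
  expect_identical(cal1$intr$fx, cal2$intr$fx)
  expect_identical(cal1$k1, cal2$k1)
  expect_identical(cal1$inliers, cal2$inliers)
})

test_that("camera parameters survive a JSON round trip", {
  cal <- clean_calibration()$cal
  p <- withr::local_tempfile(fileext = ".json")
  write_cameras_json(cal, p)
  back <- read_cameras_json(p)
  expect_equal(back$intr$fx, cal$intr$fx)
  expect_equal(back$k1, cal$k1)
  expect_equal(back$views[[3]]$R, cal$views[[3]]$R, tolerance = 1e-12)
  expect_equal(back$views[[3]]$t, cal$views[[3]]$t, tolerance = 1e-12)
})
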