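test_that("projection maps camera-frame points through the pinhole model", {
  K <- intrinsics(500, 500, 320, 240)
  E <- extrinsics(diag(3), c(0, 0, 0))
  expect_equal(project(c(0, 0, 1), K, E), c(320, 240))
  expect_equal(project(c(0.2, 0, 1), K, E), c(420, 240))
  # scale invariance of the homogeneous projection
  p <- c(0.3, -0.2, 2)
  for (lam in c(0.5, 3, 17)) {
    expect_equal(project(lam * p, K, E), project(p, K, E), tolerance = 1e-12)
  }
  expect_error(project(c(1, 1, 0), K, E), "infinity")
})

test_that("intrinsics and extrinsics enforce their invariants", {
  expect_error(intrinsics(-1, 500, 0, 0), "fx")
  expect_error(intrinsics(500, 500, 900, 240, width = 640, height = 480),
               "bounds")
  expect_error(extrinsics(matrix(1, 3, 3), c(0, 0, 0)), "orthonormal")
  R_reflect <- diag(c(1, 1, -1))
  expect_error(extrinsics(R_reflect, c(0, 0, 0)), "det")
})

test_that("forward distortion matches the displacement model term by term", {
  expect_equal(distort_forward(c(0.1, 0), distortion_model(k1 = 0.1)),
               c(0.1001, 0))
  expect_equal(distort_forward(c(0, 0.1), distortion_model(p1 = 0.01))[1],
               1e-4)
  # zero-coefficient model is the identity on a 1000-point grid, exactly
  with_seed_test(5, {
    g <- matrix(stats::runif(2000, -1, 1), ncol = 2)
    expect_identical(distort_forward(g, distortion_model()), g)
  })
})

test_that("radial pixel distortion and its fixed-point inverse agree", {
  Ki <- intrinsics(100, 100, 100, 100)
  expect_equal(radial_correct(c(110, 100), Ki, 0.1), c(110.01, 100))
  K <- intrinsics(500, 500, 320, 240)
  expect_equal(radial_correct(c(371, 212), K, 0), c(371, 212))
  with_seed_test(6, {
    pts <- cbind(stats::runif(200, 0, 640), stats::runif(200, 0, 480))
    for (k1 in c(-0.2, -0.05, 0.05, 0.2)) {
      pd <- radial_correct(pts, K, k1)
      back <- radial_undistort(pd, K, k1)
      expect_lt(max(abs(back - pts)), 1e-6)
    }
  })
})

test_that("calibration target has the radial 15x4 layout", {
  target <- calibration_target()
  expect_equal(nrow(target$points), 60)
  expect_equal(length(unique(target$points$group)), 15)
  expect_true(all(table(target$points$group) == 4))
  expect_gt(target$min_spacing_cm, 2)
})

test_that("turntable rig poses rotate by the azimuth step about the vertical axis", {
  rig <- turntable_rig()
  poses <- rig_poses(rig)
  expect_length(poses, 60)
  for (e in poses) {
    expect_lt(max(abs(crossprod(e$R) - diag(3))), 1e-9)
    expect_equal(det(e$R), 1, tolerance = 1e-9)
  }
  # consecutive same-ring poses: pure 24-degree azimuth rotation
  ring <- attr(poses, "ring")
  for (v in c(1, 7, 31, 59)) {
    if (ring[v] == ring[v + 1])
      expect_equal(relative_rotation_angle(poses[[v]], poses[[v + 1]]), 24,
                   tolerance = 1e-9)
  }
  single <- rig_poses(turntable_rig(1, 1, 15))
  expect_length(single, 1)
  expect_error(turntable_rig(1, 15, elevations_deg = 40), "10, 25")
})
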