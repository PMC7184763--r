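test_that("plant generator honours its spec and is seed-deterministic", {
  sp <- plant_spec(footprint_length_cm = 40, footprint_width_cm = 30,
                   canopy_top_cm = 60, cotyledon_cm = 5, seed = 1)
  pl <- make_plant_cloud(sp, 2000)
  expect_equal(pl$truth$canopy_height_cm, 55)
  expect_equal(pl$truth$canopy_area_cm2, 1200)
  expect_equal(pl$truth$plant_volume_dm3, 66)
  expect_error(make_plant_cloud(sp, 100), "500")
  pl2 <- make_plant_cloud(sp, 2000)
  expect_identical(pl$cloud$positions, pl2$cloud$positions)
  # normals are unit and the cloud stays in the stated bounding box
  expect_equal(sqrt(rowSums(pl$cloud$normals^2)), rep(1, 2000),
               tolerance = 1e-9)
  expect_lte(max(abs(pl$cloud$positions[, 1])), 20 + 1e-9)
  expect_lte(max(abs(pl$cloud$positions[, 2])), 15 + 1e-9)
  expect_lte(max(pl$cloud$positions[, 3]), 60 + 1e-9)
  expect_error(plant_spec(cotyledon_cm = 50, apex_cm = 40), "below the apex")
})

test_that("growth-series generator lies on the curve at zero noise", {
  spec0 <- growth_spec(noise_sd_frac = 0, seed = 5)
  gs <- make_growth_series(spec0)
  truth <- attr(gs, "truth")
  for (tr in names(gs)) {
    expect_equal(gs[[tr]]$values,
                 logistic_value(truth[[tr]], gs[[tr]]$days))
    expect_length(gs[[tr]]$values, 9)
  }
  spec2 <- growth_spec(noise_sd_frac = 0.02, seed = 6)
  expect_identical(make_growth_series(spec2)[[1]]$values,
                   make_growth_series(spec2)[[1]]$values)
})

test_that("rendering produces the rig's views with exact dot reprojection", {
  fx <- render_fixture()
  expect_length(fx$rs$images, 60)
  expect_identical(dim(fx$rs$images[[1]]), c(240L, 320L, 3L))
  # recorded correspondences are noiseless projections of the dot samples
  co <- fx$rs$correspondences
  i <- which(co$view_a == 1)[1:50]
  X <- fx$rs$dot_xyz[match(co$point_id[i], fx$rs$dot_ids), ]
  uv <- project(X, fx$K, fx$rs$poses[[1]])
  expect_equal(cbind(co$ua[i], co$va[i]), uv, tolerance = 1e-9,
               ignore_attr = TRUE)
  # determinism under a fixed seed
  rs2 <- render_views(fx$plant$cloud, fx$rig, fx$K, n_dots = 1500, seed = 3)
  expect_identical(rs2$correspondences, fx$rs$correspondences)
  expect_error(render_views(point_cloud(matrix(0, 0, 3)), fx$rig, fx$K),
               "empty scene")
})
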