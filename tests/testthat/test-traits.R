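test_that("minimum-area rectangle matches geometry and the sweep oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  r <- min_area_rectangle(sq)
  expect_equal(r$length, 1, tolerance = 1e-12)
  expect_equal(r$width, 1, tolerance = 1e-12)
  th <- pi / 4
  Rm <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  r45 <- min_area_rectangle(sq %*% t(Rm))
  expect_equal(r45$area, 1, tolerance = 1e-9)   # not the axis-aligned sqrt(2) box
  expect_error(min_area_rectangle(rbind(c(0, 0), c(1, 1))), "degenerate")
  expect_error(min_area_rectangle(cbind(1:5, 2 * (1:5) + 3)), "degenerate")
  with_seed_test(3, {
    for (i in 1:100) {
      pts <- matrix(stats::rnorm(2 * sample(10:60, 1)), ncol = 2)
      a_impl <- min_area_rectangle(pts)$area
      a_grid <- brute_rect_area(pts)
      # calipers is the exact optimum: never above the grid minimum, and
      # below it by at most the grid's own resolution error
      expect_lte(a_impl, a_grid * (1 + 1e-6))
      expect_gte(a_impl, a_grid * (1 - 1e-3))
    }
  })
})

test_that("rectangle dimensions are rotation-invariant and scale covariantly", {
  with_seed_test(8, {
    pts <- matrix(stats::rnorm(80), ncol = 2)
    r0 <- min_area_rectangle(pts)
    for (th in c(0.3, 1.1, 2.5)) {
      Rm <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
      r1 <- min_area_rectangle(pts %*% t(Rm))
      expect_equal(r1$length, r0$length, tolerance = 1e-9)
      expect_equal(r1$width, r0$width, tolerance = 1e-9)
    }
  })
})

test_that("trait extraction recovers the generator's exact ground truth", {
  plant <- make_plant_cloud(plant_spec(seed = 2), 20000)
  rec <- extract_traits(plant$cloud, ground_frame(cotyledon_height_cm = 5))
  truth <- plant$truth
  for (cc in c("plant_length_cm", "plant_width_cm", "plant_height_cm",
               "canopy_height_cm", "canopy_area_cm2", "plant_volume_dm3")) {
    expect_lt(abs(rec[[cc]] - truth[[cc]]) / truth[[cc]], 0.01)
  }
  # the defining products hold exactly
  expect_equal(rec$canopy_area_cm2, rec$plant_length_cm * rec$plant_width_cm)
  expect_equal(rec$plant_volume_dm3,
               rec$plant_length_cm * rec$plant_width_cm *
                 rec$canopy_height_cm / 1000)
  expect_gte(rec$plant_length_cm, rec$plant_width_cm)
  expect_error(extract_traits(point_cloud(matrix(0, 1, 3))), "degenerate")
  expect_error(
    extract_traits(plant$cloud, ground_frame(cotyledon_height_cm = 100)),
    "inconsistent reference")
})

test_that("asymptotic DN251 length and width reproduce the printed canopy area", {
  # fitted plant-length and plant-width asymptotes of variety DN251
  area <- 62.528 * 57.668
  expect_equal(area, 3605.848, tolerance = 1e-4)
})

test_that("traits scale as lengths, areas and volumes under uniform scaling", {
  plant <- make_plant_cloud(plant_spec(seed = 5), 5000)
  frame <- ground_frame(cotyledon_height_cm = 5)
  r1 <- extract_traits(plant$cloud, frame)
  lam <- 1.7
  scaled <- point_cloud(plant$cloud$positions * lam)
  r2 <- extract_traits(scaled, ground_frame(cotyledon_height_cm = 5 * lam))
  expect_equal(r2$plant_length_cm, lam * r1$plant_length_cm, tolerance = 1e-9)
  expect_equal(r2$canopy_height_cm, lam * r1$canopy_height_cm, tolerance = 1e-9)
  expect_equal(r2$canopy_area_cm2, lam^2 * r1$canopy_area_cm2, tolerance = 1e-9)
  expect_equal(r2$plant_volume_dm3, lam^3 * r1$plant_volume_dm3,
               tolerance = 1e-9)
})

test_that("cotyledon-node height estimation finds the generator's mark", {
  plant <- make_plant_cloud(plant_spec(cotyledon_cm = 5, seed = 3), 20000)
  est <- estimate_cotyledon_height(plant$cloud)
  expect_lt(abs(est - 5), 0.5)
  expect_equal(estimate_cotyledon_height(plant$cloud, override = 4.2), 4.2)
  flat <- point_cloud(cbind(stats::runif(50), stats::runif(50),
                            stats::runif(50, 3, 3.8)))
  expect_equal(estimate_cotyledon_height(flat), min(flat$positions[, 3]))
})
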