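p0 <- list(n0 = 10, k = 100, r = 0.1)

test_that("logistic curve hits its closed-form landmarks", {
  expect_equal(logistic_value(p0, 0), 10)
  expect_equal(logistic_value(p0, log(9) / 0.1), 50)
  expect_equal(logistic_value(p0, 1e6), 100, tolerance = 1e-9)
  expect_error(logistic_value(list(n0 = -1, k = 10, r = 0.1), 1), "positive")
  # monotone increasing for K > N0
  tt <- seq(0, 200, by = 0.25)
  expect_true(all(diff(logistic_value(p0, tt)) > 0))
})

test_that("growth rate follows dN/dt = r(1 - N/K)N with max rK/4 at K/2", {
  expect_equal(growth_rate(p0, log(9) / 0.1), 2.5, tolerance = 1e-12)
  early <- growth_rate(list(n0 = 1, k = 1000, r = 0.2), 0)
  expect_equal(early, 0.1998, tolerance = 1e-6)
  # numeric argmax on a dense grid equals t* = ln(K/N0-1)/r
  tt <- seq(0, 100, by = 0.001)
  tstar_grid <- tt[which.max(growth_rate(p0, tt))]
  expect_equal(tstar_grid, max_rate_time(p0), tolerance = 0.001)
})

test_that("max-rate time is ln(K/N0 - 1)/r with boundary and error cases", {
  expect_equal(max_rate_time(p0), log(9) / 0.1)
  expect_equal(max_rate_time(list(n0 = 50, k = 100, r = 0.2)), 0)
  expect_error(max_rate_time(list(n0 = 100, k = 50, r = 0.2)), "invalid fit")
  expect_equal(max_rate_time(p0, round_days = TRUE), 22)
})

test_that("gradient-descent fit recovers generating parameters", {
  days <- c(10, 20, 30, 40, 55, 70, 85, 100, 115)
  truth <- list(n0 = 8, k = 85, r = 0.12)
  s <- trait_series("A", "plant_height_cm", days, logistic_value(truth, days))
  f <- fit_logistic(s)
  expect_lt(abs(f$n0 - truth$n0) / truth$n0, 0.005)
  expect_lt(abs(f$k - truth$k) / truth$k, 0.005)
  expect_lt(abs(f$r - truth$r) / truth$r, 0.005)
  # derived identities hold exactly for the fitted parameters
  expect_equal(growth_rate(f, f$t_inflection), f$rate_max, tolerance = 1e-9)
  expect_equal(logistic_value(f, f$t_inflection), f$k / 2, tolerance = 1e-9)
  expect_error(fit_logistic(trait_series("A", "x", 1:3, c(1, 2, 3))), "4")
})

test_that("constant series warns and fits the constant as the asymptote", {
  s <- trait_series("A", "x", c(10, 20, 30, 40), rep(42, 4))
  expect_warning(f <- fit_logistic(s), "constant")
  expect_false(f$converged)
  expect_equal(f$k, 42, tolerance = 0.1)
})

test_that("Monte-Carlo recovery under 2% noise is accurate and unbiased", {
  days <- c(10, 20, 30, 40, 55, 70, 85, 100, 115)
  truth <- list(n0 = 8, k = 85, r = 0.12)
  errs <- with_seed_test(42, {
    t(vapply(1:100, function(i) {
      y <- pmax(0, logistic_value(truth, days) +
                  stats::rnorm(length(days), 0, 0.02 * truth$k))
      f <- suppressWarnings(fit_logistic(trait_series("A", "x", days, y)))
      c((f$k - truth$k) / truth$k,
        (f$r - truth$r) / truth$r,
        (f$n0 - truth$n0) / truth$n0)
    }, numeric(3)))
  })
  # the asymptote is pinned tightly by the data; the early-season
  # parameters are only unbiased (their per-fit spread is noise-driven)
  expect_lt(stats::median(abs(errs[, 1])), 0.03)
  expect_lt(abs(stats::median(errs[, 2])), 0.03)
  expect_lt(abs(stats::median(errs[, 3])), 0.03)
})

test_that("fingerprint normalizes the four traits to [0,1] with per-trait max 1", {
  tab <- expand.grid(variety = c("A", "B", "C", "D", "E"),
                     stage = c("V3", "V4", "R1", "R2", "R3", "R5", "R6",
                               "R7", "R8"))
  with_seed_test(9, {
    for (cc in c("plant_height_cm", "plant_length_cm", "plant_width_cm",
                 "canopy_height_cm"))
      tab[[cc]] <- stats::runif(nrow(tab), 10, 90)
  })
  fp <- fingerprint(tab)
  expect_equal(dim(fp$values), c(45, 4))
  expect_true(all(fp$values >= 0 & fp$values <= 1))
  expect_equal(unname(apply(fp$values, 2, max)), rep(1, 4))
  # single variety, single stage: all ones
  fp1 <- fingerprint(tab[1, , drop = FALSE])
  expect_equal(unname(fp1$values[1, ]), rep(1, 4), ignore_attr = TRUE)
  # dominance: scale variety A above everyone
  tab2 <- tab
  sel <- tab2$variety == "A"
  for (cc in c("plant_height_cm", "plant_length_cm", "plant_width_cm",
               "canopy_height_cm"))
    tab2[[cc]][sel] <- tab2[[cc]][sel] + 100
  fp2 <- fingerprint(tab2)
  expect_true(all(fp2$values[fp2$meta$variety != "A", ] < 1))
  expect_true(any(fp2$values[fp2$meta$variety == "A", 1] == 1))
  # normalization preserves within-trait ordering
  raw <- tab2$plant_height_cm[match(paste(fp2$meta$variety, fp2$meta$stage),
                                    paste(tab2$variety, tab2$stage))]
  expect_equal(order(fp2$values[, 1]), order(raw))
  expect_error(fingerprint(tab[, -3]), "incomplete")
})

test_that("pearson correlation matches hand computations", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 0.981980506,
               tolerance = 1e-8)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(pearson_r(1:2, 1:2), "3")
})

test_that("Welch t-test separates shifted groups and calibrates type-I error", {
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  far <- welch_t_test(c(1, 2, 3), c(101, 102, 103))
  expect_lt(far$p_value, 1e-4)
  expect_error(welch_t_test(1, c(1, 2)), ">= 2")
  rej <- with_seed_test(12, {
    mean(vapply(1:1000, function(i) {
      welch_t_test(stats::rnorm(8), stats::rnorm(8))$p_value < 0.05
    }, logical(1)))
  })
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})
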