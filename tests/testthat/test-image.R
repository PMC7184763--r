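test_that("wavelet denoising passes constants through and reduces noise", {
  flat <- array(128, c(32, 32, 3))
  expect_equal(wavelet_denoise(flat), flat, tolerance = 1e-10)
  with_seed_test(1, {
    clean <- array(rep(100 + outer(sin((1:64) / 8), cos((1:64) / 9)) * 40, 3),
                   c(64, 64, 3))
    noisy <- pmin(pmax(clean + array(stats::rnorm(64 * 64 * 3, 0, 20),
                                     c(64, 64, 3)), 0), 255)
    den <- wavelet_denoise(noisy)
    expect_lt(mean((den - clean)^2), mean((noisy - clean)^2))
    expect_true(all(den >= 0 & den <= 255))
    # near-idempotent: a second pass moves almost nothing
    den2 <- wavelet_denoise(den)
    expect_lt(sum((den2 - den)^2), 0.01 * sum((den - noisy)^2))
  })
  expect_error(wavelet_denoise(array(0, c(8, 8, 3)), levels = 4),
               "too small|level too deep")
  expect_error(wavelet_denoise(array(0, c(32, 32, 3)), levels = 6),
               "level too deep")
})

test_that("blue-screen rule classifies pixels by chroma dominance", {
  px <- function(r, g, b) {
    img <- array(0, c(1, 1, 3)); img[1, 1, ] <- c(r, g, b)
    segment_blue_screen(img, 30, clean = FALSE)[1, 1]
  }
  expect_false(px(0, 0, 255))       # pure blue -> background
  expect_true(px(0, 255, 0))        # pure green -> foreground
  expect_false(px(128, 128, 160))   # 160 > 158 on both -> background
  expect_true(px(128, 128, 158))    # not strictly dominant -> foreground
})

test_that("mask partitions the image and cleanup removes speckle", {
  with_seed_test(4, {
    img <- array(stats::runif(60 * 80 * 3, 0, 255), c(60, 80, 3))
    m <- segment_blue_screen(img, 30)
    expect_identical(dim(m), c(60L, 80L))
    expect_equal(sum(m) + sum(!m), 60 * 80)
    # salt noise on a blue field: isolated foreground pixels removed
    blue <- array(0, c(60, 80, 3)); blue[, , 3] <- 255
    blue[10, 10, ] <- c(255, 0, 0)
    m2 <- segment_blue_screen(blue, 30, min_area = 5)
    expect_false(any(m2))
  })
})

test_that("segmentation of rendered views matches the true silhouette", {
  fx <- render_fixture()
  iou <- vapply(seq_along(fx$masks), function(v) {
    a <- fx$masks[[v]]; b <- fx$rs$silhouettes[[v]]
    sum(a & b) / sum(a | b)
  }, numeric(1))
  expect_gt(min(iou), 0.98)
})

test_that("images and masks survive PNG round trips", {
  with_seed_test(2, {
    img <- array(sample(0:255, 30 * 40 * 3, TRUE), c(30, 40, 3))
    p <- withr::local_tempfile(fileext = ".png")
    write_image(img, p)
    expect_equal(read_image(p), img)
    m <- matrix(stats::runif(30 * 40) > 0.5, 30, 40)
    pm <- withr::local_tempfile(fileext = ".png")
    write_mask(m, pm)
    expect_equal(read_mask(pm), m)
  })
})
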