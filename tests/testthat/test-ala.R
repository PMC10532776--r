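test_that("patch variability matches hand-computed window statistics", {
  flat <- matrix(42, 9, 9)
  expect_equal(patch_variability(flat, 5, 5, 2, "stddev"), 0)
  expect_equal(patch_variability(flat, 5, 5, 2, "range"), 0)

  y <- matrix(0, 9, 9); y[5, 5] <- 255
  expect_equal(patch_variability(y, 5, 5, 1, "stddev"), 255 * sqrt(8) / 9)
  expect_equal(patch_variability(y, 5, 5, 1, "range"), 255)

  ## corner windows are clipped: statistic over the 2x2 partial window only
  z <- matrix(c(10, 20, 30, 40), 2, 2)[rep(1:2, 3), rep(1:2, 3)]
  win <- z[1:2, 1:2]
  expect_equal(patch_variability(z, 1, 1, 1, "stddev"),
               sqrt(mean((win - mean(win))^2)))
  expect_equal(patch_variability(z, 1, 1, 1, "range"), max(win) - min(win))

  expect_error(patch_variability(flat, 0, 5, 1), "coordinate error")
  expect_error(patch_variability(flat, 5, 10, 1), "coordinate error")
})

test_that("per-pixel adaptive average reproduces the brute-force loop", {
  p <- ala_params(threshold = 6)
  flat <- matrix(123, 7, 7)
  expect_equal(ala_pixel(flat, 4, 4, p), 123)

  y <- make_test_plane(9, 9, sigma = 5, seed = 21)
  o <- oracle_ala(y, 6)
  for (ij in list(c(5, 5), c(1, 1), c(9, 3), c(2, 8))) {
    expect_identical(ala_pixel(y, ij[1], ij[2], p), o[ij[1], ij[2]])
  }

  ## pixel adjacent to a hard step whose r = 1 window already exceeds Th
  step <- matrix(0, 8, 8); step[, 5:8] <- 255
  expect_identical(ala_pixel(step, 3, 4, ala_params(threshold = 50)), 0)
})

test_that("vectorized filter equals the brute-force oracle exactly", {
  p5 <- ala_params(threshold = 5.6)
  for (seed in 1:4) {
    y <- make_test_plane(32, 32, sigma = c(2, 5, 10, 30)[seed], seed = seed)
    expect_identical(ala_filter(y, p5), oracle_ala(y, 5.6))
  }
  ## range statistic has its own oracle path
  y <- make_test_plane(24, 24, sigma = 5, seed = 31)
  expect_identical(ala_filter(y, ala_params(threshold = 25,
                                            variability_statistic = "range")),
                   oracle_ala(y, 25, statistic = "range"))
})

test_that("constant planes are fixed points and output stays in the input range", {
  flat <- matrix(200, 16, 16)
  expect_identical(ala_filter(flat, ala_params(threshold = 10)), flat)
  expect_identical(ala_filter(flat), flat)  # auto threshold (= mu/60) too
  for (seed in 1:10) {
    y <- make_test_plane(24, 24, sigma = 10, seed = 100 + seed)
    f <- ala_filter(y, ala_params(threshold = 8))
    expect_gte(min(f), min(y))
    expect_lte(max(f), max(y))
  }
})

test_that("filtering a noisy plane reduces variance and conserves brightness", {
  for (seed in 1:20) {
    set.seed(seed)
    y <- round(pmin(pmax(96 + rnorm(48 * 48, sd = 8), 0), 255))
    y <- matrix(y, 48, 48)
    f <- ala_filter(y, ala_params(threshold = 10))
    expect_lte(stats::var(as.vector(f)), stats::var(as.vector(y)))
    expect_lt(abs(mean(f) - mean(y)) / mean(y), 0.01)
  }
})

test_that("a noiseless step edge below-threshold nowhere is left untouched", {
  ## Th below the r = 1 cross-edge stddev: windows crossing the contour fail
  ## at once, windows inside a region average a constant -- exact identity.
  step <- matrix(0, 32, 32); step[, 17:32] <- 255
  expect_identical(ala_filter(step, ala_params(threshold = 50)), step)
})

test_that("auto threshold inside the filter equals the explicit formula", {
  y <- make_test_plane(32, 32, sigma = 4, seed = 77)
  expect_identical(ala_filter(y),
                   ala_filter(y, ala_params(threshold = ala_threshold(noise_stats(y)))))
})

test_that("parameter validation rejects degenerate configurations", {
  expect_error(ala_params(threshold = -1), "domain error")
  expect_error(ala_params(min_extent = 0), "min_extent")
  expect_error(ala_params(min_extent = 4, max_extent = 4), "max_extent")
  expect_error(ala_filter(matrix(5, 1, 1), ala_params(threshold = 1)), "size error")
})
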