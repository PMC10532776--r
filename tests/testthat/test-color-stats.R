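test_that("YUV decomposition isolates luminance with neutral chroma at 128", {
  gray <- array(rep(c(0, 67, 128, 255), each = 4), dim = c(4, 4, 3))
  yuv <- rgb_to_yuv(gray)
  expect_equal(yuv$y, gray[, , 1], tolerance = 1e-12)
  expect_equal(yuv$u, matrix(128, 4, 4), tolerance = 1e-12)
  expect_equal(yuv$v, matrix(128, 4, 4), tolerance = 1e-12)

  red <- array(0, dim = c(2, 2, 3)); red[, , 1] <- 255
  expect_equal(round(rgb_to_yuv(red)$y[1, 1]), 76)  # BT.601 luma of pure red

  expect_error(rgb_to_yuv(array(0, dim = c(4, 4, 2))), "channel-count")
})

test_that("rgb -> yuv -> rgb round trip is identity within one gray level", {
  for (seed in 1:5) {
    set.seed(seed)
    img <- array(sample(0:255, 16 * 16 * 3, replace = TRUE), dim = c(16, 16, 3))
    back <- yuv_to_rgb(rgb_to_yuv(img))
    expect_lt(max(abs(back - img)), 1 + 1e-9)
  }
})

test_that("yuv_to_rgb handles neutral chroma, black, and rejects mismatched planes", {
  n <- matrix(128, 3, 3)
  gray <- yuv_to_rgb(list(y = n, u = n, v = n))
  expect_equal(gray, array(128, dim = c(3, 3, 3)), tolerance = 1e-12)
  black <- yuv_to_rgb(list(y = matrix(0, 3, 3), u = n, v = n))
  expect_equal(black, array(0, dim = c(3, 3, 3)), tolerance = 1e-12)
  expect_error(yuv_to_rgb(list(y = matrix(0, 3, 3), u = n, v = matrix(128, 4, 4))),
               "dimension")
})

test_that("metric grayscale is the unweighted channel mean", {
  px <- array(c(30, 60, 90), dim = c(1, 1, 3))[rep(1, 2), rep(1, 2), ]
  expect_equal(rgb_to_gray(px), matrix(60, 2, 2))
  set.seed(3)
  img <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), dim = c(8, 8, 3))
  perm <- img[, , c(3, 1, 2)]
  expect_equal(rgb_to_gray(img), rgb_to_gray(perm))        # permutation-invariant
  expect_equal(mean(rgb_to_gray(img)), mean(img))          # linearity of the mean
})

test_that("median brightness uses the midpoint convention for even counts", {
  expect_equal(median_brightness(matrix(96, 5, 5)), 96)
  expect_equal(median_brightness(matrix(1:9, 3, 3)), 5)
  expect_equal(median_brightness(matrix(c(0, 0, 255, 255), 2, 2)), 127.5)
  ## two central order statistics of {0,0,0,255} are both 0
  expect_equal(median_brightness(matrix(c(0, 0, 0, 255), 2, 2)), 0)
})

test_that("Laplacian noise estimate annihilates constant and affine planes", {
  expect_equal(estimate_noise_sigma(matrix(77, 6, 6)), 0)
  ramp <- matrix(rep(seq(0, 50, length.out = 12), each = 12), 12, 12)
  expect_equal(estimate_noise_sigma(ramp), 0, tolerance = 1e-10)
  expect_error(estimate_noise_sigma(matrix(0, 2, 5)), "size error")
})

test_that("Laplacian noise estimate matches a brute-force convolution oracle", {
  y <- matrix(0, 5, 5); y[3, 3] <- 60
  ## direct 3x3 convolution over the 3x3 interior
  kern <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  acc <- c()
  for (i in 2:4) for (j in 2:4) {
    acc <- c(acc, abs(sum(kern * y[(i - 1):(i + 1), (j - 1):(j + 1)])))
  }
  expect_equal(estimate_noise_sigma(y), sqrt(pi / 40) * mean(acc))

  ## unbiasedness under pure Gaussian noise: estimate ~= true sigma
  set.seed(11)
  est <- replicate(20, {
    n <- matrix(pmin(pmax(128 + rnorm(96 * 96, sd = 6), 0), 255), 96, 96)
    estimate_noise_sigma(n)
  })
  expect_equal(mean(est), 6, tolerance = 0.05)
})

test_that("noise estimate is monotone in noise amplitude", {
  clean <- 100 + 40 * outer(sin(seq_len(64) / 13), cos(seq_len(64) / 17))
  sig <- sapply(1:20, function(seed) {
    set.seed(seed)
    sapply(c(2, 8, 20), function(s) {
      estimate_noise_sigma(pmin(pmax(clean + rnorm(64 * 64, sd = s), 0), 255))
    })
  })
  expect_true(all(sig[2, ] > sig[1, ]))
  expect_true(all(sig[3, ] > sig[2, ]))
})

test_that("threshold formula Th = 2 sigma + mu / 60 is exact and affine", {
  expect_equal(ala_threshold(list(mu_median = 120, sigma_laplacian = 3)), 8)
  expect_equal(ala_threshold(list(mu_median = 0, sigma_laplacian = 0)), 0)
  expect_equal(ala_threshold(list(mu_median = 96, sigma_laplacian = 2)), 5.6)
  ## affine: doubling sigma at fixed mu raises Th by exactly 2 sigma
  for (mu in c(0, 60, 200)) {
    for (s in c(0.5, 3, 10)) {
      expect_equal(ala_threshold(list(mu_median = mu, sigma_laplacian = 2 * s)) -
                     ala_threshold(list(mu_median = mu, sigma_laplacian = s)),
                   2 * s)
    }
  }
  expect_error(ala_threshold(list(mu_median = 10, sigma_laplacian = -1)), "domain")
})

test_that("noise_stats bundles the two global statistics of a plane", {
  y <- make_test_plane(32, 32, sigma = 4, seed = 9)
  st <- noise_stats(y)
  expect_s3_class(st, "noise_stats")
  expect_equal(st$mu_median, median_brightness(y))
  expect_equal(st$sigma_laplacian, estimate_noise_sigma(y))
})
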