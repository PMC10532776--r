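test_that("scenes are deterministic and structurally as specified", {
  flat <- make_scene("flat", size = c(16, 16))
  expect_equal(flat, array(96, dim = c(16, 16, 3)))

  step <- make_scene("two_region_step", size = c(32, 32))
  g <- rgb_to_gray(step)
  expect_setequal(unique(as.vector(g)), c(50, 200))
  expect_true(all(g[, 1:16] == 50) && all(g[, 17:32] == 200))

  ramp <- rgb_to_gray(make_scene("gradient_ramp", size = c(8, 16)))
  expect_true(all(diff(t(ramp)) >= 0))
  expect_equal(ramp[1, 1], 0); expect_equal(ramp[1, 16], 255)

  chk <- rgb_to_gray(make_scene("checker", size = c(48, 48)))
  expect_setequal(unique(as.vector(chk)), c(40, 215))
  expect_true(all(chk[1:16, 1:16] == chk[1, 1]))

  b1 <- make_scene("blobs_texture", size = c(64, 64), seed = 3)
  b2 <- make_scene("blobs_texture", size = c(64, 64), seed = 3)
  expect_identical(b1, b2)
  expect_false(identical(b1, make_scene("blobs_texture", size = c(64, 64), seed = 4)))
  ## contains a sharp contour (multiple levels) and a homogeneous region
  gb <- rgb_to_gray(b1)
  expect_gt(length(unique(as.vector(round(gb)))), 3)
  homog <- apply(gb[, 44:64], 1, function(r) any(diff(r) == 0))
  expect_true(any(homog))
  expect_error(make_scene("flat", size = c(1, 5)), "configuration error")
})

test_that("gaussian noise has the requested amplitude and determinism", {
  flat <- make_scene("flat", size = c(128, 128))
  expect_equal(add_noise(flat, "gaussian", sigma = 0, seed = 1), flat)
  for (seed in 1:3) {
    n <- add_noise(flat, "gaussian", sigma = 10, seed = seed)
    s <- stats::sd(n - flat)
    expect_gt(s, 9); expect_lt(s, 11)   # clipping negligible at level 96
  }
  expect_identical(add_noise(flat, "gaussian", sigma = 5, seed = 7),
                   add_noise(flat, "gaussian", sigma = 5, seed = 7))
  expect_false(identical(add_noise(flat, "gaussian", sigma = 5, seed = 7),
                         add_noise(flat, "gaussian", sigma = 5, seed = 8)))
  expect_error(add_noise(flat, "gaussian", sigma = -1), "domain error")
  expect_error(add_noise(flat, poisson_scale = 0), "domain error")
})

test_that("poisson-gaussian noise variance grows with signal level", {
  step <- make_scene("two_region_step", size = c(96, 96))
  n <- add_noise(step, "poisson_gaussian", sigma = 2, poisson_scale = 1, seed = 5)
  resid <- rgb_to_gray(n) - rgb_to_gray(step)
  v_dark <- stats::var(as.vector(resid[, 1:44]))     # level 50 region
  v_bright <- stats::var(as.vector(resid[, 53:96]))  # level 200 region
  expect_gt(v_bright, v_dark)
})

test_that("per-channel sigmas produce channel-dependent noise levels", {
  flat <- make_scene("flat", size = c(96, 96))
  n <- add_noise(flat, "gaussian", per_channel_sigma = c(2, 6, 12), seed = 3)
  sds <- sapply(1:3, function(ch) stats::sd(n[, , ch] - 96))
  expect_true(all(diff(sds) > 0))
})

test_that("frame averaging converges to the clean scene at the CLT rate", {
  flat <- make_scene("flat", size = c(48, 48))
  one <- make_ground_truth(flat, n_frames = 1, model = "gaussian", sigma = 10,
                           seed = 2)
  expect_gt(stats::sd(one - flat), 8)    # a single frame is still noisy
  gt <- make_ground_truth(flat, n_frames = 200, model = "gaussian", sigma = 10,
                          seed = 2)
  resid_sd <- stats::sd(gt - flat)
  expect_gt(resid_sd, 10 / sqrt(200) * 0.8)
  expect_lt(resid_sd, 10 / sqrt(200) * 1.2)
})

test_that("ground-truth quality is monotone in the number of averaged frames", {
  clean <- make_scene("two_region_step", size = c(32, 32))
  mean_psnr <- sapply(c(1, 10, 100), function(n) {
    mean(sapply(1:10, function(seed) {
      psnr_pair(clean, make_ground_truth(clean, n_frames = n, model = "gaussian",
                                         sigma = 10, seed = seed))
    }))
  })
  expect_true(all(diff(mean_psnr) > 0))
})

test_that("fixture batches land on disk with the pairing convention", {
  dir <- withr::local_tempdir()
  man <- write_fixture_batch(dir, n_scenes = 3, size = c(48, 48), n_frames = 10,
                             seed = 5)
  expect_equal(nrow(man), 3)
  expect_true(all(file.exists(file.path(dir, paste0(man$id, "_real.png")))))
  expect_true(all(file.exists(file.path(dir, paste0(man$id, "_mean.png")))))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
})
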