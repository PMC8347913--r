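test_that("SSIM of an image with itself is 1 in both modes", {
  set.seed(42)
  x <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  expect_equal(ssim(x, x, mode = "windowed"), 1, tolerance = 1e-12)
})

test_that("SSIM is symmetric and bounded by 1 over random pairs", {
  set.seed(7)
  for (i in 1:100) {
    x <- matrix(runif(256, 0, 255), 16, 16)
    y <- matrix(runif(256, 0, 255), 16, 16)
    s1 <- ssim(x, y); s2 <- ssim(y, x)
    expect_equal(s1, s2, tolerance = 1e-12)
    expect_lte(s1, 1 + 1e-12)
  }
})

test_that("constant-image SSIM decreases with the intensity gap", {
  v <- vapply(c(10, 60, 140), function(d)
    ssim(matrix(100, 8, 8), matrix(100 + d, 8, 8)), numeric(1))
  expect_true(all(v > 0 & v < 1))
  expect_true(all(diff(v) < 0))
})

test_that("anticorrelated checkerboard reproduces the hand-worked value", {
  x <- matrix(c(0, 0, 255, 255), 2, 2)
  y <- 255 - x
  # hand evaluation: means 127.5, variances 127.5^2, covariance -127.5^2
  C1 <- 2.55^2; C2 <- 7.65^2
  hand <- ((2 * 127.5^2 + C1) * (-2 * 127.5^2 + C2)) /
          ((2 * 127.5^2 + C1) * (2 * 127.5^2 + C2))
  expect_equal(ssim(x, y), hand, tolerance = 1e-12)
  expect_equal(hand, -0.996, tolerance = 5e-4)
})

test_that("shape mismatches and bad constants are rejected", {
  expect_error(ssim(matrix(0, 4, 4), matrix(0, 5, 5)), "shapes differ")
  expect_error(ssim(matrix(0, 4, 4), matrix(0, 4, 4), C1 = 0), "positive")
})

test_that("mean adjacent SSIM samples at the requested interval", {
  frames <- replicate(30, matrix(runif(64, 0, 255), 8, 8), simplify = FALSE)
  # identical frames: similarity 1 at any interval
  same <- replicate(12, frames[[1]], simplify = FALSE)
  expect_equal(mean_adjacent_ssim(same, 3), 1, tolerance = 1e-12)
  # 30 frames at interval 15 -> exactly one pair (frames 1 and 16)
  expect_equal(mean_adjacent_ssim(frames, 15), ssim(frames[[1]], frames[[16]]))
  expect_error(mean_adjacent_ssim(frames, 30), "smaller than")
})

test_that("interval selection picks the mean SSIM closest to target", {
  tab <- c("10" = 0.8406, "15" = 0.8090, "20" = 0.7781)
  expect_identical(select_sampling_interval(tab, 0.7992), 15L)
  expect_identical(select_sampling_interval(c("7" = 0.5)), 7L)
  # exact tie breaks toward the larger interval
  expect_identical(select_sampling_interval(c("10" = 0.79, "20" = 0.81), 0.80),
                   20L)
  # order invariance
  expect_identical(select_sampling_interval(tab[c(3, 1, 2)], 0.7992), 15L)
  expect_error(select_sampling_interval(numeric(0)), "no candidate")
})

test_that("sampling report aggregates sequences and picks an interval", {
  base <- eye_scene(image_size = 48, pupil = ellipse_params(24, 24, 10, 9, 0),
                    noise_sd = 1, rng_seed = 8)
  dyn <- sequence_dynamics(24, plr_trajectory(24, c(20, 18), c(10, 9), 0.12))
  rep_ <- sampling_report(render_sequence(base, dyn), intervals = c(2, 5, 8),
                          target = 0.9)
  expect_s3_class(rep_, "sampling_report")
  expect_true(attr(rep_, "chosen") %in% c(2L, 5L, 8L))
  expect_true(all(rep_$mean_ssim <= 1 + 1e-12))
})
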