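small_training_setup <- function(n = 40, size = 32, seed = 9) {
  ds <- synth_eye_dataset(n, image_size = size, seed = seed)
  spec <- network_spec(filters = 4, input_size = size)
  list(ds = ds, spec = spec)
}

test_that("training reduces the loss and is seed-deterministic", {
  s <- small_training_setup()
  ctl <- pupilnet_control(epochs_per_stage = 5, seed = 0)
  fit1 <- pupilnet(s$ds, s$spec, ctl)
  stage1 <- fit1$history[fit1$history$stage == 1, ]
  expect_lt(tail(stage1$loss, 1), stage1$loss[1])
  fit2 <- pupilnet(s$ds, s$spec, ctl)
  expect_equal(tail(fit1$history$loss, 1), tail(fit2$history$loss, 1),
               tolerance = 1e-6)
  expect_equal(predict(fit1, s$ds), predict(fit2, s$ds), tolerance = 1e-8)
})

test_that("stage partition is disjoint and near-equal", {
  parts <- pupilsize:::stage_partition(sample.int(9), 3)
  expect_equal(lengths(parts), c("1" = 3L, "2" = 3L, "3" = 3L))
  expect_length(Reduce(intersect, parts), 0)
  expect_setequal(unlist(parts), 1:9)
  parts2 <- pupilsize:::stage_partition(1:10, 3)
  expect_equal(unname(lengths(parts2)), c(4L, 3L, 3L))
})

test_that("degenerate inputs are rejected", {
  s <- small_training_setup()
  empty <- pupilsize:::subset_dataset(s$ds, integer(0))
  expect_error(pupilnet(empty, s$spec), "empty training set")
  expect_error(pupilnet_control(learning_rates = c(1e-3, 1e-3, 1e-4)),
               "strictly decreasing")
  fit <- pupilnet(s$ds, s$spec, pupilnet_control(epochs_per_stage = 1, seed = 1))
  expect_error(predict(fit, matrix(0, 64, 64)), "must be 32 x 32")
})

test_that("prediction has the shape contract and honors a zeroed head", {
  s <- small_training_setup(n = 8)
  fit <- pupilnet(s$ds, s$spec, pupilnet_control(epochs_per_stage = 1, seed = 2))
  pred <- predict(fit, s$ds$images[1:4])
  expect_equal(dim(pred), c(4, 2))
  expect_true(all(is.finite(pred)))

  head_i <- length(fit$weights)
  fit$weights[[head_i]]$w[] <- 0
  fit$weights[[head_i]]$b[] <- c(0.25, -0.5)
  pz <- predict(fit, s$ds$images[1:3])
  expected <- c(0.25, -0.5) * fit$target_scale + fit$target_center
  for (i in 1:3) expect_equal(unname(pz[i, ]), unname(expected),
                              tolerance = 1e-12)
})

test_that("model methods expose fit diagnostics", {
  s <- small_training_setup(n = 12)
  fit <- pupilnet(s$ds, s$spec, pupilnet_control(epochs_per_stage = 1, seed = 3))
  expect_output(print(fit), "parameters")
  expect_output(print(summary(fit)), "mean axis-length error")
  expect_equal(dim(residuals(fit)), c(12, 2))
  expect_equal(fitted(fit) + residuals(fit),
               as.matrix(s$ds$labels[, c("major_px", "minor_px")]),
               ignore_attr = TRUE)
  expect_gt(length(coef(fit)), 3)
})

test_that("mean error reproduces hand-worked cases", {
  r <- mean_error(cbind(11, 9), cbind(10, 10))
  expect_equal(r$mean_error_length, 10)
  expect_equal(r$mean_error_area, 1)
  ident <- mean_error(cbind(c(40, 30), c(24, 22)), cbind(c(40, 30), c(24, 22)))
  expect_equal(ident$mean_error_length, 0)
  expect_equal(ident$mean_error_area, 0)
})

test_that("mean error is scale-aware and permutation-invariant", {
  set.seed(13)
  truth <- cbind(runif(20, 20, 50), runif(20, 10, 20))
  pred <- truth * matrix(runif(40, 0.8, 1.2), 20, 2)
  r1 <- mean_error(pred, truth)
  r2 <- mean_error(3 * pred, 3 * truth)
  expect_equal(r1$mean_error_length, r2$mean_error_length, tolerance = 1e-12)
  perm <- sample.int(20)
  r3 <- mean_error(pred[perm, ], truth[perm, ])
  expect_equal(r1$mean_error_length, r3$mean_error_length, tolerance = 1e-12)
  expect_equal(r1$mean_error_area, r3$mean_error_area, tolerance = 1e-12)
  expect_error(mean_error(pred, truth * 0), "positive")
})

test_that("prediction pair ordering does not affect evaluation", {
  pred <- cbind(c(30, 18), c(35, 12))   # first row has minor > major
  truth <- cbind(c(36, 20), c(30, 12))
  swapped <- pred[, 2:1]
  expect_equal(mean_error(pred, truth)$mean_error_length,
               mean_error(swapped, truth)$mean_error_length)
})

test_that("a middle-depth network outperforms the shallow one at desk scale", {
  # same split, same seed: C(4,2,1) vs C(1,1,1), Type I filters
  ds <- synth_eye_dataset(1500, image_size = 48, seed = 500)
  tr <- pupilsize:::subset_dataset(ds, 1:1200)
  te <- pupilsize:::subset_dataset(ds, 1201:1500)
  errs <- vapply(c("K333_C111_D111", "K333_C421_D111"), function(p) {
    fit <- pupilnet(tr, network_preset(p, filters = 8, input_size = 48),
                    pupilnet_control(epochs_per_stage = 10, seed = 0))
    mean_error(predict(fit, te), te)$mean_error_length
  }, numeric(1))
  expect_lte(errs[["K333_C421_D111"]], errs[["K333_C111_D111"]])
})
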