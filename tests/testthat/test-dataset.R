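test_that("augmentation draws transform labels consistently", {
  e <- ellipse_params(76, 76, 20, 12, 30)
  img <- render_eye(reference_scene(noise_sd = 0))$image
  flip <- list(scale = 1, shift_x = 0, shift_y = 0, rotation = 0,
               flip_h = TRUE, flip_v = FALSE)
  out <- augment_sample(img, e, flip)
  expect_equal(unname(axis_lengths(out$label)), c(40, 24))

  sc13 <- list(scale = 1.3, shift_x = 0, shift_y = 0, rotation = 0,
               flip_h = FALSE, flip_v = FALSE)
  out <- augment_sample(img, e, sc13)
  expect_equal(unname(axis_lengths(out$label)), c(52, 31.2))

  rot <- list(scale = 1, shift_x = 0, shift_y = 0, rotation = 30,
              flip_h = FALSE, flip_v = FALSE)
  out <- augment_sample(img, e, rot)
  expect_equal(unname(axis_lengths(out$label)), c(40, 24))
  expect_equal(out$label$theta, 60)
})

test_that("augmented noiseless images re-fit to the transformed label", {
  sc <- reference_scene(noise_sd = 0,
                        pupil = ellipse_params(76, 76, 18, 13, 40))
  r <- render_eye(sc)
  cfg <- augmentation_config()
  set.seed(17)
  checked <- 0
  while (checked < 8) {
    d <- sample_augmentation_draw(cfg)
    out <- augment_sample(r$image, r$pupil, d)
    ext <- pupilsize:::ellipse_extent(out$label)
    inside <- out$label$cx - ext[1] > 3 && out$label$cx + ext[1] < 150 &&
              out$label$cy - ext[2] > 3 && out$label$cy + ext[2] < 150
    if (!inside) next
    f <- fit_ellipse(extract_pupil_contour(out$image))
    expect_lt(abs(2 * f$a - 2 * out$label$a) / (2 * out$label$a), 0.03)
    expect_lt(abs(2 * f$b - 2 * out$label$b) / (2 * out$label$b), 0.03)
    checked <- checked + 1
  }
})

test_that("labels round-trip through CSV and PNG", {
  ds <- synth_eye_dataset(12, image_size = 48, seed = 3)
  path <- file.path(tempfile("labdir"), "labels.csv")
  write_labels(ds, path)
  back <- read_labels(path)
  expect_equal(back$labels$major_px, ds$labels$major_px, tolerance = 1e-9)
  expect_equal(back$labels$theta_deg, ds$labels$theta_deg, tolerance = 1e-9)
  # images quantized to 8 bits on write
  expect_lt(max(abs(back$images[[1]] - ds$images[[1]])), 0.51)
})

test_that("label schema violations and empty files behave as specified", {
  dir <- tempfile("lab2"); dir.create(dir)
  f <- file.path(dir, "labels.csv")
  write.csv(data.frame(filename = "a.png", cx = 1, cy = 1, minor_px = 2,
                       theta_deg = 0), f, row.names = FALSE)
  expect_error(read_labels(f), "major_px")
  write.csv(data.frame(filename = character(), cx = numeric(),
                       cy = numeric(), major_px = numeric(),
                       minor_px = numeric(), theta_deg = numeric()),
            f, row.names = FALSE)
  empty <- read_labels(f)
  expect_length(empty$images, 0)
})

test_that("split arithmetic, determinism and ordering hold", {
  ds <- synth_eye_dataset(10, image_size = 48, seed = 5)
  out <- build_dataset(ds, aug = NULL, split = split_config(shuffle_seed = 2))
  expect_length(out$train$images, 7)
  expect_length(out$test$images, 3)
  out2 <- build_dataset(ds, aug = NULL, split = split_config(shuffle_seed = 2))
  expect_identical(out$train$labels$origin, out2$train$labels$origin)

  expect_error(build_dataset(ds, target_count = 5), "smaller than")
  expect_error(split_config(train_fraction = 1.0), "strictly in")
})

test_that("splitting before augmentation keeps descendants with their originals", {
  ds <- synth_eye_dataset(50, image_size = 48, seed = 6)
  out <- build_dataset(ds, aug = augmentation_config(),
                       split = split_config(shuffle_seed = 3,
                                            split_order = "before_augmentation"),
                       target_count = 160)
  expect_length(out$train$images, 112)
  expect_length(out$test$images, 48)
  leak <- intersect(out$train$labels$origin, out$test$labels$origin)
  expect_length(leak, 0)

  # after_augmentation reproduces the leak-prone order: descendants may split
  out2 <- build_dataset(ds, aug = augmentation_config(),
                        split = split_config(shuffle_seed = 3,
                                             split_order = "after_augmentation"),
                        target_count = 160)
  expect_equal(length(out2$train$images) + length(out2$test$images), 160)
})

test_that("balancing tops up sources toward equal counts", {
  ds1 <- synth_eye_dataset(9, image_size = 48, seed = 7)
  ds2 <- synth_eye_dataset(3, image_size = 48, seed = 8)
  ds2$labels$source_id <- "small_source"
  pool <- pupil_dataset(c(ds1$images, ds2$images),
                        rbind(ds1$labels, ds2$labels))
  pool$labels$origin <- seq_len(12)
  out <- pupilsize:::balance_augment(pool, augmentation_config(rng_seed = 1), 30)
  counts <- table(out$labels$source_id)
  expect_equal(length(out$images), 30)
  expect_gte(min(counts[["small_source"]]), 3)
})
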