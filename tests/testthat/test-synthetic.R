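test_that("rendered ground truth is the requested ellipse", {
  sc <- reference_scene(noise_sd = 0)
  r <- render_eye(sc)
  expect_equal(unname(axis_lengths(r$pupil)), c(40, 24))
  expect_equal(dim(r$image), c(152, 152))
  expect_true(all(r$image >= 0 & r$image <= 255))
})

test_that("intensity ordering holds inside pupil vs iris annulus", {
  sc <- reference_scene(noise_sd = 0)
  r <- render_eye(sc)
  xs <- matrix(rep(1:152, each = 152), 152)
  ys <- matrix(rep(1:152, times = 152), 152)
  d2 <- (xs - 76)^2 + (ys - 76)^2
  inner <- (xs - 76)^2 / 10^2 + (ys - 76)^2 / 10^2 <= 1   # well inside pupil
  annulus <- d2 > 30^2 & d2 < 60^2                        # iris ring
  expect_lt(mean(r$image[inner]), mean(r$image[annulus]))
})

test_that("rendering is bit-identical under a fixed seed", {
  sc <- reference_scene(noise_sd = 8, seed = 99)
  expect_identical(render_eye(sc)$image, render_eye(sc)$image)
})

test_that("invalid scenes are rejected", {
  expect_error(eye_scene(pupil = ellipse_params(76, 76, 80, 40),
                         iris_radius = 60), "beyond the iris")
  expect_error(eye_scene(pupil = ellipse_params(5, 76, 20, 12)),
               "inside the image")
  expect_error(ellipse_params(76, 76, -3, -5), "a >= b > 0")
  expect_error(eye_scene(intensities = c(sclera = 10, iris = 100, pupil = 30)),
               "ordering")
})

test_that("sequences follow the trajectory and validate their inputs", {
  base <- reference_scene(noise_sd = 0)
  tr <- matrix(rep(c(40, 24), each = 5), 5)
  frames <- render_sequence(base, sequence_dynamics(5, tr))
  expect_length(frames, 5)
  for (f in frames) expect_identical(f$image, frames[[1]]$image)

  two <- render_sequence(base, sequence_dynamics(2, tr[1:2, ]))
  expect_length(two, 2)

  expect_error(sequence_dynamics(4, tr), "n_frames x 2")
  expect_error(sequence_dynamics(1, tr[1, , drop = FALSE]), "n_frames >= 2")
  expect_error(sequence_dynamics(2, -tr[1:2, ]), "major >= minor > 0")
})

test_that("constriction sequences lose similarity with frame gap", {
  base <- eye_scene(image_size = 96,
                    pupil = ellipse_params(48, 48, 22, 19, 10),
                    noise_sd = 2, rng_seed = 5)
  dyn <- sequence_dynamics(30, plr_trajectory(30, start = c(44, 38),
                                              end = c(20, 17), rate = 0.1),
                           center_jitter_sd = 0.3)
  frames <- render_sequence(base, dyn)
  ms <- vapply(c(1, 5, 10), function(g) mean_adjacent_ssim(frames, g),
               numeric(1))
  expect_true(all(diff(ms) <= 0))
})

test_that("true area is monotone along a monotone trajectory", {
  tr <- plr_trajectory(12, start = c(44, 38), end = c(20, 17))
  areas <- ellipse_area(tr[, 1] / 2, tr[, 2] / 2)
  expect_true(all(diff(areas) < 0))
})

test_that("rendered pupils are recovered by the fitting pipeline", {
  # round-trip oracle at zero noise over varied scenes
  scenes <- random_eye_scenes(5, image_size = 152, noise_sd = 0,
                              highlight_prob = 0, seed = 31)
  for (sc in scenes) {
    r <- render_eye(sc)
    f <- fit_ellipse(extract_pupil_contour(r$image))
    expect_lt(abs(f$a - r$pupil$a) / r$pupil$a, 0.02)
    expect_lt(abs(f$b - r$pupil$b) / r$pupil$b, 0.02)
  }
})

test_that("eyelid occlusion covers the requested pupil fraction", {
  sc <- eye_scene(image_size = 96, pupil = ellipse_params(48, 48, 18, 15, 0),
                  noise_sd = 0, occlusion_fraction = 0.3)
  r <- render_eye(sc)
  # pupil-dark pixels remaining vs the unoccluded render
  sc0 <- eye_scene(image_size = 96, pupil = ellipse_params(48, 48, 18, 15, 0),
                   noise_sd = 0)
  dark <- function(img) sum(img < 60)
  frac <- 1 - dark(r$image) / dark(render_eye(sc0)$image)
  expect_equal(frac, 0.3, tolerance = 0.05)
})
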