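# Shared fixtures. Everything is generated in code; the trained model used
# by the evaluation and Grad-CAM acceptance checks is built once per run
# and cached in this environment.

.fixture_env <- new.env(parent = emptyenv())

# A clean reference scene (152 px, mildly elliptical pupil).
reference_scene <- function(noise_sd = 0, seed = 1, image_size = 152,
                            pupil = NULL) {
  if (is.null(pupil))
    pupil <- ellipse_params(0.5 * image_size, 0.5 * image_size,
                            a = 20, b = 12, theta = 30)
  eye_scene(image_size = image_size, pupil = pupil, noise_sd = noise_sd,
            rng_seed = seed)
}

# Train the scaled-down shallow Type I model once (input 64, 16 filters,
# 10 epochs per stage) on n_train synthetic images and evaluate on a
# held-out set; cached by (n_train, seed).
train_eval_cached <- function(n_train, seed, n_test = 300) {
  key <- sprintf("fit_%d_%d", n_train, seed)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  ds <- synth_eye_dataset(n_train + n_test, image_size = 64,
                          seed = 1000 + seed)
  train <- pupilsize:::subset_dataset(ds, seq_len(n_train))
  test <- pupilsize:::subset_dataset(ds, n_train + seq_len(n_test))
  spec <- network_preset("K333_C111_D111", filters = 16, input_size = 64)
  fit <- pupilnet(train, spec,
                  pupilnet_control(epochs_per_stage = 10, seed = seed))
  rep_ <- mean_error(predict(fit, test), test)
  out <- list(fit = fit, test = test, report = rep_)
  .fixture_env[[key]] <- out
  out
}
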