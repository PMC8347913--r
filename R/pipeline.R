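# End-to-end pipeline: generate -> build-dataset -> train -> evaluate
# (-> gradcam), driven by a versioned YAML/list config with strict schema
# checking (unknown keys are errors, preventing silent typos in K/C/D).

pipeline_schema <- list(
  top = c("version", "seed", "output_dir", "generate", "dataset", "network",
          "train", "gradcam"),
  generate = c("n", "image_size", "noise_sd", "highlight_prob"),
  dataset = c("train_fraction", "split_order", "target_count", "augmentation"),
  augmentation = c("scale_range", "shift_fraction", "rotation_range",
                   "flip_horizontal", "flip_vertical"),
  network = c("preset", "K", "C", "D", "filters", "input_size", "hidden_units"),
  train = c("n_stages", "learning_rates", "epochs_per_stage", "batch_size"),
  gradcam = c("n_images", "target"))

check_keys <- function(x, section) {
  bad <- setdiff(names(x), pipeline_schema[[section]])
  if (length(bad))
    config_error("unknown key(s) in '%s' config section: %s",
                 section, paste(bad, collapse = ", "))
  x
}

load_pipeline_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) config_error("config file not found: %s", config)
    yaml::read_yaml(config)
  } else if (is.list(config)) config
  else config_error("config must be a file path or a list")
  check_keys(cfg, "top")
  if (!identical(as.integer(cfg$version %||% 1L), 1L))
    config_error("unsupported config version: %s", cfg$version %||% "missing")
  for (s in c("generate", "dataset", "network", "train", "gradcam"))
    if (!is.null(cfg[[s]])) check_keys(cfg[[s]], s)
  if (!is.null(cfg$dataset$augmentation))
    check_keys(cfg$dataset$augmentation, "augmentation")
  if (is.null(cfg$generate$n))
    config_error("config must set generate.n (number of synthetic images)")
  cfg
}

config_hash <- function(cfg) {
  cfg$output_dir <- NULL   # the configuration, not where it lands on disk
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the full pupil-size pipeline
#'
#' Executes the pipeline described by a config (YAML path or list):
#' synthesize a labeled eye-image dataset, build balanced train/test sets,
#' train the configured network, evaluate pooled axis-length and area
#' errors on the held-out set, and optionally write Grad-CAM heatmaps. All
#' artifacts (images + labels CSV, model, evaluation report JSON, run
#' manifest JSON) are written under the output directory, and re-running
#' with the same config and seed reproduces all numeric outputs.
#'
#' @param config Path to a YAML config, or an equivalent named list.
#'   Sections: `generate` (n, image_size, noise_sd), `dataset`
#'   (train_fraction, split_order, target_count, augmentation), `network`
#'   (preset or K/C/D triples, filters, hidden_units), `train` (n_stages,
#'   learning_rates, epochs_per_stage, batch_size), optional `gradcam`
#'   (n_images, target). Unknown keys are rejected.
#' @param output_dir Overrides `output_dir` in the config.
#' @param seed Overrides `seed` in the config; drives every random draw.
#' @param quiet Suppress progress messages.
#' @return A `"run_manifest"` (invisibly): config hash, seed, paths,
#'   network summary, and the evaluation report.
#' @export
run_pipeline <- function(config, output_dir = NULL, seed = NULL,
                         quiet = FALSE) {
  cfg <- load_pipeline_config(config)
  seed <- seed %||% cfg$seed %||% 0L
  out <- output_dir %||% cfg$output_dir %||% tempfile("pupilsize_run_")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  gen <- cfg$generate
  size <- gen$image_size %||% 152L
  say("[generate] rendering %d synthetic eye images (%dx%d)", gen$n, size, size)
  ds <- synth_eye_dataset(gen$n, image_size = size,
                          noise_sd = gen$noise_sd %||% 6,
                          highlight_prob = gen$highlight_prob %||% 0.5,
                          seed = seed)
  data_dir <- file.path(out, "data")
  write_labels(ds, file.path(data_dir, "labels.csv"))

  dcfg <- cfg$dataset %||% list()
  aug <- if (!is.null(dcfg$augmentation)) {
    a <- dcfg$augmentation
    augmentation_config(scale_range = unlist(a$scale_range) %||% c(0.7, 1.3),
                        shift_fraction = a$shift_fraction %||% 0.10,
                        rotation_range = a$rotation_range %||% 30,
                        flip_horizontal = a$flip_horizontal %||% TRUE,
                        flip_vertical = a$flip_vertical %||% TRUE)
  } else augmentation_config()
  split <- split_config(train_fraction = dcfg$train_fraction %||% 0.7,
                        shuffle_seed = seed + 1L,
                        split_order = dcfg$split_order %||% "before_augmentation")
  sets <- build_dataset(ds, aug = aug, split = split,
                        target_count = dcfg$target_count)
  say("[dataset] train %d / test %d images", length(sets$train$images),
      length(sets$test$images))

  ncfg <- cfg$network %||% list()
  spec <- if (!is.null(ncfg$preset))
    network_preset(ncfg$preset, filters = ncfg$filters %||% 32,
                   input_size = ncfg$input_size %||% size,
                   hidden_units = ncfg$hidden_units %||% 0)
  else
    network_spec(K = unlist(ncfg$K) %||% c(3, 3, 3),
                 C = unlist(ncfg$C) %||% c(1, 1, 1),
                 D = unlist(ncfg$D) %||% c(1, 1, 1),
                 filters = ncfg$filters %||% 32,
                 input_size = ncfg$input_size %||% size,
                 hidden_units = ncfg$hidden_units %||% 0)
  if (spec$input_size != size)
    config_error("network input_size (%d) must match generated image size (%d)",
                 spec$input_size, size)
  say("[train] %s | %d parameters | block FOVs %s",
      sprintf("K(%s)C(%s)D(%s)", paste(spec$K, collapse = ","),
              paste(spec$C, collapse = ","), paste(spec$D, collapse = ",")),
      count_parameters(spec),
      paste(effective_fov(spec$K, spec$D), collapse = "/"))

  tcfg <- cfg$train %||% list()
  ctl <- pupilnet_control(
    n_stages = tcfg$n_stages %||% 3,
    learning_rates = unlist(tcfg$learning_rates) %||% c(1e-3, 1e-4, 1e-5),
    epochs_per_stage = tcfg$epochs_per_stage %||% 100,
    batch_size = tcfg$batch_size %||% 128,
    seed = seed + 2L)
  fit <- pupilnet(sets$train, spec = spec, control = ctl)
  model_path <- file.path(out, "model.rds")
  saveRDS(fit, model_path)

  pred <- predict(fit, sets$test)
  report <- mean_error(pred, sets$test)
  report_path <- file.path(out, "report.json")
  jsonlite::write_json(list(mean_error_length = report$mean_error_length,
                            mean_error_area = report$mean_error_area,
                            n_test = report$n, n_train = fit$n_train),
                       report_path, auto_unbox = TRUE, digits = NA)
  say("[evaluate] mean error: length %.3f%% | area %.3f%%",
      report$mean_error_length, report$mean_error_area)

  gc_paths <- character(0)
  if (!is.null(cfg$gradcam)) {
    ng <- min(cfg$gradcam$n_images %||% 4, length(sets$test$images))
    for (i in seq_len(ng)) {
      m <- gradcam(fit, sets$test$images[[i]],
                   target = cfg$gradcam$target %||% "sum")
      p <- file.path(out, sprintf("gradcam_%03d.png", i))
      png::writePNG(m$heatmap, p)
      gc_paths <- c(gc_paths, p)
    }
  }

  manifest <- structure(list(
    config_hash = config_hash(cfg), seed = seed,
    package_version = as.character(utils::packageVersion("pupilsize")),
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    paths = list(output_dir = out, data = data_dir, model = model_path,
                 report = report_path, gradcam = gc_paths),
    network = list(K = spec$K, C = spec$C, D = spec$D,
                   filters = spec$filters,
                   parameters = count_parameters(spec),
                   fov = effective_fov(spec$K, spec$D)),
    evaluation = list(mean_error_length = report$mean_error_length,
                      mean_error_area = report$mean_error_area,
                      n_test = report$n)), class = "run_manifest")
  jsonlite::write_json(unclass(manifest), file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("pupilsize run", x$config_hash, "\n")
  cat("  output:", x$paths$output_dir, "\n")
  cat(sprintf("  network: %d parameters | test mean error %.3f%% (length), %.3f%% (area)\n",
              x$network$parameters, x$evaluation$mean_error_length,
              x$evaluation$mean_error_area))
  invisible(x)
}
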