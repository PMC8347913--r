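#' Labeled pupil-image dataset
#'
#' A lightweight container pairing grayscale images with their pupil labels.
#' The label table carries the full ellipse (center, full axis lengths in
#' pixels, orientation) plus a `source_id` identifying the originating
#' subject/sequence — used for balancing and leakage-free splitting.
#'
#' @param images List of numeric matrices (`[0, 255]`), all the same size.
#' @param labels Data frame with columns `cx, cy, major_px, minor_px,
#'   theta_deg` (and optionally `filename`, `source_id`, `origin`,
#'   `augmented`).
#' @return Object of class `"pupil_dataset"`.
#' @export
pupil_dataset <- function(images, labels) {
  if (length(images) != nrow(labels))
    data_error("images (%d) and labels (%d) differ in length",
               length(images), nrow(labels))
  need <- c("cx", "cy", "major_px", "minor_px", "theta_deg")
  miss <- setdiff(need, names(labels))
  if (length(miss))
    data_error("label table missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(labels) > 0) {
    if (any(labels$minor_px <= 0) || any(labels$major_px < labels$minor_px))
      data_error("labels must satisfy major_px >= minor_px > 0")
    if (is.null(labels$source_id)) labels$source_id <- "s1"
    if (is.null(labels$origin)) labels$origin <- seq_len(nrow(labels))
    if (is.null(labels$augmented)) labels$augmented <- FALSE
  }
  structure(list(images = images, labels = labels,
                 image_size = if (length(images)) dim(images[[1]]) else NULL),
            class = "pupil_dataset")
}

#' @export
print.pupil_dataset <- function(x, ...) {
  cat(sprintf("pupil_dataset: %d images", length(x$images)))
  if (!is.null(x$image_size))
    cat(sprintf(" (%d x %d)", x$image_size[1], x$image_size[2]))
  if (nrow(x$labels) > 0)
    cat(sprintf(", %d source(s), %d augmented",
                length(unique(x$labels$source_id)), sum(x$labels$augmented)))
  cat("\n")
  invisible(x)
}

#' @export
length.pupil_dataset <- function(x) length(x$images)

subset_dataset <- function(ds, idx) {
  pupil_dataset(ds$images[idx], ds$labels[idx, , drop = FALSE])
}

#' Render a labeled synthetic dataset
#'
#' Convenience wrapper over [random_eye_scenes()] and [render_eye()]: draws
#' `n` scenes and returns a [pupil_dataset()] with exact labels. Each scene
#' is its own `source_id` (single images, as in still-image datasets).
#'
#' @inheritParams random_eye_scenes
#' @param ... Passed to [random_eye_scenes()].
#' @return A [pupil_dataset()].
#' @export
synth_eye_dataset <- function(n, image_size = 152, seed = NULL, ...) {
  scenes <- random_eye_scenes(n, image_size = image_size, seed = seed, ...)
  imgs <- vector("list", n)
  lab <- vector("list", n)
  for (i in seq_len(n)) {
    r <- render_eye(scenes[[i]])
    imgs[[i]] <- r$image
    p <- r$pupil
    lab[[i]] <- data.frame(filename = sprintf("eye_%05d.png", i),
                           cx = p$cx, cy = p$cy,
                           major_px = 2 * p$a, minor_px = 2 * p$b,
                           theta_deg = p$theta,
                           source_id = sprintf("scene_%05d", i))
  }
  pupil_dataset(imgs, do.call(rbind, lab))
}

#' Read a labeled dataset from a labels CSV
#'
#' Reads the labels CSV dialect (`filename, cx, cy, major_px, minor_px,
#' theta_deg[, source_id]`) and loads the referenced 8-bit grayscale PNG
#' images from the CSV's directory. An empty CSV yields an empty dataset;
#' missing columns or unreadable images are errors.
#'
#' @param path Path to the labels CSV.
#' @return A [pupil_dataset()].
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) data_error("labels file not found: %s", path)
  lab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("filename", "cx", "cy", "major_px", "minor_px", "theta_deg")
  miss <- setdiff(need, names(lab))
  if (length(miss))
    data_error("labels CSV missing column(s): %s", paste(miss, collapse = ", "))
  dir <- dirname(path)
  imgs <- lapply(lab$filename, function(f) {
    fp <- file.path(dir, f)
    if (!file.exists(fp)) data_error("image not found: %s", fp)
    m <- png::readPNG(fp)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m * 255
  })
  pupil_dataset(imgs, lab)
}

#' Write a labeled dataset to disk
#'
#' Writes every image as an 8-bit grayscale PNG next to a labels CSV at
#' `path`. Round-trips with [read_labels()].
#'
#' @param ds A [pupil_dataset()].
#' @param path Path of the labels CSV to write; images go in its directory.
#' @return `path`, invisibly.
#' @export
write_labels <- function(ds, path) {
  stopifnot(inherits(ds, "pupil_dataset"))
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lab <- ds$labels
  if (is.null(lab$filename) && nrow(lab) > 0)
    lab$filename <- sprintf("eye_%05d.png", seq_len(nrow(lab)))
  for (i in seq_along(ds$images))
    png::writePNG(pmin(pmax(ds$images[[i]], 0), 255) / 255,
                  file.path(dir, lab$filename[i]))
  keep <- intersect(c("filename", "cx", "cy", "major_px", "minor_px",
                      "theta_deg", "source_id"), names(lab))
  utils::write.csv(lab[, keep, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Geometric augmentation configuration
#'
#' Ranges for the augmentation draws applied during dataset building:
#' isotropic scaling 0.7--1.3 (producing different pupil sizes), shifts of
#' up to 10% of the image per axis (the pupil edge may touch or leave the
#' frame), rotations of +/-30 degrees, and horizontal/vertical flips.
#'
#' @param scale_range Length-2 positive numeric, `c(min, max)`.
#' @param shift_fraction Maximum shift per axis as a fraction of image size,
#'   in `[0, 1)`.
#' @param rotation_range Maximum absolute rotation, degrees.
#' @param flip_horizontal,flip_vertical Allow the respective flip (drawn
#'   with probability 1/2 each when allowed).
#' @param fill_value Intensity for exposed borders; `NULL` uses the image
#'   median.
#' @param rng_seed Seed for the augmentation draws.
#' @return Object of class `"augmentation_config"`.
#' @export
augmentation_config <- function(scale_range = c(0.7, 1.3),
                                shift_fraction = 0.10,
                                rotation_range = 30,
                                flip_horizontal = TRUE,
                                flip_vertical = TRUE,
                                fill_value = NULL,
                                rng_seed = NULL) {
  if (length(scale_range) != 2 || any(scale_range <= 0) ||
      scale_range[1] > scale_range[2])
    config_error("scale_range must be positive c(min, max)")
  if (shift_fraction < 0 || shift_fraction >= 1)
    config_error("shift_fraction must lie in [0, 1)")
  if (rotation_range < 0) config_error("rotation_range must be nonnegative")
  structure(list(scale_range = scale_range, shift_fraction = shift_fraction,
                 rotation_range = rotation_range,
                 flip_horizontal = flip_horizontal,
                 flip_vertical = flip_vertical,
                 fill_value = fill_value, rng_seed = rng_seed),
            class = "augmentation_config")
}

#' Sample one augmentation draw
#'
#' @param config An [augmentation_config()].
#' @return List with `scale`, `shift_x`, `shift_y` (fractions of image
#'   size), `rotation` (degrees), `flip_h`, `flip_v`.
#' @export
sample_augmentation_draw <- function(config) {
  list(scale = runif(1, config$scale_range[1], config$scale_range[2]),
       shift_x = runif(1, -config$shift_fraction, config$shift_fraction),
       shift_y = runif(1, -config$shift_fraction, config$shift_fraction),
       rotation = runif(1, -config$rotation_range, config$rotation_range),
       flip_h = config$flip_horizontal && runif(1) < 0.5,
       flip_v = config$flip_vertical && runif(1) < 0.5)
}

# Forward linear map (about the image center) of a draw.
draw_matrix <- function(draw) {
  phi <- draw$rotation * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  Fl <- diag(c(if (draw$flip_h) -1 else 1, if (draw$flip_v) -1 else 1))
  Fl %*% R * draw$scale
}

#' Apply an augmentation draw to an image and its ellipse label
#'
#' The image is warped by the similarity transform (scale, rotation, flips
#' about the image center, then shift) with bilinear interpolation; exposed
#' borders take `fill_value` (image median by default). The label is
#' transformed *consistently*: scaling by `s` multiplies both axis lengths
#' by `s`; rotation, flips and shifts leave the lengths unchanged (they move
#' the center and orientation only). The pupil is allowed to touch or leave
#' the frame.
#'
#' @param image Numeric matrix.
#' @param label An [ellipse_params()] object (the pre-transform pupil).
#' @param draw A draw from [sample_augmentation_draw()].
#' @param fill_value Border fill intensity (`NULL`: image median).
#' @return List with `image` and `label` (transformed [ellipse_params()]).
#' @export
augment_sample <- function(image, label, draw, fill_value = NULL) {
  stopifnot_image(image)
  stopifnot(inherits(label, "ellipse_params"))
  H <- nrow(image); W <- ncol(image)
  M <- draw_matrix(draw)
  shift <- c(draw$shift_x * W, draw$shift_y * H)
  img2 <- warp_affine(image, M, shift = shift, fill = fill_value)

  c0 <- c((W + 1) / 2, (H + 1) / 2)
  ctr <- drop(M %*% (c(label$cx, label$cy) - c0)) + c0 + shift
  theta <- label$theta + draw$rotation
  if (xor(isTRUE(draw$flip_h), isTRUE(draw$flip_v))) theta <- -theta
  lab2 <- ellipse_params(ctr[1], ctr[2],
                         a = label$a * draw$scale, b = label$b * draw$scale,
                         theta = theta)
  list(image = img2, label = lab2)
}

#' Train/test split configuration
#'
#' @param train_fraction Fraction of samples assigned to the training set
#'   (default 0.7 for a 7:3 split); must lie strictly inside `(0, 1)`.
#' @param shuffle_seed Seed for the pre-split shuffle and augmentation draws.
#' @param split_order `"before_augmentation"` (default): the originals are
#'   split first and each side is augmented separately, so no augmented
#'   descendant of a test original can reach the training set.
#'   `"after_augmentation"` reproduces the alternative (leak-prone) order:
#'   augment the whole pool first, then shuffle and split.
#' @return Object of class `"split_config"`.
#' @export
split_config <- function(train_fraction = 0.7, shuffle_seed = NULL,
                         split_order = c("before_augmentation",
                                         "after_augmentation")) {
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1)
    config_error("train_fraction must lie strictly in (0, 1)")
  structure(list(train_fraction = train_fraction, shuffle_seed = shuffle_seed,
                 split_order = match.arg(split_order)),
            class = "split_config")
}

# Augment a dataset up to `target` samples, balancing per-source counts:
# each source is topped up toward ceiling(target / n_sources) by augmenting
# its own originals with fresh draws.
balance_augment <- function(ds, aug, target) {
  n <- length(ds$images)
  if (target <= n) return(ds)
  src <- ds$labels$source_id
  sources <- unique(src)
  quota <- ceiling(target / length(sources))
  new_imgs <- list(); new_lab <- list()
  counts <- table(factor(src, levels = sources))
  for (s in sources) {
    idx <- which(src == s)
    need <- quota - counts[[s]]
    j <- 0
    while (need > 0 && length(new_imgs) + n < target + length(sources)) {
      i <- idx[(j %% length(idx)) + 1]; j <- j + 1
      draw <- sample_augmentation_draw(aug)
      lab <- ds$labels[i, ]
      e <- ellipse_params(lab$cx, lab$cy, lab$major_px / 2, lab$minor_px / 2,
                          lab$theta_deg)
      out <- augment_sample(ds$images[[i]], e, draw, aug$fill_value)
      new_imgs[[length(new_imgs) + 1]] <- out$image
      lab$cx <- out$label$cx; lab$cy <- out$label$cy
      lab$major_px <- 2 * out$label$a; lab$minor_px <- 2 * out$label$b
      lab$theta_deg <- out$label$theta
      lab$origin <- ds$labels$origin[i]
      lab$augmented <- TRUE
      new_lab[[length(new_lab) + 1]] <- lab
      need <- need - 1
    }
  }
  out <- pupil_dataset(c(ds$images, new_imgs),
                       rbind(ds$labels, do.call(rbind, new_lab)))
  # keep originals, trim surplus augmented samples
  if (length(out$images) > target) {
    keep <- c(which(!out$labels$augmented),
              which(out$labels$augmented))[seq_len(target)]
    out <- subset_dataset(out, sort(keep))
  }
  out
}

#' Build balanced, shuffled train/test sets
#'
#' Balances per-source counts via geometric augmentation up to
#' `target_count` images, shuffles, and splits into train/test at
#' `split$train_fraction`. With `split_order = "before_augmentation"` the
#' originals are split first and each side augmented separately (no
#' leakage); with `"after_augmentation"` the pool is augmented before the
#' shuffle and split. Deterministic for fixed seeds.
#'
#' @param ds A [pupil_dataset()] of original samples.
#' @param aug An [augmentation_config()], or `NULL` for no augmentation.
#' @param split A [split_config()].
#' @param target_count Total images after balancing; `NULL` keeps the
#'   original count (no augmentation).
#' @return List with elements `train` and `test` (both [pupil_dataset()]s).
#' @export
build_dataset <- function(ds, aug = augmentation_config(),
                          split = split_config(), target_count = NULL) {
  stopifnot(inherits(ds, "pupil_dataset"))
  n <- length(ds$images)
  if (n < 2) data_error("need at least 2 samples to split")
  if (!is.null(target_count) && target_count < n)
    data_error("target_count (%d) is smaller than the sample count (%d)",
               target_count, n)
  with_preserved_seed(split$shuffle_seed, {
    if (split$split_order == "before_augmentation") {
      perm <- sample.int(n)
      ntr <- max(1L, min(n - 1L, floor(n * split$train_fraction)))
      tr <- subset_dataset(ds, perm[seq_len(ntr)])
      te <- subset_dataset(ds, perm[(ntr + 1L):n])
      if (!is.null(target_count) && !is.null(aug) && target_count > n) {
        tr_target <- round(target_count * split$train_fraction)
        tr <- balance_augment(tr, aug, tr_target)
        te <- balance_augment(te, aug, target_count - tr_target)
      }
      tr <- subset_dataset(tr, sample.int(length(tr$images)))
      te <- subset_dataset(te, sample.int(length(te$images)))
    } else {
      pool <- if (!is.null(target_count) && !is.null(aug))
        balance_augment(ds, aug, target_count) else ds
      np <- length(pool$images)
      perm <- sample.int(np)
      ntr <- max(1L, min(np - 1L, floor(np * split$train_fraction)))
      tr <- subset_dataset(pool, perm[seq_len(ntr)])
      te <- subset_dataset(pool, perm[(ntr + 1L):np])
    }
    list(train = tr, test = te)
  })
}
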