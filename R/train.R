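# Forward/backward passes over the layer list produced by init_network().
# Images travel as (H, W, C, N) arrays; dense activations as (units x N)
# matrices. The cache records what each backward step needs.

net_forward <- function(layers, x, cache = FALSE) {
  records <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    if (l$kind == "conv") {
      # im2col buffers are recomputed in the backward pass: re-deriving them
      # is cheaper than keeping hundreds of MB of fresh pages alive.
      fw <- .conv2d_fwd(x, l$w, l$b, l$d, l$pad, TRUE, FALSE)
      records[[li]] <- if (cache) list(x = x, y = fw$y, im2col = NULL) else NULL
      x <- fw$y
    } else if (l$kind == "pool") {
      mp <- .maxpool2_fwd(x)
      records[[li]] <- if (cache) list(argmax = mp$argmax, in_dim = dim(x)) else NULL
      x <- mp$y
    } else {                       # dense: flatten on first dense layer
      if (!is.matrix(x)) {
        dn <- dim(x)
        x <- matrix(x, nrow = prod(dn[1:3]), ncol = dn[4])
        flat_dim <- dn
      } else flat_dim <- NULL
      z <- l$w %*% x + l$b
      if (isTRUE(l$relu)) z <- pmax(z, 0)
      records[[li]] <- if (cache) list(x = x, y = z, flat_dim = flat_dim) else NULL
      x <- z
    }
  }
  list(out = x, records = records)
}

net_backward <- function(layers, records, dout) {
  grads <- vector("list", length(layers))
  dy <- dout
  for (li in rev(seq_along(layers))) {
    l <- layers[[li]]
    r <- records[[li]]
    if (l$kind == "dense") {
      if (isTRUE(l$relu)) dy <- dy * (r$y > 0)
      grads[[li]] <- list(dw = dy %*% t(r$x), db = rowSums(dy))
      dy <- t(l$w) %*% dy
      if (!is.null(r$flat_dim)) dy <- array(dy, dim = r$flat_dim)
    } else if (l$kind == "pool") {
      dx <- numeric(prod(r$in_dim))
      dx[as.vector(r$argmax)] <- as.vector(dy)
      dy <- array(dx, dim = r$in_dim)
      grads[[li]] <- list()
    } else {
      first_conv <- li == min(which(vapply(layers, function(z) z$kind == "conv",
                                           logical(1))))
      g <- .conv2d_bwd(r$x, l$w, dy, r$y, l$d, l$pad, TRUE,
                       r$im2col, !first_conv)
      grads[[li]] <- list(dw = g$dw, db = g$db)
      dy <- g$dx
    }
  }
  grads
}

adam_init <- function(layers) {
  lapply(layers, function(l)
    if (length(l$w)) list(mw = l$w * 0, vw = l$w * 0,
                          mb = l$b * 0, vb = l$b * 0) else list())
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
  for (li in seq_along(layers)) {
    if (!length(layers[[li]]$w)) next
    g <- grads[[li]]; s <- state[[li]]
    s$mw <- beta1 * s$mw + (1 - beta1) * g$dw
    s$vw <- beta2 * s$vw + (1 - beta2) * g$dw^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    layers[[li]]$w <- layers[[li]]$w - lr * (s$mw / c1) / (sqrt(s$vw / c2) + eps)
    layers[[li]]$b <- layers[[li]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[li]] <- s
  }
  list(layers = layers, state = state)
}

#' Training control parameters
#'
#' The staged schedule: the training set is partitioned into `n_stages`
#' disjoint parts; stage `s` trains only on part `s` (fresh, previously
#' unseen data) for `epochs_per_stage` epochs at `learning_rates[s]`, with
#' the Adam optimizer and mean-squared-error loss on the (internally
#' z-scored) axis lengths. Learning rates must be strictly decreasing; the
#' defaults step geometrically from 1e-3 to 1e-5.
#'
#' @param n_stages Number of training stages.
#' @param learning_rates One strictly decreasing rate per stage.
#' @param epochs_per_stage Epochs within each stage.
#' @param batch_size Mini-batch size (a smaller final batch is allowed).
#' @param seed Integer seed for weight initialization, the stage partition
#'   and batch shuffling.
#' @param verbose Print per-epoch losses.
#' @return Object of class `"pupilnet_control"`.
#' @export
pupilnet_control <- function(n_stages = 3,
                             learning_rates = c(1e-3, 1e-4, 1e-5),
                             epochs_per_stage = 100,
                             batch_size = 128,
                             seed = NULL,
                             verbose = FALSE) {
  if (length(learning_rates) != n_stages)
    config_error("need one learning rate per stage")
  if (n_stages > 1 && any(diff(learning_rates) >= 0))
    config_error("learning rates must be strictly decreasing across stages")
  if (any(c(n_stages, epochs_per_stage, batch_size) < 1))
    config_error("stage/epoch/batch counts must be positive")
  structure(list(n_stages = as.integer(n_stages),
                 learning_rates = learning_rates,
                 epochs_per_stage = as.integer(epochs_per_stage),
                 batch_size = as.integer(batch_size),
                 seed = seed, verbose = isTRUE(verbose)),
            class = "pupilnet_control")
}

# Near-equal disjoint stage partition of shuffled indices.
stage_partition <- function(idx, n_stages) {
  sizes <- rep(length(idx) %/% n_stages, n_stages)
  extra <- length(idx) %% n_stages
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(idx, rep(seq_len(n_stages), times = sizes))
}

dataset_to_array <- function(images) {
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  x <- array(0, dim = c(H, W, 1L, length(images)))
  for (i in seq_along(images)) x[, , 1, i] <- images[[i]] / 255
  x
}

#' Fit a pupil-size regression network
#'
#' Trains a member of the dilated-convolution network family to regress the
#' pupil's full major and minor axis lengths (pixels) from a grayscale eye
#' image. Inputs are scaled to `[0, 1]`; targets are z-scored per output
#' internally (the stored center/scale are undone at prediction time).
#' Training follows the staged schedule of [pupilnet_control()]. The run is
#' deterministic for a fixed `control$seed` on a fixed BLAS.
#'
#' @param x A [pupil_dataset()] training set (images + labels).
#' @param spec A [network_spec()] (or preset via [network_preset()]); its
#'   `input_size` must match the images.
#' @param control A [pupilnet_control()].
#' @return An object of class `"pupilnet"` with `print()`, `summary()`,
#'   `predict()`, `plot()`, `residuals()`, `fitted()` and `coef()` methods.
#' @examples
#' \donttest{
#' ds <- synth_eye_dataset(60, image_size = 48, seed = 1)
#' sets <- build_dataset(ds, aug = NULL, split = split_config(shuffle_seed = 1))
#' fit <- pupilnet(sets$train,
#'                 spec = network_spec(filters = 8, input_size = 48),
#'                 control = pupilnet_control(epochs_per_stage = 2, seed = 1))
#' pred <- predict(fit, sets$test)
#' mean_error(pred, sets$test)
#' }
#' @export
pupilnet <- function(x, spec = network_spec(),
                     control = pupilnet_control()) {
  stopifnot(inherits(x, "pupil_dataset"), inherits(spec, "network_spec"),
            inherits(control, "pupilnet_control"))
  n <- length(x$images)
  if (n == 0) data_error("empty training set")
  if (!all(x$image_size == spec$input_size))
    data_error("images are %dx%d but spec$input_size is %d",
               x$image_size[1], x$image_size[2], spec$input_size)

  xa <- dataset_to_array(x$images)
  y <- t(as.matrix(x$labels[, c("major_px", "minor_px")]))   # 2 x N
  ctr <- rowMeans(y)
  scl <- apply(y, 1, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  yz <- (y - ctr) / scl

  with_preserved_seed(control$seed, {
    layers <- init_network(spec, seed = NULL)
    state <- adam_init(layers)
    parts <- stage_partition(sample.int(n), control$n_stages)
    hist <- list()
    t_adam <- 0
    for (s in seq_len(control$n_stages)) {
      sidx <- parts[[s]]
      if (length(sidx) == 0) next
      lr <- control$learning_rates[s]
      for (ep in seq_len(control$epochs_per_stage)) {
        ord <- sidx[sample.int(length(sidx))]
        bstart <- seq(1, length(ord), by = control$batch_size)
        eploss <- 0
        for (bs in bstart) {
          bi <- ord[bs:min(bs + control$batch_size - 1, length(ord))]
          xb <- xa[, , , bi, drop = FALSE]
          yb <- yz[, bi, drop = FALSE]
          fw <- net_forward(layers, xb, cache = TRUE)
          err <- fw$out - yb
          loss <- mean(err^2)
          grads <- net_backward(layers, fw$records, 2 * err / length(err))
          t_adam <- t_adam + 1
          upd <- adam_step(layers, grads, state, lr, t_adam)
          layers <- upd$layers; state <- upd$state
          eploss <- eploss + loss * length(bi)
        }
        eploss <- eploss / length(sidx)
        hist[[length(hist) + 1]] <- data.frame(stage = s, epoch = ep,
                                               loss = eploss)
        if (control$verbose)
          message(sprintf("stage %d epoch %3d loss %.5f", s, ep, eploss))
      }
    }
    fit <- structure(list(spec = spec, control = control, weights = layers,
                          target_center = ctr, target_scale = scl,
                          history = do.call(rbind, hist),
                          n_train = n, stage_sizes = lengths(parts)),
                     class = "pupilnet")
    fitted_tr <- predict(fit, x)
    fit$fitted.values <- fitted_tr
    fit$train_targets <- t(y)
    fit
  })
}

#' Predict pupil axis lengths
#'
#' @param object A fitted [pupilnet()].
#' @param newdata A [pupil_dataset()], a list of image matrices, or a single
#'   matrix, at the model's input size.
#' @param ... Unused.
#' @return `n x 2` matrix with columns `major_px`, `minor_px` (raw network
#'   outputs; no ordering is enforced — [mean_error()] reorders each pair
#'   before evaluation).
#' @export
predict.pupilnet <- function(object, newdata, ...) {
  imgs <- if (inherits(newdata, "pupil_dataset")) newdata$images
          else if (is.matrix(newdata)) list(newdata)
          else newdata
  if (length(imgs) == 0) data_error("no images to predict")
  sz <- object$spec$input_size
  if (!all(vapply(imgs, function(m) all(dim(m) == c(sz, sz)), logical(1))))
    data_error("prediction images must be %d x %d", sz, sz)
  nb <- 256L  # forward in chunks to bound memory
  out <- matrix(0, length(imgs), 2,
                dimnames = list(NULL, c("major_px", "minor_px")))
  for (bs in seq(1, length(imgs), by = nb)) {
    bi <- bs:min(bs + nb - 1, length(imgs))
    xa <- dataset_to_array(imgs[bi])
    z <- net_forward(object$weights, xa)$out
    out[bi, ] <- t(z * object$target_scale + object$target_center)
  }
  out
}

#' @export
fitted.pupilnet <- function(object, ...) object$fitted.values

#' @export
residuals.pupilnet <- function(object, ...)
  object$train_targets - object$fitted.values

#' @export
coef.pupilnet <- function(object, ...) {
  w <- Filter(function(l) length(l$w) > 0, object$weights)
  lapply(w, function(l) list(kind = l$kind, w = l$w, b = l$b))
}

#' @export
print.pupilnet <- function(x, ...) {
  sp <- x$spec
  cat(sprintf("pupilnet: K(%s) C(%s) D(%s), %d filters, input %dx%d\n",
              paste(sp$K, collapse = ","), paste(sp$C, collapse = ","),
              paste(sp$D, collapse = ","), sp$filters,
              sp$input_size, sp$input_size))
  cat(sprintf("  parameters: %d | block FOVs: %s | maps: %s\n",
              count_parameters(sp),
              paste(effective_fov(sp$K, sp$D), collapse = ", "),
              paste(feature_map_sizes(sp), collapse = " -> ")))
  cat(sprintf("  trained on %d images in %d stage(s) of %d epoch(s); final loss %.5f\n",
              x$n_train, x$control$n_stages, x$control$epochs_per_stage,
              utils::tail(x$history$loss, 1)))
  invisible(x)
}

#' @export
summary.pupilnet <- function(object, ...) {
  res <- residuals(object)
  pct <- abs(res) / object$train_targets * 100
  out <- list(model = object,
              stage_final_loss = tapply(object$history$loss,
                                        object$history$stage, utils::tail, 1),
              train_mean_error_pct = mean(pct))
  class(out) <- "summary.pupilnet"
  out
}

#' @export
print.summary.pupilnet <- function(x, ...) {
  print(x$model)
  cat("  final loss per stage:",
      paste(sprintf("%.5f", x$stage_final_loss), collapse = ", "), "\n")
  cat(sprintf("  training-set mean axis-length error: %.2f%%\n",
              x$train_mean_error_pct))
  invisible(x)
}

#' @export
plot.pupilnet <- function(x, ...) {
  h <- x$history
  graphics::plot(seq_len(nrow(h)), h$loss, type = "l", log = "y",
                 xlab = "epoch (cumulative over stages)",
                 ylab = "training MSE (z-scored targets)", ...)
  bnd <- cumsum(table(h$stage))
  graphics::abline(v = bnd[-length(bnd)] + 0.5, lty = 3)
  invisible(x)
}

#' Pooled percent mean error of predicted axis lengths
#'
#' The headline evaluation metric: the mean over all `2 * N` axis values of
#' `|prediction - truth| / truth * 100` (the major and minor axes are
#' pooled, so `n` equals twice the number of images), plus the ellipse-area
#' percent error, computed per image from semi-axes equal to half the
#' predicted/true lengths (`area = a * b * pi`) and then averaged. Each
#' predicted pair is reordered (larger value first) before comparison,
#' since the raw network outputs carry no ordering constraint.
#'
#' @param predictions `n x 2` matrix of predicted `(major_px, minor_px)`.
#' @param truths `n x 2` matrix of true axis lengths, or a
#'   [pupil_dataset()] whose labels supply them.
#' @return An `"evaluation_report"`: list with `mean_error_length`,
#'   `mean_error_area` (both percent), `n` (number of images) and
#'   `per_image` residual table.
#' @export
mean_error <- function(predictions, truths) {
  if (inherits(truths, "pupil_dataset"))
    truths <- as.matrix(truths$labels[, c("major_px", "minor_px")])
  predictions <- as.matrix(predictions)
  truths <- as.matrix(truths)
  if (nrow(predictions) != nrow(truths))
    data_error("prediction and truth counts differ (%d vs %d)",
               nrow(predictions), nrow(truths))
  if (any(truths <= 0)) data_error("ground-truth axis lengths must be positive")
  p <- cbind(pmax(predictions[, 1], predictions[, 2]),
             pmin(predictions[, 1], predictions[, 2]))
  t_ <- cbind(pmax(truths[, 1], truths[, 2]), pmin(truths[, 1], truths[, 2]))
  len_pct <- abs(p - t_) / t_ * 100
  area_p <- (p[, 1] / 2) * (p[, 2] / 2) * pi
  area_t <- (t_[, 1] / 2) * (t_[, 2] / 2) * pi
  area_pct <- abs(area_p - area_t) / area_t * 100
  structure(list(mean_error_length = mean(len_pct),
                 mean_error_area = mean(area_pct),
                 n = nrow(p),
                 per_image = data.frame(major_err_pct = len_pct[, 1],
                                        minor_err_pct = len_pct[, 2],
                                        area_err_pct = area_pct)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation over %d images (%d axis values):\n", x$n, 2 * x$n))
  cat(sprintf("  mean error, axis length: %.3f%%\n", x$mean_error_length))
  cat(sprintf("  mean error, ellipse area: %.3f%%\n", x$mean_error_area))
  invisible(x)
}
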