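#' Grad-CAM heatmap for a fitted pupil-size network
#'
#' Gradient-weighted activation mapping adapted to regression: the gradient
#' of the chosen output (the sum of both axis outputs, or one of them) is
#' backpropagated to the last convolution layer; each channel's weight is
#' the spatial mean of its gradient, and the map is the ReLU of the
#' weighted channel sum, bilinearly upsampled to the input resolution and
#' min-max normalized when nonconstant. The hot region shows which pixels
#' the network used — for a well-trained model, the pupil.
#'
#' @param model A fitted [pupilnet()].
#' @param image Numeric matrix at the model's input size, `[0, 255]`.
#' @param target `"sum"`, `"major"` or `"minor"`: which output(s) the
#'   channel weights are computed against.
#' @return Object of class `"gradcam_map"`: list with `heatmap`
#'   (nonnegative matrix, input resolution) and `target`.
#' @export
gradcam <- function(model, image, target = c("sum", "major", "minor")) {
  target <- match.arg(target)
  stopifnot(inherits(model, "pupilnet"))
  stopifnot_image(image)
  sz <- model$spec$input_size
  if (!all(dim(image) == c(sz, sz)))
    data_error("gradcam image must be %d x %d", sz, sz)
  layers <- model$weights
  conv_idx <- max(which(vapply(layers, function(l) l$kind == "conv",
                               logical(1))))

  xa <- array(image / 255, dim = c(sz, sz, 1L, 1L))
  fw <- net_forward(layers, xa, cache = TRUE)
  e <- switch(target, sum = c(1, 1), major = c(1, 0), minor = c(0, 1))
  dy <- matrix(e, nrow = 2, ncol = 1)

  for (li in rev(seq_along(layers))) {
    if (li == conv_idx) break
    l <- layers[[li]]; r <- fw$records[[li]]
    if (l$kind == "dense") {
      if (isTRUE(l$relu)) dy <- dy * (r$y > 0)
      dy <- t(l$w) %*% dy
      if (!is.null(r$flat_dim)) dy <- array(dy, dim = r$flat_dim)
    } else if (l$kind == "pool") {
      dx <- numeric(prod(r$in_dim))
      dx[as.vector(r$argmax)] <- as.vector(dy)
      dy <- array(dx, dim = r$in_dim)
    } else {
      g <- .conv2d_bwd(r$x, l$w, dy, r$y, l$d, l$pad, TRUE, r$im2col, TRUE)
      dy <- g$dx
    }
  }

  A <- fw$records[[conv_idx]]$y          # (h, w, F, 1) post-ReLU activations
  dA <- dy                               # gradient at the same activations
  hF <- dim(A)[3]
  wts <- vapply(seq_len(hF), function(c) mean(dA[, , c, 1]), numeric(1))
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (c in seq_len(hF)) cam <- cam + wts[c] * A[, , c, 1]
  cam <- pmax(cam, 0)
  heat <- resize_bilinear(cam, sz, sz)
  heat <- pmax(heat, 0)
  rng <- range(heat)
  if (rng[2] > rng[1]) heat <- (heat - rng[1]) / (rng[2] - rng[1])
  structure(list(heatmap = heat, target = target), class = "gradcam_map")
}

#' @export
print.gradcam_map <- function(x, ...) {
  cat(sprintf("gradcam_map (%d x %d), target = %s, mass fraction > 0: %.2f\n",
              nrow(x$heatmap), ncol(x$heatmap), x$target,
              mean(x$heatmap > 0)))
  invisible(x)
}

#' @export
plot.gradcam_map <- function(x, image = NULL, ...) {
  h <- x$heatmap
  graphics::image(t(h)[, nrow(h):1], col = grDevices::hcl.colors(64, "Inferno"),
                  axes = FALSE, asp = 1, ...)
  invisible(x)
}

#' Centroid of the top-decile heat mass
#'
#' Helper for localization checks: the intensity-weighted centroid of the
#' pixels at or above the 90th percentile of the heatmap.
#'
#' @param map A [gradcam()] result.
#' @return `c(x, y)` in pixel coordinates.
#' @export
gradcam_centroid <- function(map) {
  h <- map$heatmap
  thr <- stats::quantile(h, 0.9, names = FALSE)
  sel <- which(h >= thr, arr.ind = TRUE)
  w <- h[sel]
  if (sum(w) == 0) w <- rep(1, nrow(sel))
  c(x = sum(sel[, 2] * w) / sum(w), y = sum(sel[, 1] * w) / sum(w))
}
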