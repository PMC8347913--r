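#' Structural similarity index between two images
#'
#' Computes
#' \deqn{SSIM(x,y) = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'                       {(\mu_x^2+\mu_y^2+C_1)(\sigma_x^2+\sigma_y^2+C_2)}}
#' where \eqn{\mu}, \eqn{\sigma} and \eqn{\sigma_{xy}} are (population)
#' means, standard deviations and covariance, and \eqn{C_1, C_2} are
#' stabilization constants. In `"global"` mode the formula is applied once
#' to whole-image statistics; in `"windowed"` mode it is averaged over an
#' 11x11 Gaussian-weighted sliding window (sigma 1.5, valid region), the
#' common reference implementation. SSIM equals 1 iff the images are
#' identical.
#'
#' @param x,y Numeric matrices of the same shape, intensities in `[0, L]`.
#' @param L Dynamic range (255 for 8-bit images).
#' @param C1,C2 Stabilization constants; defaults `(0.01 L)^2`, `(0.03 L)^2`.
#' @param mode `"global"` or `"windowed"`.
#' @return Scalar SSIM in `(-1, 1]`.
#' @export
ssim <- function(x, y, L = 255, C1 = (0.01 * L)^2, C2 = (0.03 * L)^2,
                 mode = c("global", "windowed")) {
  mode <- match.arg(mode)
  stopifnot_image(x); stopifnot_image(y)
  if (!all(dim(x) == dim(y)))
    data_error("ssim: image shapes differ (%dx%d vs %dx%d)",
               nrow(x), ncol(x), nrow(y), ncol(y))
  if (C1 <= 0 || C2 <= 0) config_error("SSIM constants must be positive")
  if (mode == "global") {
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    ((2 * mx * my + C1) * (2 * cxy + C2)) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
  } else {
    win <- 11L
    if (min(dim(x)) < win)
      data_error("windowed SSIM needs images at least %d pixels per side", win)
    g <- dnorm(seq(-5, 5), sd = 1.5)
    kern <- outer(g, g); kern <- kern / sum(kern)
    f <- function(m) conv_valid(m, kern)
    mx <- f(x); my <- f(y)
    vx <- f(x * x) - mx^2; vy <- f(y * y) - my^2
    cxy <- f(x * y) - mx * my
    m <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
         ((mx^2 + my^2 + C1) * (vx + vy + C2))
    mean(m)
  }
}

# Valid-region 2-D weighted local sum via the package's conv engine.
conv_valid <- function(m, kern) {
  k <- nrow(kern)
  x <- array(m, dim = c(nrow(m), ncol(m), 1L, 1L))
  w <- array(kern, dim = c(k, k, 1L, 1L))
  y <- .conv2d_fwd(x, w, 0, 1L, 0L, FALSE, FALSE)$y
  matrix(y, nrow = dim(y)[1])
}

#' Mean SSIM of consecutively sampled frames
#'
#' Samples frames `1, 1+interval, 1+2*interval, ...` from an ordered frame
#' list and returns the mean SSIM over consecutive sampled pairs. This is
#' the statistic used to pick a video sampling interval that keeps sampled
#' frames sufficiently dissimilar for training.
#'
#' @param frames List of numeric matrices (ordered video frames), or a list
#'   of `render_eye()`-style lists with an `image` element.
#' @param interval Sampling interval in frames (>= 1, < number of frames).
#' @param ... Passed to [ssim()] (e.g. `mode`).
#' @return Mean SSIM over the sampled adjacent pairs.
#' @export
mean_adjacent_ssim <- function(frames, interval, ...) {
  frames <- lapply(frames, function(f) if (is.list(f)) f$image else f)
  n <- length(frames)
  interval <- as.integer(interval)
  if (interval < 1) config_error("interval must be >= 1")
  if (interval >= n)
    data_error("interval (%d) must be smaller than the number of frames (%d)",
               interval, n)
  idx <- seq(1L, n, by = interval)
  vals <- vapply(seq_len(length(idx) - 1L), function(i)
    ssim(frames[[idx[i]]], frames[[idx[i + 1L]]], ...), numeric(1))
  mean(vals)
}

#' Select the sampling interval closest to a target SSIM
#'
#' Given candidate intervals with their mean adjacent-frame SSIM, returns
#' the interval whose mean SSIM is closest to `target`; ties are broken
#' toward the larger interval (fewer, more dissimilar frames).
#'
#' @param candidates Named numeric vector: names are intervals (frames),
#'   values are mean SSIMs.
#' @param target Target mean SSIM (default 0.7992).
#' @return The selected interval (integer).
#' @export
select_sampling_interval <- function(candidates, target = 0.7992) {
  if (length(candidates) == 0) data_error("no candidate intervals supplied")
  iv <- as.integer(names(candidates))
  if (anyNA(iv)) config_error("candidates must be named by integer intervals")
  d <- abs(as.numeric(candidates) - target)
  tied <- which(d <= min(d) + 1e-9)
  max(iv[tied])
}

#' Sampling-interval report for a frame sequence
#'
#' Evaluates [mean_adjacent_ssim()] at each candidate interval and selects
#' the interval via [select_sampling_interval()]. With a list of sequences,
#' the per-interval mean SSIM is averaged across sequences.
#'
#' @param frames A frame list, or a list of frame lists (multiple sequences).
#' @param intervals Candidate sampling intervals.
#' @param target Target mean SSIM.
#' @param ... Passed to [ssim()].
#' @return A `"sampling_report"`: data frame of intervals and mean SSIMs,
#'   with the chosen interval and target as attributes.
#' @export
sampling_report <- function(frames, intervals = c(10, 15, 20),
                            target = 0.7992, ...) {
  first <- frames[[1]]
  single <- is.matrix(first) || (is.list(first) && is.matrix(first$image))
  seqs <- if (single) list(frames) else frames
  ms <- vapply(intervals, function(iv)
    mean(vapply(seqs, mean_adjacent_ssim, numeric(1), interval = iv, ...)),
    numeric(1))
  names(ms) <- intervals
  rep_df <- data.frame(interval = as.integer(intervals), mean_ssim = ms,
                       row.names = NULL)
  structure(rep_df, class = c("sampling_report", "data.frame"),
            chosen = select_sampling_interval(ms, target), target = target)
}

#' @export
print.sampling_report <- function(x, ...) {
  cat("Frame sampling report (target mean SSIM:",
      attr(x, "target"), ")\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat("chosen interval:", attr(x, "chosen"), "frames\n")
  invisible(x)
}
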