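#' @useDynLib pupilsize, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif dnorm quantile median sd
#' @importFrom utils read.csv write.csv packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr with a fixed RNG seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Condition constructors: the CLI maps these classes to exit codes.
ps_error <- function(class, msg, ...) {
  stop(structure(class = c(class, "pupilsize_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
config_error  <- function(msg, ...) ps_error("pupilsize_config_error", msg, ...)
data_error    <- function(msg, ...) ps_error("pupilsize_data_error", msg, ...)
numeric_error <- function(msg, ...) ps_error("pupilsize_numeric_error", msg, ...)

# Bilinear sampling of a matrix at fractional (x, y) pixel coordinates.
# Convention: img[row, col] has center (x = col, y = row), 1-based.
# Coordinates outside the raster return `fill`, or are clamped to the
# border when `clamp = TRUE` (used for heatmap upsampling).
bilinear_sample <- function(img, x, y, fill = 0, clamp = FALSE) {
  H <- nrow(img); W <- ncol(img)
  if (clamp) {
    x <- pmin(pmax(x, 1), W)
    y <- pmin(pmax(y, 1), H)
  }
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;   fy <- y - y0
  out <- rep(fill, length(x))
  ok <- x >= 1 & x <= W & y >= 1 & y <= H
  if (any(ok)) {
    x0k <- pmin(x0[ok], W - 1L); y0k <- pmin(y0[ok], H - 1L)
    x0k <- pmax(x0k, 1L); y0k <- pmax(y0k, 1L)
    fxk <- x[ok] - x0k; fyk <- y[ok] - y0k
    i00 <- y0k + H * (x0k - 1)
    v <- img[i00]       * (1 - fxk) * (1 - fyk) +
         img[i00 + H]   * fxk       * (1 - fyk) +
         img[i00 + 1]   * (1 - fxk) * fyk +
         img[i00 + H + 1] * fxk     * fyk
    out[ok] <- v
  }
  out
}

# Inverse-mapped affine warp: out(p') = in(Minv (p' - c0 - t) + c0).
warp_affine <- function(img, M, shift = c(0, 0), fill = NULL) {
  H <- nrow(img); W <- ncol(img)
  if (is.null(fill)) fill <- stats::median(img)
  c0 <- c((W + 1) / 2, (H + 1) / 2)
  xq <- rep(seq_len(W), each = H)
  yq <- rep(seq_len(H), times = W)
  Minv <- solve(M)
  px <- xq - c0[1] - shift[1]
  py <- yq - c0[2] - shift[2]
  sx <- Minv[1, 1] * px + Minv[1, 2] * py + c0[1]
  sy <- Minv[2, 1] * px + Minv[2, 2] * py + c0[2]
  matrix(bilinear_sample(img, sx, sy, fill = fill), nrow = H, ncol = W)
}

# Resize by bilinear interpolation (pixel-center aligned).
resize_bilinear <- function(img, H, W) {
  h <- nrow(img); w <- ncol(img)
  xq <- ((seq_len(W) - 0.5) * w / W) + 0.5
  yq <- ((seq_len(H) - 0.5) * h / H) + 0.5
  grid_x <- rep(xq, each = H)
  grid_y <- rep(yq, times = W)
  matrix(bilinear_sample(img, grid_x, grid_y, clamp = TRUE), nrow = H, ncol = W)
}

stopifnot_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0)
    data_error("expected a nonempty numeric matrix image")
}
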