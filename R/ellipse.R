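#' Geometric ellipse parameters
#'
#' Constructs the parameter set describing a pupil ellipse: center, semi-axes
#' and orientation. This is the ground-truth carrier used throughout the
#' package; the regression networks predict the corresponding *full* axis
#' lengths `(2a, 2b)` in pixels (see [axis_lengths()]).
#'
#' Pixel coordinate convention: origin at the top-left, `x` rightward
#' (matrix column), `y` downward (matrix row), pixel centers at integer
#' coordinates (1-based). Orientation `theta` is measured counter-clockwise
#' from the +x axis in degrees and normalized to `[0, 180)`.
#'
#' @param cx,cy Center, in pixels.
#' @param a Semi-major axis, pixels. Must satisfy `a >= b > 0`.
#' @param b Semi-minor axis, pixels.
#' @param theta Orientation in degrees; normalized modulo 180.
#' @return An object of class `"ellipse_params"`.
#' @examples
#' e <- ellipse_params(76, 76, a = 20, b = 12, theta = 30)
#' axis_lengths(e)
#' @export
ellipse_params <- function(cx, cy, a, b, theta = 0) {
  if (!all(is.finite(c(cx, cy, a, b, theta))))
    data_error("ellipse parameters must be finite")
  if (b <= 0 || a < b)
    data_error("ellipse semi-axes must satisfy a >= b > 0 (got a=%g, b=%g)", a, b)
  structure(list(cx = cx, cy = cy, a = a, b = b, theta = theta %% 180),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf("ellipse: center (%.3f, %.3f), semi-axes a=%.3f b=%.3f, theta=%.2f deg\n",
              x$cx, x$cy, x$a, x$b, x$theta))
  invisible(x)
}

#' Full major/minor axis lengths of an ellipse
#'
#' The regression label pair: full axis lengths `(2a, 2b)` in pixels.
#'
#' @param e An [ellipse_params()] object.
#' @return Named numeric vector `c(major_px, minor_px)`.
#' @export
axis_lengths <- function(e) {
  stopifnot(inherits(e, "ellipse_params"))
  c(major_px = 2 * e$a, minor_px = 2 * e$b)
}

#' Ellipse area
#'
#' Area of an ellipse with semi-axes `a` and `b`: `a * b * pi`. The result is
#' symmetric in its arguments.
#'
#' @param a,b Semi-axes in pixels; both must be positive.
#' @return Area in square pixels.
#' @export
ellipse_area <- function(a, b) {
  if (any(a <= 0) || any(b <= 0))
    data_error("ellipse_area: semi-axes must be positive")
  a * b * pi
}

#' Points on an ellipse
#'
#' Samples `n` points on the ellipse boundary at evenly spaced parameter
#' values (useful for fitting tests and plotting).
#'
#' @param e An [ellipse_params()] object.
#' @param n Number of points.
#' @param t0 Parameter offset in radians.
#' @return An `n x 2` matrix with columns `x`, `y`.
#' @export
ellipse_points <- function(e, n = 100, t0 = 0) {
  t <- t0 + seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  th <- e$theta * pi / 180
  x <- e$cx + e$a * cos(t) * cos(th) - e$b * sin(t) * sin(th)
  y <- e$cy + e$a * cos(t) * sin(th) + e$b * sin(t) * cos(th)
  cbind(x = x, y = y)
}

#' Convert geometric ellipse parameters to conic coefficients
#'
#' Returns the coefficients of `A x^2 + B x y + C y^2 + D x + E y + F = 0`,
#' normalized to a unit-norm coefficient vector with `A + C > 0`.
#'
#' @param e An [ellipse_params()] object.
#' @return A named numeric vector of class `"conic"` with elements
#'   `A, B, C, D, E, F`.
#' @export
geometric_to_conic <- function(e) {
  th <- e$theta * pi / 180
  ct <- cos(th); st <- sin(th)
  A <- ct^2 / e$a^2 + st^2 / e$b^2
  C <- st^2 / e$a^2 + ct^2 / e$b^2
  B <- 2 * ct * st * (1 / e$a^2 - 1 / e$b^2)
  D <- -2 * A * e$cx - B * e$cy
  E <- -B * e$cx - 2 * C * e$cy
  F <- A * e$cx^2 + B * e$cx * e$cy + C * e$cy^2 - 1
  normalize_conic(c(A = A, B = B, C = C, D = D, E = E, F = F))
}

normalize_conic <- function(v) {
  v <- v / sqrt(sum(v^2))
  if (v[["A"]] + v[["C"]] < 0) v <- -v
  structure(v, class = "conic")
}

#' Convert conic coefficients to geometric ellipse parameters
#'
#' Closed-form inversion of [geometric_to_conic()], via the eigen
#' decomposition of the quadratic-form matrix. Errors unless the conic is a
#' real ellipse (`B^2 - 4AC < 0` with a positive-definite normalized form).
#'
#' @param conic Numeric vector/list with elements `A, B, C, D, E, F`.
#' @return An [ellipse_params()] object (with `a >= b`, `theta` in `[0,180)`).
#' @export
conic_to_geometric <- function(conic) {
  v <- unlist(conic)[c("A", "B", "C", "D", "E", "F")]
  if (anyNA(v)) data_error("conic must supply coefficients A..F")
  A <- v[1]; B <- v[2]; C <- v[3]; D <- v[4]; E <- v[5]; F <- v[6]
  disc <- B^2 - 4 * A * C
  if (!is.finite(disc) || disc >= 0)
    numeric_error("conic is not an ellipse (B^2 - 4AC = %g >= 0)", disc)
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  ctr <- drop(-0.5 * solve(Q, c(D, E)))
  val <- F - 0.25 * drop(crossprod(c(D, E), solve(Q, c(D, E))))
  eg <- eigen(Q, symmetric = TRUE)
  semis2 <- -val / eg$values
  if (any(semis2 <= 0))
    numeric_error("conic does not describe a real ellipse")
  semis <- sqrt(semis2)
  imaj <- which.max(semis)
  vmaj <- eg$vectors[, imaj]
  theta <- atan2(vmaj[2], vmaj[1]) * 180 / pi
  ellipse_params(ctr[1], ctr[2], max(semis), min(semis), theta %% 180)
}

#' Direct least-squares ellipse fit
#'
#' Fits an ellipse to a 2-D point set by the non-iterative direct
#' least-squares method: the conic coefficients minimize the algebraic
#' residual subject to the ellipse constraint `4AC - B^2 = 1`, solved as a
#' (numerically stabilized, block-partitioned) generalized eigenproblem.
#' The constraint guarantees the result is always an ellipse. Points are
#' centered and isotropically scaled before fitting, and the conic is
#' transformed back, so the fit is translation- and rotation-stable.
#'
#' @param points An `n x 2` matrix (or data frame) of `(x, y)` coordinates;
#'   at least 6 non-collinear points are required.
#' @return Conic coefficients of class `"conic"` (unit norm, `A + C > 0`,
#'   discriminant `B^2 - 4AC < 0`). Use [conic_to_geometric()] to obtain
#'   center/axes/orientation.
#' @references Fitzgibbon, Pilu & Fisher (1999) "Direct least square fitting
#'   of ellipses"; Halir & Flusser (1998) numerically stable variant.
#' @export
fit_ellipse_direct <- function(points) {
  pts <- as.matrix(points)
  if (ncol(pts) != 2 || !is.numeric(pts) || !all(is.finite(pts)))
    data_error("points must be a numeric n x 2 matrix of finite coordinates")
  n <- nrow(pts)
  if (n < 6)
    data_error("ellipse fitting requires at least 6 points (got %d)", n)
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  xc <- pts[, 1] - mx; yc <- pts[, 2] - my
  sv <- svd(cbind(xc, yc), nu = 0, nv = 0)$d
  if (sv[2] < 1e-12 * max(sv[1], 1))
    numeric_error("degenerate (collinear) point configuration")
  s <- sqrt(mean(xc^2 + yc^2) / 2)
  x <- xc / s; y <- yc / s

  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, rep(1, n))
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  eg <- eigen(M)
  vec <- Re(eg$vectors)
  cond <- 4 * vec[1, ] * vec[3, ] - vec[2, ]^2
  ok <- which(cond > 0 & abs(Im(eg$values)) < 1e-8)
  if (length(ok) == 0)
    numeric_error("direct ellipse fit failed: no ellipse eigenvector")
  a1 <- vec[, ok[1]]
  av <- c(a1, drop(Tm %*% a1))   # (A, B, C, D, E, F) in normalized coords

  # undo the normalization x -> (x - mx)/s, y -> (y - my)/s
  A <- av[1] / s^2; B <- av[2] / s^2; C <- av[3] / s^2
  D <- (-2 * av[1] * mx - av[2] * my) / s^2 + av[4] / s
  E <- (-av[2] * mx - 2 * av[3] * my) / s^2 + av[5] / s
  F <- (av[1] * mx^2 + av[2] * mx * my + av[3] * my^2) / s^2 -
       (av[4] * mx + av[5] * my) / s + av[6]
  normalize_conic(c(A = A, B = B, C = C, D = D, E = E, F = F))
}

#' Fit an ellipse to points and return geometric parameters
#'
#' Convenience wrapper: [fit_ellipse_direct()] followed by
#' [conic_to_geometric()].
#'
#' @inheritParams fit_ellipse_direct
#' @return An [ellipse_params()] object.
#' @export
fit_ellipse <- function(points) conic_to_geometric(fit_ellipse_direct(points))

#' Extract the pupil boundary from an eye image
#'
#' Finds the largest connected dark region below an intensity threshold
#' (Otsu's method when `threshold = "auto"`) and returns its boundary as a
#' sub-pixel point set: for every boundary pixel pair (inside, outside
#' 4-neighbor) the position where the intensity crosses the threshold is
#' linearly interpolated. Thresholding and connected components are delegated
#' to \pkg{EBImage}.
#'
#' @param image Numeric matrix with intensities in `[0, 255]` (rows = y,
#'   columns = x).
#' @param threshold Intensity threshold, or `"auto"` for Otsu.
#' @param subpixel If `FALSE`, return boundary pixel centers instead of
#'   interpolated crossings.
#' @return An `n x 2` matrix of `(x, y)` boundary coordinates.
#' @export
extract_pupil_contour <- function(image, threshold = "auto", subpixel = TRUE) {
  stopifnot_image(image)
  if (identical(threshold, "auto")) {
    # Two-stage Otsu: the global threshold separates the bright sclera from
    # the iris+pupil population; re-thresholding that dark sub-population
    # isolates the pupil, the darkest structure.
    t1 <- 255 * EBImage::otsu(image / 255, range = c(0, 1), levels = 256)
    dark <- image[image < t1]
    threshold <- if (length(unique(round(dark))) > 2)
      255 * EBImage::otsu(matrix(dark / 255, ncol = 1),
                          range = c(0, 1), levels = 256)
    else t1
  }
  mask <- image < threshold
  if (!any(mask))
    data_error("no pupil found: no pixels below threshold %.1f", threshold)
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  comp <- lab == which.max(tab)

  H <- nrow(image); W <- ncol(image)
  pts_x <- numeric(0); pts_y <- numeric(0)
  for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
    rows <- seq_len(H); cols <- seq_len(W)
    r2 <- rows + d[1]; c2 <- cols + d[2]
    rok <- r2 >= 1 & r2 <= H; cok <- c2 >= 1 & c2 <= W
    inside <- comp[rok, cok, drop = FALSE]
    outside <- !comp[r2[rok], c2[cok], drop = FALSE]
    hit <- which(inside & outside, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    r <- rows[rok][hit[, 1]]; cc <- cols[cok][hit[, 2]]
    if (subpixel) {
      I1 <- image[cbind(r, cc)]
      I2 <- image[cbind(r + d[1], cc + d[2])]
      t <- (threshold - I1) / (I2 - I1)
      t[!is.finite(t)] <- 0.5
      t <- pmin(pmax(t, 0), 1)
      pts_x <- c(pts_x, cc + t * d[2])
      pts_y <- c(pts_y, r + t * d[1])
    } else {
      pts_x <- c(pts_x, cc)
      pts_y <- c(pts_y, r)
    }
  }
  if (!subpixel) {
    keep <- !duplicated(cbind(pts_x, pts_y))
    pts_x <- pts_x[keep]; pts_y <- pts_y[keep]
  }
  cbind(x = pts_x, y = pts_y)
}
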