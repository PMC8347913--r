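test_that("direct fit recovers a sampled ellipse to near machine precision", {
  e <- ellipse_params(76, 76, a = 20, b = 12, theta = 30)
  f <- fit_ellipse(ellipse_points(e, 12))
  expect_lt(abs(f$cx - e$cx) / e$cx, 1e-6)
  expect_lt(abs(f$cy - e$cy) / e$cy, 1e-6)
  expect_lt(abs(f$a - e$a) / e$a, 1e-6)
  expect_lt(abs(f$b - e$b) / e$b, 1e-6)
  expect_lt(min(abs(f$theta - e$theta), 180 - abs(f$theta - e$theta)), 1e-4)
})

test_that("round trip geometric -> points -> fit holds over random ellipses", {
  set.seed(11)
  for (i in 1:100) {
    e <- ellipse_params(runif(1, -50, 200), runif(1, -50, 200),
                        a = runif(1, 10, 60) + 5, b = runif(1, 5, 14),
                        theta = runif(1, 0, 180))
    f <- fit_ellipse(ellipse_points(e, 40, t0 = runif(1)))
    expect_lt(abs(f$a - e$a) / e$a, 1e-6)
    expect_lt(abs(f$b - e$b) / e$b, 1e-6)
    expect_lt(abs(f$cx - e$cx) / max(abs(e$cx), 1), 1e-6)
    expect_lt(abs(f$cy - e$cy) / max(abs(e$cy), 1), 1e-6)
    if (e$a / e$b > 1.01) {
      dth <- abs(f$theta - e$theta)
      expect_lt(min(dth, 180 - dth), 1e-4)
    }
  }
})

test_that("fitted conic always satisfies the ellipse discriminant", {
  set.seed(12)
  for (i in 1:25) {
    e <- ellipse_params(runif(1, 20, 130), runif(1, 20, 130),
                        a = runif(1, 8, 40) + 2, b = runif(1, 4, 10),
                        theta = runif(1, 0, 180))
    pts <- ellipse_points(e, 10) + matrix(rnorm(20, sd = 0.2), 10, 2)
    cf <- fit_ellipse_direct(pts)
    expect_lt(cf[["B"]]^2 - 4 * cf[["A"]] * cf[["C"]], 0)
  }
})

test_that("fit is invariant under translation and rotation of the points", {
  e <- ellipse_params(0, 0, a = 17, b = 9, theta = 25)
  pts <- ellipse_points(e, 30)
  base <- fit_ellipse(pts)
  # translation
  f1 <- fit_ellipse(sweep(pts, 2, c(-120, 350), "+"))
  expect_equal(f1$a, base$a, tolerance = 1e-9)
  expect_equal(f1$b, base$b, tolerance = 1e-9)
  expect_equal(f1$cx, base$cx - 120, tolerance = 1e-9)
  # rotation by 40 degrees about the origin
  phi <- 40 * pi / 180
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  f2 <- fit_ellipse(t(R %*% t(pts)))
  expect_equal(f2$a, base$a, tolerance = 1e-9)
  expect_equal(f2$b, base$b, tolerance = 1e-9)
  expect_equal((f2$theta - base$theta) %% 180, 40, tolerance = 1e-6)
})

test_that("circle fits report equal semi-axes", {
  t <- seq(0, 2 * pi, length.out = 13)[-13]
  f <- fit_ellipse(cbind(10 * cos(t) + 3, 10 * sin(t) - 7))
  expect_equal(f$a, 10, tolerance = 1e-7)
  expect_equal(f$b, 10, tolerance = 1e-7)
})

test_that("degenerate point sets are rejected", {
  expect_error(fit_ellipse_direct(cbind(1:5, 2 * (1:5))), "at least 6")
  expect_error(fit_ellipse_direct(cbind(1:10, 2 * (1:10) + 3)), "collinear")
  expect_error(fit_ellipse_direct(cbind(c(1, NA, 2, 3, 4, 5), 1:6)), "finite")
})

test_that("conic/geometric conversions invert each other", {
  g <- conic_to_geometric(c(A = 1 / 25, B = 0, C = 1 / 9, D = 0, E = 0, F = -1))
  expect_equal(g$cx, 0, tolerance = 1e-12)
  expect_equal(g$cy, 0, tolerance = 1e-12)
  expect_equal(g$a, 5, tolerance = 1e-12)
  expect_equal(g$b, 3, tolerance = 1e-12)
  expect_equal(g$theta, 0, tolerance = 1e-9)

  e <- ellipse_params(40, 60, 22, 13, 117)
  back <- conic_to_geometric(geometric_to_conic(e))
  expect_equal(back$a, e$a, tolerance = 1e-9)
  expect_equal(back$b, e$b, tolerance = 1e-9)
  expect_equal(back$theta, e$theta, tolerance = 1e-6)
})

test_that("non-ellipse conics are rejected", {
  expect_error(conic_to_geometric(c(A = 1, B = 0, C = -1, D = 0, E = 0, F = -1)),
               "not an ellipse")
  expect_error(conic_to_geometric(c(A = 1, B = 2, C = 1, D = 0, E = 0, F = -1)),
               "not an ellipse")
})

test_that("axis lengths and area follow their definitions", {
  e <- ellipse_params(0, 0, 20, 12)
  expect_equal(unname(axis_lengths(e)), c(40, 24))
  expect_equal(unname(axis_lengths(ellipse_params(0, 0, 5, 5))), c(10, 10))
  expect_equal(ellipse_area(1, 1), pi)
  expect_equal(ellipse_area(2, 3), 6 * pi)
  expect_equal(ellipse_area(2, 3), ellipse_area(3, 2))
  expect_error(ellipse_area(0, 3), "positive")
  # strictly increasing in each argument
  expect_true(ellipse_area(2.1, 3) > ellipse_area(2, 3))
  expect_true(ellipse_area(2, 3.1) > ellipse_area(2, 3))
})

test_that("ellipse area matches a pixel-count estimate of the interior", {
  # brute-force oracle: count supersampled pixel centers inside the ellipse
  set.seed(21)
  for (i in 1:5) {
    a <- runif(1, 10, 35); b <- runif(1, 10, a)
    th <- runif(1, 0, pi)
    g <- seq(-40, 40, by = 0.125)
    X <- outer(g * 0 + 1, g); Y <- outer(g, g * 0 + 1)
    xr <- X * cos(th) + Y * sin(th); yr <- -X * sin(th) + Y * cos(th)
    count_area <- sum((xr / a)^2 + (yr / b)^2 <= 1) * 0.125^2
    expect_equal(ellipse_area(a, b), count_area, tolerance = 0.01)
  }
})

test_that("contour extraction finds the pupil and errors sensibly", {
  r <- render_eye(reference_scene(noise_sd = 0))
  f <- fit_ellipse(extract_pupil_contour(r$image))
  expect_lt(abs(f$a - r$pupil$a) / r$pupil$a, 0.02)
  expect_lt(abs(f$b - r$pupil$b) / r$pupil$b, 0.02)

  expect_error(extract_pupil_contour(matrix(250, 50, 50), threshold = 100),
               "no pupil found")

  rn <- render_eye(reference_scene(noise_sd = 5, seed = 4))
  expect_gte(nrow(extract_pupil_contour(rn$image)), 20)
})
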