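#' Synthetic eye scene description
#'
#' Parameters of a rendered eye image: a dark elliptical pupil inside an iris
#' disc on a bright sclera background, optional specular highlight, optional
#' eyelid occlusion, and additive Gaussian sensor noise. The renderer
#' produces images with *exact* ellipse ground truth, emulating the
#' statistical structure of near-infrared eye-tracker imagery (dark pupil,
#' mid-gray iris, bright sclera) so that labeling, augmentation and network
#' training are testable without any external dataset.
#'
#' @param image_size Pixels per side (square image). Default 152.
#' @param pupil An [ellipse_params()] object; defaults to a mildly elliptical
#'   pupil at the image center.
#' @param iris_radius Iris radius in pixels (concentric with the pupil).
#' @param intensities Named vector `c(sclera=, iris=, pupil=)` in `[0, 255]`;
#'   must satisfy pupil < iris < sclera.
#' @param noise_sd Additive Gaussian noise SD, intensity units.
#' @param highlight Optional specular highlight: `list(cx=, cy=, radius=,
#'   intensity=)`, or `NULL`.
#' @param occlusion_fraction Fraction of the pupil covered from above by a
#'   synthetic eyelid (horizontal chord), in `[0, 1)`. Default 0: only
#'   images with complete pupils are generated, matching the usual dataset
#'   curation rule for pupillometry.
#' @param rng_seed Integer seed making the render bit-reproducible; `NULL`
#'   uses (and advances) the ambient RNG.
#' @return An object of class `"eye_scene"`.
#' @export
eye_scene <- function(image_size = 152,
                      pupil = ellipse_params(image_size / 2, image_size / 2,
                                             a = 0.16 * image_size,
                                             b = 0.13 * image_size, theta = 0),
                      iris_radius = 0.45 * image_size,
                      intensities = c(sclera = 200, iris = 100, pupil = 30),
                      noise_sd = 6,
                      highlight = NULL,
                      occlusion_fraction = 0,
                      rng_seed = NULL) {
  stopifnot(inherits(pupil, "ellipse_params"))
  it <- intensities[c("sclera", "iris", "pupil")]
  if (anyNA(it)) config_error("intensities must name sclera, iris and pupil")
  if (!(it["pupil"] < it["iris"] && it["iris"] < it["sclera"]))
    config_error("intensity ordering violated: need pupil < iris < sclera")
  if (occlusion_fraction < 0 || occlusion_fraction >= 1)
    config_error("occlusion_fraction must lie in [0, 1)")
  if (noise_sd < 0) config_error("noise_sd must be nonnegative")
  if (pupil$a > iris_radius)
    data_error("pupil (a=%.1f) extends beyond the iris (radius %.1f)",
               pupil$a, iris_radius)
  if (occlusion_fraction == 0) {
    ext <- ellipse_extent(pupil)
    if (pupil$cx - ext[1] < 0.5 || pupil$cx + ext[1] > image_size + 0.5 ||
        pupil$cy - ext[2] < 0.5 || pupil$cy + ext[2] > image_size + 0.5)
      data_error("pupil ellipse must lie fully inside the image")
  }
  structure(list(image_size = as.integer(image_size), pupil = pupil,
                 iris_radius = iris_radius, intensities = it,
                 noise_sd = noise_sd, highlight = highlight,
                 occlusion_fraction = occlusion_fraction, rng_seed = rng_seed),
            class = "eye_scene")
}

# Half-width and half-height of an ellipse's axis-aligned bounding box.
ellipse_extent <- function(e) {
  th <- e$theta * pi / 180
  c(sqrt((e$a * cos(th))^2 + (e$b * sin(th))^2),
    sqrt((e$a * sin(th))^2 + (e$b * cos(th))^2))
}

box_downsample <- function(m, ss) {
  n <- nrow(m) / ss
  r1 <- matrix(colMeans(matrix(m, nrow = ss)), nrow = n)      # rows averaged
  t(matrix(colMeans(matrix(t(r1), nrow = ss)), nrow = n))     # cols averaged
}

#' Render a synthetic eye image
#'
#' Rasterizes an [eye_scene()] with supersampled anti-aliasing (4x
#' oversampling followed by box down-sampling, so ellipse edges have
#' sub-pixel coverage values as in real imagery), adds Gaussian noise and
#' clips to `[0, 255]`. Deterministic for a fixed `rng_seed`.
#'
#' @param scene An [eye_scene()] object.
#' @param supersample Oversampling factor for anti-aliasing.
#' @return A list with elements `image` (numeric matrix, `[0, 255]`) and
#'   `pupil` (the exact [ellipse_params()] ground truth).
#' @export
render_eye <- function(scene, supersample = 4L) {
  stopifnot(inherits(scene, "eye_scene"))
  with_preserved_seed(scene$rng_seed, render_eye_impl(scene, supersample))
}

render_eye_impl <- function(scene, ss) {
  n <- scene$image_size
  it <- scene$intensities
  u <- (seq_len(n * ss) - 0.5) / ss + 0.5   # supersampled pixel-center coords
  X <- matrix(u, nrow = n * ss, ncol = n * ss, byrow = TRUE)
  Y <- matrix(u, nrow = n * ss, ncol = n * ss)
  p <- scene$pupil
  img <- matrix(it["sclera"], n * ss, n * ss)

  dx <- X - p$cx; dy <- Y - p$cy
  img[dx^2 + dy^2 <= scene$iris_radius^2] <- it["iris"]

  th <- p$theta * pi / 180
  xr <- dx * cos(th) + dy * sin(th)
  yr <- -dx * sin(th) + dy * cos(th)
  inpupil <- (xr / p$a)^2 + (yr / p$b)^2 <= 1
  img[inpupil] <- it["pupil"]

  if (!is.null(scene$highlight)) {
    h <- scene$highlight
    img[(X - h$cx)^2 + (Y - h$cy)^2 <= h$radius^2] <- h$intensity
  }
  if (scene$occlusion_fraction > 0) {
    ylid <- stats::quantile(Y[inpupil], probs = scene$occlusion_fraction,
                            names = FALSE)
    img[Y <= ylid] <- it["sclera"]   # skin-bright eyelid chord from the top
  }
  out <- box_downsample(img, ss)
  if (scene$noise_sd > 0)
    out <- out + matrix(rnorm(n * n, sd = scene$noise_sd), n, n)
  list(image = pmin(pmax(out, 0), 255), pupil = scene$pupil)
}

#' Pupil dynamics for a synthetic frame sequence
#'
#' @param n_frames Number of frames (at least 2).
#' @param axis_trajectory `n_frames x 2` matrix of full (major, minor) axis
#'   lengths in pixels; every row must satisfy `major >= minor > 0`.
#' @param center_jitter_sd Per-frame Gaussian jitter of the pupil center,
#'   pixels.
#' @param noise_sd Per-frame additive noise SD; `NULL` keeps the base
#'   scene's value.
#' @return An object of class `"sequence_dynamics"`.
#' @export
sequence_dynamics <- function(n_frames, axis_trajectory,
                              center_jitter_sd = 0, noise_sd = NULL) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 2) config_error("a sequence needs n_frames >= 2")
  tr <- as.matrix(axis_trajectory)
  if (nrow(tr) != n_frames || ncol(tr) != 2)
    config_error("axis_trajectory must be an n_frames x 2 matrix (got %d x %d)",
                 nrow(tr), ncol(tr))
  if (any(tr <= 0) || any(tr[, 1] < tr[, 2]))
    config_error("axis trajectory must have major >= minor > 0 at every frame")
  structure(list(n_frames = n_frames, axis_trajectory = tr,
                 center_jitter_sd = center_jitter_sd, noise_sd = noise_sd),
            class = "sequence_dynamics")
}

#' Exponential pupillary-constriction trajectory
#'
#' Full axis lengths decaying exponentially from `start` toward `end`, a
#' smooth stand-in for a pupillary light reflex recorded on video.
#'
#' @param n_frames Number of frames.
#' @param start,end Full `(major, minor)` axis lengths at t = 0 and the
#'   asymptote, pixels.
#' @param rate Decay rate per frame.
#' @return `n_frames x 2` matrix of axis lengths.
#' @export
plr_trajectory <- function(n_frames, start = c(44, 38), end = c(22, 19),
                           rate = 0.08) {
  t <- seq_len(n_frames) - 1
  decay <- exp(-rate * t)
  cbind(end[1] + (start[1] - end[1]) * decay,
        end[2] + (start[2] - end[2]) * decay)
}

#' Render a synthetic eye-image sequence
#'
#' Renders `dyn$n_frames` frames whose pupil follows the axis trajectory,
#' with optional per-frame center jitter and noise. Adjacent frames differ
#' only by the trajectory step, jitter and noise — mimicking consecutive
#' eye-tracker video frames.
#'
#' @param base An [eye_scene()] providing everything but the per-frame pupil.
#' @param dyn A [sequence_dynamics()] object.
#' @return List of length `n_frames`; each element has `image` and `pupil`
#'   as in [render_eye()].
#' @export
render_sequence <- function(base, dyn) {
  stopifnot(inherits(base, "eye_scene"), inherits(dyn, "sequence_dynamics"))
  noise <- dyn$noise_sd %||% base$noise_sd
  with_preserved_seed(base$rng_seed, {
    lapply(seq_len(dyn$n_frames), function(i) {
      jit <- if (dyn$center_jitter_sd > 0) rnorm(2, sd = dyn$center_jitter_sd)
             else c(0, 0)
      pup <- ellipse_params(base$pupil$cx + jit[1], base$pupil$cy + jit[2],
                            a = dyn$axis_trajectory[i, 1] / 2,
                            b = dyn$axis_trajectory[i, 2] / 2,
                            theta = base$pupil$theta)
      sc <- base
      sc$pupil <- pup
      sc$noise_sd <- noise
      sc$rng_seed <- NULL        # consume the ambient (seeded) stream
      render_eye(sc)
    })
  })
}

#' Sample randomized synthetic eye scenes
#'
#' Draws `n` scenes with varied pupil size/eccentricity/orientation, iris
#' radius, intensity levels and optional specular highlights. These defaults
#' define the synthetic study conditions used by the package's experiments:
#' pupil semi-major axis 12--30% of the image size, axis ratio 0.7--1,
#' uniform orientation, center within +/-8% of the image center, and
#' near-infrared-like intensity levels.
#'
#' @param n Number of scenes.
#' @param image_size Pixels per side.
#' @param noise_sd Additive noise SD (intensity units).
#' @param highlight_prob Probability a scene carries a specular highlight.
#' @param seed Integer seed; the scene draw and each scene's render seed are
#'   derived from it.
#' @return List of [eye_scene()] objects.
#' @export
random_eye_scenes <- function(n, image_size = 152, noise_sd = 6,
                              highlight_prob = 0.5, seed = NULL) {
  with_preserved_seed(seed, {
    lapply(seq_len(n), function(i) {
      s <- image_size
      a <- runif(1, 0.12, 0.30) * s
      b <- a * runif(1, 0.7, 1)
      cx <- s / 2 + runif(1, -0.08, 0.08) * s
      cy <- s / 2 + runif(1, -0.08, 0.08) * s
      theta <- runif(1, 0, 180)
      iris <- max(runif(1, 0.38, 0.48) * s, a + 2)
      hl <- NULL
      if (runif(1) < highlight_prob) {
        ang <- runif(1, 0, 2 * pi); rad <- runif(1, 0, 0.5) * b
        hl <- list(cx = cx + rad * cos(ang), cy = cy + rad * sin(ang),
                   radius = runif(1, 0.03, 0.08) * s, intensity = 250)
      }
      eye_scene(image_size = s,
                pupil = ellipse_params(cx, cy, a = a, b = b, theta = theta),
                iris_radius = iris,
                intensities = c(sclera = runif(1, 170, 220),
                                iris = runif(1, 80, 130),
                                pupil = runif(1, 15, 45)),
                noise_sd = noise_sd, highlight = hl,
                rng_seed = sample.int(.Machine$integer.max, 1))
    })
  })
}
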