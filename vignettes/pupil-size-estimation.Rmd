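---
title: "Estimating pupil size with small dilated-convolution networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating pupil size with small dilated-convolution networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilsize)
```

## The problem

Pupil size — the major and minor axis lengths of the pupil ellipse, in
pixels — is a clinically useful signal: the pupillary light reflex (PLR)
reflects retinal, optic-nerve and brainstem function, and abnormal or
asymmetric responses accompany glaucoma, diabetic retinopathy and several
central disorders. Measuring it from near-infrared eye-tracker images
usually relies on rule-based segmentation; **pupilsize** instead trains a
very small convolutional network that maps a grayscale eye image directly
to the two axis lengths, small enough to run in real time on embedded
hardware. The package covers the entire workflow: synthesizing labeled eye
images, deriving ellipse ground truth by direct least-squares fitting,
choosing a video sampling interval by structural similarity, building
augmented train/test sets, fitting and evaluating the network family, and
inspecting a trained model with Grad-CAM.

Everything runs on synthetic imagery with exact ground truth, so every
stage is testable without downloading eye-tracking datasets.

## Conventions

Images are numeric matrices in `[0, 255]` with rows = y (downward),
columns = x (rightward), and pixel centers at integer 1-based
coordinates. Ellipse orientation is degrees counter-clockwise from +x,
normalized to `[0, 180)`. The regression label is the pair of *full* axis
lengths `(2a, 2b)` in pixels — "pixels on the major and minor axes" — and
the area formula `a b π` is applied to the half-lengths. These conventions
are fixed across the renderer, the fitter, augmentation and the network.

## The synthetic eye model

`eye_scene()` describes a dark elliptical pupil concentric with a mid-gray
iris disc on a bright sclera, with optional specular highlight and eyelid
chord, plus additive Gaussian sensor noise. Rendering uses 4x supersampled
anti-aliasing (box down-sampling), so ellipse edges carry sub-pixel
coverage values — the property that makes ellipse fitting on real imagery
nontrivial. `random_eye_scenes()` fixes the study conditions used by the
package's experiments:

* pupil semi-major axis 12–30% of the image side, axis ratio 0.7–1,
  uniform orientation, center within ±8% of the image center;
* iris radius 38–48% of the image side;
* intensity levels: pupil 15–45, iris 80–130, sclera 170–220 (8-bit);
* additive noise SD 6; a specular highlight near the pupil in half of the
  scenes.

These are realistic stand-ins chosen once: the source imagery this
emulates is described only qualitatively in the pupillometry literature
(no published noise or illumination statistics), so the defaults encode a
typical near-infrared contrast ordering (pupil darkest, sclera brightest)
and pupil sizes in the range eye trackers encounter. What the synthetic
data does *not* contain: eyelashes, glasses reflections, makeup, off-axis
gaze distortion, motion blur, or inter-subject texture variation. Passing
the package's tests therefore demonstrates the correctness of the
pipeline's machinery on images with this statistical structure, not
performance on any real dataset.

`render_sequence()` produces video-like frame stacks whose pupil follows a
smooth trajectory (`plr_trajectory()` gives an exponential constriction
toward an asymptote, mimicking a light reflex), with optional per-frame
center jitter — the input for the frame-sampling stage.

## Ground-truth labeling by direct least-squares fitting

`extract_pupil_contour()` thresholds the image (two-stage Otsu by default:
the first threshold separates the sclera, the second isolates the pupil
within the dark sub-population), keeps the largest connected dark
component, and interpolates the threshold crossing along every boundary
pixel pair, giving sub-pixel contour points. `fit_ellipse_direct()` then
solves the non-iterative direct least-squares problem with the ellipse
constraint `4AC − B² = 1` in its numerically stable block-partitioned
form, after centering and isotropically scaling the points (the conic is
transformed back afterwards). The constraint guarantees an ellipse for any
admissible input; fewer than 6 points or a centered design whose smallest
singular value is below 1e-12 is rejected as degenerate.

On noiseless renders the full round trip (render → contour → fit) recovers
the axis lengths to a few tenths of a percent, well inside the 2%
tolerance the tests assert; on noiseless *augmented* images (bilinear
resampling) the contract is 3%.

## Frame sampling by structural similarity

Consecutive video frames are nearly identical, and training on all of them
invites overfitting. `ssim()` implements the structural similarity index

$$\mathrm{SSIM}(x,y)=\frac{(2\mu_x\mu_y+C_1)(2\sigma_{xy}+C_2)}
{(\mu_x^2+\mu_y^2+C_1)(\sigma_x^2+\sigma_y^2+C_2)}$$

with \(C_1=(0.01L)^2\), \(C_2=(0.03L)^2\), \(L=255\) — the standard
stabilization constants, since the index's definition calls them only
"constants". The default mode applies the formula once to whole-image
(population) statistics, which is the literal reading of the formula; a
`windowed` mode (11×11 Gaussian window, σ = 1.5, averaged over the valid
region) is provided because SSIM averages reported in the eye-tracking
literature are often computed with the windowed implementation.
`mean_adjacent_ssim()` averages the index over consecutive sampled pairs
at a candidate interval, and `select_sampling_interval()` picks the
interval whose mean is closest to the target 0.7992, breaking ties toward
the larger interval (fewer, more dissimilar frames). With reference
per-interval means of {10: 0.8406, 15: 0.8090, 20: 0.7781} this selects a
15-frame interval. A per-interval "average SSIM" could in principle pool
adjacent pairs, whole videos or both; this implementation averages over
adjacent sampled pairs of one sequence and `sampling_report()` averages
that statistic across sequences.

## Dataset assembly and augmentation

`augmentation_config()` encodes the geometric augmentation ranges:
isotropic scale 0.7–1.3, shifts up to 10% of the image per axis, rotation
±30°, horizontal and vertical flips. One deliberate correction: a
similarity transform that scales the image by `s` *must* scale a
pixel-length label by `s`; treating augmented labels as unchanged is
geometrically impossible for scaling. `augment_sample()` therefore
transforms labels consistently (scale multiplies both lengths; rotation,
flips and shifts move only center and orientation), and the label-contract
test re-fits augmented images to verify it. Shifted pupils may touch or
leave the frame by design; exposed borders are filled with the image
median, and interpolation is bilinear.

`build_dataset()` balances per-source counts by augmenting each source
toward an equal share of `target_count`, shuffles, and splits 7:3. The
default split order is `before_augmentation`: the originals are split
first and each side is augmented separately, so no augmented descendant of
a test original can appear in training — splitting after augmentation
lets the model peek at test data through near-duplicates. The
`after_augmentation` mode reproduces that alternative order for
comparison, and a membership audit in the tests demonstrates the
difference.

## The network family

`network_spec()` describes three convolution blocks (kernel size, layer
count and dilation rate per block), each followed by a 2×2 max-pool, then
a flatten and a 2-output linear head. The nine named presets span three
depths — shallow `C(1,1,1)`, middle `C(4,2,1)`, deep `C(8,4,2)` — and
three filter types: Type I regular `K(3,3,3) D(1,1,1)`, Type II dilated
`K(3,3,3) D(3,2,1)`, and Type III regular `K(7,5,3) D(1,1,1)`, whose
kernels span the same effective fields of view as Type II
(`effective_fov(k, d) = k + (k−1)(d−1)`, so 7/5/3). Dilation widens the
field of view at constant parameter count — `count_parameters()` is
provably independent of `D`. With 32 filters and 152-px inputs the maps
shrink 152 → 76 → 38 → 19 ("same" zero padding keeps each block
size-preserving; the padding mode is an assumption, chosen to make that
progression exact).

Design choices where the design was genuinely open:

* **Loss.** The family's definition fixes no loss function; mean squared
  error on the two axis lengths is the standard choice for coordinate
  regression and is used here. The percent mean error is the
  *evaluation* metric, not the loss.
* **Head.** The architecture diagrams do not describe the head; a flatten
  plus a single 2-output linear layer is used, with an optional hidden
  dense layer behind a config switch.
* **Target scaling.** Targets are z-scored per output during training and
  un-scaled at prediction time — standard regression-network practice
  that makes the MSE landscape independent of image resolution.
* **Output ordering.** Raw outputs are not constrained to major ≥ minor;
  `mean_error()` reorders each predicted pair before comparison, since no
  ordering mechanism exists in a linear head.
* **Stage schedule.** The training set is partitioned into three disjoint
  parts and stage `s` trains only on part `s` ("fresh data per stage", the
  reading consistent with each stage's data being previously unknown),
  with learning rates stepping geometrically 1e-3 → 1e-4 → 1e-5, batch
  size 128, Adam, 100 epochs per stage at full scale.
* **Initialization.** He-normal for ReLU convolutions, Glorot-uniform for
  dense layers, deterministic under the control seed.

The convolution engine itself (dilated same-padding convolution via
im2col + GEMM, 2×2 max-pooling with argmax bookkeeping, Adam) is
implemented in compiled code inside the package; gradients are verified
against finite differences in the test suite.

## Evaluation

`mean_error()` pools both axes: the mean over all `2N` axis values of
`|prediction − truth| / truth × 100`. Written without the absolute
value, positive and negative deviations cancel and the statistic is
meaningless, so the absolute value is part of the definition here. The area error applies
`a b π` per image to half the predicted and true lengths and averages the
percent deviations; per-image aggregation is the only reading that
defines a statistic on data (deriving it from the pooled length error
does not reproduce any consistent quantity).

## Grad-CAM for regression

`gradcam()` backpropagates the gradient of a chosen output (sum of both
axes by default) to the last convolution layer, weights each channel by
the spatial mean of its gradient, and returns the ReLU of the weighted
channel sum, bilinearly upsampled to the input resolution and min-max
normalized when nonconstant. For a trained model the top-decile heat mass
should sit on the pupil; the acceptance suite checks that its centroid
falls inside the true pupil bounding box for at least 70% of held-out
synthetic images.

## Problem sizes used by the experiments

At full scale this family is meant for corpora of tens of thousands of
152×152-pixel images and 3×100-epoch schedules; the package's own
experiments are deliberately desk-scale so that the full suite runs on
one CPU:

* training experiment: shallow Type I with 16 filters on 64-px synthetic
  images, 2,000 training / 300 held-out images, 10 epochs per stage,
  seeds 0–2 (the pooled axis error lands near 12%, and grows when the
  training set shrinks to 200 images);
* capacity comparison: shallow vs middle Type I with 8 filters on 48-px
  images, 600 training images, 5 epochs per stage;
* everything else (fitting, SSIM, augmentation, I/O) runs on images of
  32–152 px in seconds.

Error rates reported for full-scale training on real eye-tracking
datasets are properties of those datasets and compute budgets and are out
of scope here; the package
reproduces the *machinery* and its internal consistency, with the scaled
experiments checking the qualitative claims (training works; more data
helps; depth helps; dilation is parameter-free widening; the network
looks at the pupil).

## Known limitations

* The renderer is a contrast model, not a photorealistic eye; conclusions
  about real-data accuracy require real labeled imagery read through
  `read_labels()`.
* `extract_pupil_contour()` assumes the pupil is the largest dark
  component; strong specular highlights inside the pupil or heavy eyelid
  occlusion degrade the fit (robust occlusion-aware fitting is out of
  scope).
* Training determinism is exact for a fixed seed on a fixed BLAS; across
  different BLAS builds results agree only statistically.
* Video container decoding is not included: sequences are directories of
  numbered PNG frames.
* Pupillometry studies sometimes quote a "non-circularity" index for
  pupils; no standard formula for it exists, so the package reports axis
  lengths, eccentricity-free area and orientation instead of implementing
  an ad hoc index.
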