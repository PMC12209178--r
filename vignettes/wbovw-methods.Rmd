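---
title: "Weighted bag-of-visual-words texture classification: models, parameters and design choices"
author: "wbovw package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted bag-of-visual-words texture classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbovw)
```

## The problem

Early prediction of fetal growth restriction (FGR) from placental
ultrasound is, at its core, a small-sample texture classification problem:
a sonographer marks a circular region of interest (clinically a 2 cm
circle near the cord insertion), and the question is whether its local
texture is dominated by dot-like primitives (healthy) or short rod-like
primitives (FGR). Cohorts are small — on the order of 40 cases per class —
so the pipeline is built entirely from components that behave well at that
scale: hand-crafted local descriptors, a generative vocabulary, and
shallow classifiers with closed-form or convex fits.

This vignette documents the model as implemented, every tunable that
matters, the numerical choices, and what the synthetic test bed does and
does not establish about clinical data.

## Pipeline and assumptions

### Preprocessing

The circular ROI is cropped to its bounding square with a companion
boolean mask; everything outside the circle is zeroed and excluded from
all later statistics, so the artificial circle edge can never contribute
gradients or histogram mass.

* **Wavelet denoising** (`denoise_wavelet`): a 2-level separable Haar
  decomposition with soft thresholding at the universal threshold
  `sigma * sqrt(2 log n)`, where `sigma` is the median absolute deviation
  of the finest diagonal band divided by 0.6745. Haar was chosen as the
  simplest orthogonal family that is exactly invertible on the dyadic grid
  and needs no tuning; the procedure is fully parameter-free and
  deterministic.
* **Histogram equalization** (`equalize_hist`): 256-bin CDF mapping
  accumulated over masked-in pixels only. The mapping is monotone, so
  pixel rank order — and hence the sign structure of gradients — is
  preserved.

### Keypoint detection

`detect_keypoints` builds a Gaussian pyramid (`n_octaves = 4`, `s = 3`
intervals, `sigma0 = 1.6`, `k = 2^(1/3)`; the canonical
difference-of-Gaussians settings) and takes strict 26-neighbor extrema of
the DoG stack with `|D| >= contrast_threshold` (default 0.01 on [0, 1]
images). Three deliberate restrictions:

* **Strict extrema**: ties are rejected, so plateaus (constant regions)
  yield no keypoints. This makes the detector's output exactly equal to an
  exhaustive 26-neighbor scan, which the test suite asserts on random
  stacks.
* **No edge-response test and no sub-pixel refinement**: detection is
  plain extremum detection at integer positions, keeping the detector a
  minimal, fully specified procedure. The contrast threshold is the only
  rejection rule and is exposed in `scale_space_params()`.
* **Kernel support**: the Gaussian kernel is sampled at integer offsets
  with half-width `ceiling(3 * sigma)` and normalized to sum to 1, with
  symmetric reflection at borders; a constant image is therefore
  reproduced to machine precision.

A practical note on scale coverage: a blob only produces an interior 3-D
extremum if its intrinsic scale falls inside the sampled sigma range.
Structures much smaller than `sigma0` peak at the first DoG level, which
has no scale neighbor below, and are invisible to the detector. The
speckled textures this pipeline targets have their energy well inside the
sampled range.

Keypoints whose descriptor window would cross the image border or leave
the ROI mask are dropped at detection time, so every surviving keypoint is
describable. The experiment driver additionally caps keypoints per image
(`max_keypoints`, default 500, keeping the strongest absolute responses):
speckle produces thousands of weak extrema per ROI, and the cap bounds the
vocabulary-fitting cost without touching the detector itself.

### Descriptors

`keypoint_descriptor` ties window size to keypoint scale:
`side = max(16, round(6 * sigma))`, rounded up to a multiple of 4 so the
4 × 4 sub-region grid tiles the window exactly. Within each sub-region,
gradient magnitudes (central differences; one-sided at borders; unsigned
orientation folded into [0°, 180°), with a pure vertical gradient at 90°)
are accumulated **wholly** into the single 20° bin containing the pixel's
orientation — hard interval membership, not a bilinear vote — and each
9-bin cell is L2-normalized as `v / sqrt(sum(v^2) + eps^2)` with
`eps = 1e-6`, so an all-flat cell stays exactly zero instead of 0/0. The
16 cells are concatenated in row-major order to 144 dimensions.

Whether normalization should be per cell or over the whole 144-vector is
genuinely ambiguous; per-cell is the default and a `normalize = "global"`
switch in `hog_params()` provides the alternative. Descriptors are exactly
invariant to additive intensity shifts and invariant to multiplicative
rescaling up to the `eps` regularizer.

### Vocabulary

`fit_gmm` fits a K-component Gaussian mixture by EM over the pooled
training descriptors. Choices:

* **Diagonal covariances** by default: at 144 dimensions a full
  covariance has ~10⁴ parameters per component, far beyond what tens of
  thousands of descriptors support. Full covariance is available via
  `covariance_type = "full"` for low-dimensional uses.
* **Initialization**: k-means++ seeding followed by a short k-means run,
  all under the caller's seed; EM is then fully deterministic.
* **Variance floor** `1e-6` per dimension; a component whose
  responsibility mass collapses is re-seeded onto a random descriptor once
  (with a warning), then kept at the floor.
* **Stopping**: log-likelihood gain `< tol` (default `1e-3` in the
  experiment driver, `1e-4` standalone) or `max_iter`. The per-iteration
  log-likelihood trace is stored; EM guarantees it is non-decreasing, and
  every fit in the test suite asserts this.
* All densities and responsibilities are computed in log space with the
  log-sum-exp reduction, so a far-outlying descriptor whose raw densities
  underflow still receives a valid probability simplex vector.

The mixture's per-component quantity `p_ijk = π_k N(V_ij | u_k, Σ_k)` is
normalized over components into a posterior responsibility before
encoding. The unnormalized reading is also defensible, but the normalized
one makes "the probability of belonging to cluster k" literal, makes every
encoded vector a probability vector (entries ≥ 0, summing to 1), and puts
all images on a common scale regardless of descriptor density. This is the
package's single most consequential interpretation choice and is fixed as
the default rather than hidden behind a switch.

### Weight-scaled encoding

With responsibilities `P_ij` and one-hot argmax vectors `Q_ij` (ties
broken toward the lowest component index, for determinism), the image
encoding is

$$U_i = \frac{1}{J_i} \sum_{j=1}^{J_i} \big[\, \alpha P_{ij} + (1-\alpha) Q_{ij} \,\big].$$

`alpha = 1` is the probability-weighted average, `alpha = 0` the hard
visual-word histogram; the default `alpha = 0.15` sits close to the hard
end, sharpening boundary keypoints toward their dominant word while
retaining a soft correction. Two exact identities follow from `P` and `Q`
being simplex vectors and are asserted throughout the tests: `sum(U) = 1`,
and affinity `U(alpha) = alpha * U(1) + (1 - alpha) * U(0)`. The
normalizer is the per-image keypoint count `J_i` (the only reading that
keeps images comparable when their keypoint counts differ).

An image with zero surviving keypoints cannot be encoded from data. It
receives the uniform vector `1/K` and a `degenerate` flag rather than an
error, so corpus-level evaluations complete while reporting the affected
images. At the default generator settings this never happens; it can for
pathological inputs (e.g. constant ROIs).

### Classifiers

* **Broad learning system** (`fit_bls`): `n_map = 10` random affine
  mapping groups of `map_dim = 10` nodes (weights uniform on [−1, 1]),
  one tanh enhancement layer of `m_enh = 100` nodes, and output weights
  solving the ridge problem `min ||AW − Y||² + ε||W||²` in closed form as
  `W = (AᵀA + εI)⁻¹ AᵀY` with `ε = 1e-3`. The width is kept deliberately
  small: wide BLS layers overfit badly at n ≈ 50 training images. The
  closed form is verified against an SVD pseudo-inverse oracle in the
  tests. (A formulation with `(εI + AAᵀ)⁻¹` on the left is dimensionally
  inconsistent with this objective whenever A is not square; the ridge
  minimizer above is the consistent solution.)
* **Margin classifier** (`fit_margin_classifier`): an RBF-kernel SVM
  (`C = 1`, `gamma = 1/K`), backed by the `e1071` package since kernel SVMs are
  commodity; what matters to the ensemble is that it exposes the signed
  decision value `dist(x)`, oriented so positive favors FGR. For the
  binary case the per-class distances are `(−d, +d)`.
* **Ensemble**: `Y_j = λ softmax(Y_BLS)_j + (1−λ) sigmoid(dist_j)`. Each
  term is bounded by its mixing weight, so `Y_j ∈ [0, 1]`; the predicted
  label is the argmax with ties to class 0. `λ` is selected on the
  validation split by accuracy over the grid 0, 0.1, …, 1 (ties toward
  smaller λ, i.e. toward the margin classifier); with no validation data
  it falls back to 0.3 with a warning. At `λ ∈ {0, 1}` the ensemble's
  predictions coincide exactly with the corresponding single model, which
  the tests assert.

### Evaluation protocol

`run_experiment` performs `repeats` (default 10; 3 in the fast
configurations below) independent stratified 6:2:2 splits — with 80
images that is 48/16/16, balanced per class. A 6:2:2 ratio is not a fold
structure, so repetition of random stratified splits is used rather than
k-fold cross-validation. Per repeat: the vocabulary is fitted on training
descriptors only; augmentation (brightness ±0.1, contrast ×[0.9, 1.1],
rotation ±15°, crop retaining 90% of area — no scaling or shear, which
would distort the texture itself) is applied to training images only,
*after* splitting, between denoising and equalization; λ is chosen on
validation; metrics come from the untouched test split. Both the
per-repeat metrics and their mean (plus the best repeat) are reported,
with FGR as the positive class for recall/precision. All seeds derive
from the single master seed, making reports byte-reproducible.

ROC curves sweep thresholds across unique scores (tied scores cross
together) and AUC is the trapezoid integral, which equals the
Mann–Whitney pair-counting statistic with half credit for ties — asserted
against a literal pair-counting oracle.

## The synthetic test bed

`generate_dataset` emulates the *structure* of a placental ultrasound
cohort: 40 + 40 images, a centered circular ROI of radius 100 px in a
256 px image, and the class-defining texture difference — 150 isotropic
Gaussian dots (sd 2 px) for the normal class versus 150 anisotropic
Gaussian rods (8 × 2 px, uniformly random orientations) for FGR — under
multiplicative Gaussian speckle (`img * (1 + 0.15 η)`). Primitive contrast
0.4 on a 0.35 background was fixed once as visually plausible ultrasound
contrast. Speckle is modeled as multiplicative Gaussian rather than
Rayleigh for seedability and simplicity.

What passing tests on this generator establishes: that the implementation
chain — detector, descriptor, vocabulary, encoding, ensemble, protocol —
is correct and that the encoding separates oriented from isotropic
micro-texture under heavy multiplicative noise. What it does **not**
establish: clinical performance. Real placental texture differences are
far subtler, confounded by depth-dependent attenuation, probe pressure,
and acquisition variability, none of which are simulated (no PSF
convolution, attenuation or shadowing). Published accuracies on clinical
cohorts of this size are around 70%, not the ≥ 95% the clean synthetic
separation yields.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use K = 32 visual words,
3 repeats and 2 augmentations per training image on the 40 + 40 cohort —
sizes chosen so a full end-to-end run completes in a few minutes on one
core while still exercising every stage at realistic dimensionality
(30,000+ descriptors per vocabulary fit). The defaults encoded in
`wbovw_config()` (K = 128, 10 repeats) are the recommended analysis
settings.

## Known limitations

* Binary classification only; the ensemble's per-class distance
  construction is specific to two classes.
* No automatic ROI detection: the manifest must provide circle centers
  and radii in pixels (physical calibration, e.g. cm→px, is upstream
  metadata and deliberately out of scope).
* Integer keypoint positions (no sub-pixel refinement) and hard
  orientation binning trade a little descriptor precision for exact
  testability.
* The EM log-likelihood is guaranteed non-decreasing only while no
  component is re-seeded; re-seeding is rare and warned about.
* `alpha` and `K` interact (harder encodings want larger K); the defaults
  are a validated operating point, not a universal optimum. A grid sweep
  is straightforward with `run_experiment` over configs.
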