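---
title: "Methods: self-paced SVM segmentation of lung MRI with GLGCM texture features"
author: "svml package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-paced SVM segmentation of lung MRI with GLGCM texture features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svml)
```

## The problem

Lung-field segmentation of 2D MRI slices is a pixel-classification problem:
separate the parenchyma from surrounding tissue, with the hard decisions
concentrated at the boundary where the lung adheres to peripheral organs.
`svml` implements one complete answer: texture features from the gray-level
gradient co-occurrence matrix (GLGCM) feed a weighted soft-margin RBF-kernel
SVM trained under a self-paced (easy-samples-first) curriculum, followed by
2D morphological post-processing. Around the segmenter sit the standard
companions of a lung-MRI study: overlap metrics against a reference mask,
quantification of dynamic contrast-enhanced (DCE) time–signal curves, and
apparent diffusion coefficient (ADC) estimation from multi-b-value
diffusion-weighted imaging.

No clinical images ship with the package. Every experiment runs on the
bundled synthetic phantom generator, which is first-class, seeded and
tested; what that does and does not demonstrate is discussed at the end.

## Texture features

For each pixel we build a 4-component feature vector from its 5×5
neighborhood:

1. the quantized gray level `i/Lg`,
2. the quantized Sobel gradient magnitude `j/Lv`,
3. the *small-gradient advantage*
   `mu1 = sum_ij H(i,j)/j^2 / sum_ij H(i,j)`,
4. the *inverse difference moment*
   `mu2 = -sum_ij P(i,j) / (1 + (i-j)^2)`,

where `H(i,j)` counts co-occurrences of gray level `i` and gradient level
`j` over the 25 window pixels and `P = H/25`. Both statistics are means of
per-pixel window terms, so the full-image maps are computed with a sliding
box filter in O(pixels) rather than per-window loops; the unit tests verify
the equivalence against naive double-loop counting.

Choices the underlying description leaves open, fixed here:

* **Gradient operator**: 3×3 Sobel magnitude — the standard choice, with
  adequate isotropy for a 4-neighborhood texture statistic.
* **Quantization**: `Lg = Lv = 16` levels, 1-based linear min–max binning
  per image. Levels start at 1 because `mu1` divides by `j^2`.
* **Borders**: symmetric (edge-duplicating) padding for both the gradient
  and the windows.
* **Sign of `mu2`**: the leading minus is kept as-is, making
  `mu2 ∈ [-1, 0)`. It is a fixed sign convention; after z-scoring it is
  indistinguishable from the usual positive form.

## The weighted SVM and its solver

Training solves the kernelized dual

    max_a  sum_i a_i - 1/2 sum_ij a_i a_j y_i y_j K(x_i, x_j)
    s.t.   sum_i a_i y_i = 0,   0 <= a_i <= C v_i

with `K(x, x') = exp(-gamma ||x - x'||^2)`. The per-sample weights `v_i`
scale the box caps — the standard weighted-SVM construction; `v_i = 0`
removes a sample. The discriminant is
`f(x) = sum_{i=1..Ns} y_i beta_i K(x, x_i) + c` over the `Ns` support
vectors, and the *correct-rate discriminant weight* `w_t = 1 - Ns/n`
summarizes the leave-one-out error bound `E[P(error)] <= E(SV)/n`, with
`E(SV)` estimated by the realized support-vector count (no resampling).

The solver is a two-variable working-set (SMO-style) coordinate ascent:
maximal-violating-pair selection on the gradient, exact Newton step with
box clipping, stopping when the KKT residual falls below `1e-3` (capped at
`max(10n, 5000)` updates). Two numerical details matter:

* updated multipliers within `1e-12·C` of a bound are snapped exactly onto
  it — otherwise residual dust keeps a sample in the wrong working set and
  the violating pair stalls on a `1e-16` step;
* the bias `c` is the mean of `-y_i G_i` over free support vectors
  (`0 < a_i < C v_i`), falling back to the midpoint of the KKT bounds when
  none are free.

The test suite checks the dual objective against an independent
interior-point QP solution on randomized small instances, plus feasibility
(`sum a_i y_i = 0`, box constraints) and the KKT residual after every run.
Features are z-scored with training statistics by default; the statistics
travel with the model. Ties `f(x) = 0` predict background, so
segmentations are deterministic.

## Self-paced curriculum

The self-paced objective alternated by `self_paced_train()` is

    sum_i v_i L_i + eta ||w||^2 - lambda sum_i v_i,   v in {0,1}^n

with `L_i` the hinge loss and `-lambda sum v_i` the *hard* self-paced
regularizer — the simplest form whose v-step has a closed form:
`v_i = 1(L_i < lambda)`. Samples with loss below the pace threshold are
"easy" and admitted; `lambda` grows by a multiplicative factor (default
1.5) each round, admitting harder samples. Design choices:

* **Initialization**: an unweighted warm-up fit supplies the first losses;
  `lambda0` defaults to their 60th percentile.
* **Monotone inclusion**: each round's threshold set is unioned with the
  previous `v`, so a sample once admitted stays. This makes the included
  count provably non-decreasing, and the v-half-step still never increases
  the objective, because every newly admitted sample has `L_i < lambda`.
* **`eta` vs `C`**: the description calls `eta` a step length but it
  multiplies `||w||^2`; it is mapped onto the SVM trade-off as
  `C = 1/(2 eta n)` so one knob controls both. Passing `C` directly (the
  default) sets `eta = 1/(2C)` implicitly, the scaling under which SVM
  retraining at fixed `v` minimizes the objective above.
* **Degenerate rounds**: an all-zero or single-class `v` falls back to
  `v = 1` for that round with a warning.
* **Stopping**: all samples included and stable, or `max_rounds` (10).

With `lambda0` above every warm-up loss the curriculum degenerates to the
plain SVM exactly (identical multipliers); this and the block-coordinate
descent property (neither half-step increases the objective, within solver
tolerance) are asserted in the tests. On two-blob toys with 10% flipped
labels, the curriculum excludes most mislabeled points and matches or
beats the plain SVM's held-out accuracy paired over 20 seeds.

## Segmentation pipeline

`fit_pipeline()` / `run_pipeline()` chain four stages:

1. **Parenchyma extraction** — Otsu threshold, keep the two largest
   connected components not touching the border, fill holes. The bright
   class is taken as lung (the phantom convention; see below).
2. **ROI dilation** — the extracted mask dilated by `roi_dilate` (default
   4 px). The dilation matters twice: it supplies the `-1` (background)
   training pixels, and it defines the band in which the classifier makes
   its actual boundary decisions. Outside the band everything is
   background.
3. **Pixel classification** — balanced, seeded sampling of
   `train_fraction` (default 0.1, capped at `max_per_class = 500` per
   class per image) of the ROI pixels trains the self-paced SVM;
   prediction runs on every ROI pixel. Dense training is avoided because
   kernel training cost is quadratic in samples.
4. **2D morphology** — closing with a disc of radius 1, hole filling,
   removal of components under `min_component_px = 50` pixels. This never
   increases the component count and is idempotent on its own output.

The plain (non-self-paced) SVM is available with
`pipeline_config(self_paced = FALSE)` and is the package's single
baseline.

## DCE and ADC quantification

Enhancement is normalized as `E(t) = 100 (S(t) - S_pre)/S_pre` with
`S_pre` the mean pre-contrast signal. From it:

* **Steepest slope (SS)**, %/s: the maximum consecutive finite difference
  `dE/dt`. Defined on percent enhancement so the unit is %/s and the value
  is invariant to uniform signal rescaling.
* **Washout ratio (WR)**, %: `100 (E_peak - E_last)/E_peak`, the late loss
  relative to peak enhancement; undefined (NA) when nothing enhances.
* **Curve typing**: persistent / plateau / washout by the relative late
  change `r = (E_last - E_peak)/E_peak` against a ±10% band (`tol`). The
  reference peak is the *initial* peak — located by a continuous
  two-segment piecewise-linear fit with the knee chosen by grid search —
  not the global maximum: a persistently enhancing curve's global maximum
  is its own last sample, which would force `r ≈ 0` and type every
  persistent curve as plateau. The segmented fit also averages noise over
  all samples; at 2% noise the generating type is recovered for over 95%
  of seeded curves (100% in the shipped experiments).
* **ADC**, mm²/s: ordinary least squares on `ln S(b) = ln S0 - b·ADC`;
  with two b values this is the exact formula `ln(S1/S2)/(b2 - b1)`.
  Exact on noiseless decays; on noisy decays (noise 1% of S0, b =
  0/500/1000) the mean over 500 seeded repeats recovers the true ADC
  within 2%.

## The phantom generator

`generate_lung_phantom()` renders two elliptical lung fields (semi-axes
width/5 × height/3, centered left and right of the midline) on a darker
background, with optional nodule disc, in-lung texture (white noise passed
through a uniform filter of width `texture_scale`, amplitude
`noise_sigma/2`) and additive Gaussian noise. Defaults are the package's
study conditions, chosen once: 128×128 pixels, lung 200 / background 50 on
a 0–255 scale, `noise_sigma = 10`, `texture_scale = 5`. Curve phantoms are
piecewise-linear enhancement profiles (180 s at 6 s sampling, peak at
60 s, late slope +30%/0/−40% of peak for persistent/plateau/washout); DWI
phantoms are mono-exponential decays at b = 0/500/1000 s/mm² with
ADC 1.0×10⁻³ mm²/s.

Deliberate simplifications, documented rather than hidden:

* **Polarity**: lung fields are rendered *brighter* than background
  because class contrast is what the classifier consumes; real MR lung
  parenchyma is dark. Swap the two intensities to emulate the clinical
  polarity.
* **Noise** is Gaussian, not Rician; no coil bias, motion, or 3D
  structure.
* Enhancement curves are piecewise-linear, not pharmacokinetic.

Consequently, passing phantom experiments demonstrates the correctness and
determinism of the machinery — features, solver, curriculum, morphology,
metrics, curve estimators — under controlled contrast and noise. It does
not demonstrate clinical segmentation accuracy on patient MRI, which
depends on anatomy and artifacts the phantom does not model.

## Numerical choices and degenerate inputs

* Constant images quantize to level 1 everywhere, yield an empty
  parenchyma mask with a warning, and segment to all-background.
* Two empty masks have Dice 1 by convention; undefined denominators
  (empty prediction for SE, full prediction for SP, non-enhancing curve
  for WR) are reported as `NA`, never silently 0.
* The Dice denominator is `|A| + |B|` (standard). The union-denominator
  variant — which reaches 2 for identical masks — exists behind
  `dice(..., denominator = "union")` for comparability.
* SE and SP follow the A=reference / B=prediction reading
  (`|A∩B|/|B|`, `|A₁∩B₁|/|B₁|`, i.e. precision and negative predictive
  value); `evaluate_masks()` also reports the conventional
  `se_std = |A∩B|/|A|` and `sp_std = |A₁∩B₁|/|A₁|`.
* Seeds: every stochastic operation takes an explicit integer seed and is
  bit-reproducible; generators restore the caller's RNG state.

## Known limitations

* GLGCM window statistics depend on the noise level: a classifier trained
  at `noise_sigma = 10` has never seen a `sigma = 0` background window
  (gray level 1, `mu2 = -1` instead of level ≈3, `mu2 ≈ -0.3`), so its
  RBF discriminant degenerates to the bias sign on such pixels. The
  shipped noiseless experiments therefore use matched (noiseless-trained)
  models; mixing noise levels between training and inference is outside
  the validated envelope.
* The solver is exact but dense: kernel training cost is O(n²) memory and
  the pipeline caps sampled training pixels accordingly (the shipped
  experiments train on ≤2100 pixels from three 128×128 phantoms, which
  completes in seconds).
* Only binary lung-vs-background segmentation is implemented;
  nodule-vs-lung discrimination and 3D volumes are out of scope.

## Problem sizes in the shipped experiments

Training: 3 phantoms at 128×128, ≤500 sampled pixels per class per image.
Quality gate: 20 seeded phantoms at `noise_sigma = 10`. Solver validation:
20 random toys with n ≤ 30 against an interior-point QP oracle. Curve
typing: 200 seeded curves at 2% noise. ADC: 500 seeded decays at 1% of S0.
These sizes were chosen so the entire suite, including training, runs in
well under a minute on one CPU while keeping every Monte-Carlo estimate
stable to the asserted tolerance.
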