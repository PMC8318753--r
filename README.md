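# svml — self-paced SVM segmentation of lung MRI with GLGCM texture features

`svml` is an R toolkit for pixel-wise lung-field segmentation of 2D MRI
slices and for the quantitative MRI measurements that usually accompany a
lung-nodule study. It is aimed at medical-image-analysis researchers who
want a complete, dependency-light, fully seeded reference implementation
of this classical (pre-deep-learning) segmentation stack, exercisable end
to end on bundled synthetic phantoms.

## What it computes

**Texture features.** Every pixel gets a 4-vector from its 5×5 window:
quantized gray level `i/Lg`, quantized Sobel gradient level `j/Lv`, and
two statistics of the gray-level gradient co-occurrence matrix (GLGCM)
`H(i,j)` — the small-gradient advantage and the inverse difference moment:

```
mu1 = ( Σ_i Σ_j H(i,j)/j² ) / ( Σ_i Σ_j H(i,j) )
mu2 = − Σ_i Σ_j P(i,j) / (1 + (i−j)²) ,   P = H/25
```

**Classifier.** A weighted soft-margin SVM with RBF kernel
`K(x,x') = exp(−γ‖x−x'‖²)`, trained by an SMO-style exact dual solver
under per-sample box constraints `0 ≤ α_i ≤ C·v_i`. The discriminant is
`f(x) = Σ_{i=1..Ns} y_i β_i K(x, x_i) + c`, and `w_t = 1 − Ns/n` reports
the leave-one-out correct-rate weight. The sample weights `v` follow a
self-paced curriculum: alternating minimization of
`Σ v_i L_i + η‖w‖² − λ Σ v_i` with the closed-form update
`v_i = 1(L_i < λ)` and a growing pace parameter λ, so easy (low-loss)
pixels are learned first and mislabeled outliers are kept out.

**Pipeline.** Otsu-based parenchyma extraction → feature stack → pixel
classification inside a dilated region of interest → 2D morphological
post-processing (closing, hole filling, small-component removal).

**Evaluation.** Dice `2|A∩B|/(|A|+|B|)`, sensitivity, specificity and
mean squared error between predicted and reference masks.

**DCE/DWI quantification.** Percent enhancement, steepest slope (%/s),
washout ratio (%), persistent/plateau/washout curve typing, and ADC from
the log-linear mono-exponential fit `ln S(b) = ln S0 − b·ADC`.

A seeded phantom generator supplies lung-slice images with ground-truth
masks, three-type enhancement curves and DWI decays for all experiments.

## Worked example

```r
library(svml)

# three phantom slices with ground truth; train the self-paced pixel SVM
train <- lapply(1:3, function(k) generate_lung_phantom(phantom_spec(seed = 100 + k)))
cfg   <- pipeline_config(seed = 1)
model <- fit_pipeline(lapply(train, `[[`, "image"),
                      lapply(train, `[[`, "mask"), cfg)
model
#> Weighted RBF-SVM model: 46 support vectors (of 2100 samples), gamma=0.5, C=10, bias=-0.09024

# segment an unseen phantom and score it against its reference mask
ph  <- generate_lung_phantom(phantom_spec(seed = 200))
res <- run_pipeline(ph$image, model, cfg, ref = ph$mask)
res$metrics
#> Dice 1.0000 | SE 1.0000 | SP 1.0000 | MSE 0.0000  (|A|=6876, |B|=6876, |A&B|=6876, 16384 px)
correct_rate_weight(model, model$n_train)
#> [1] 0.9780952

# quantify a noisy washout enhancement curve and a DWI decay
p <- dce_params(generate_tic(curve_spec("washout", noise_sigma = 2, seed = 3)))
sprintf("SS = %.3f %%/s | WR = %.1f %% | type = %s", p$ss, p$wr, p$curve_type)
#> "SS = 2.204 %/s | WR = 35.7 % | type = washout"
compute_adc(generate_dwi(dwi_spec(noise_sigma = 10, seed = 4)))$adc
#> [1] 0.0009782096
```

The 46 support vectors out of 2100 sampled training pixels give
`w_t = 0.978` — the model expects at most ~2.2% leave-one-out error. The
unseen phantom at the default noise level is segmented perfectly. The
washout curve loses ~36% of its peak enhancement (its generator nominally
loses 40%, read through 2% noise), and the fitted ADC of
9.78×10⁻⁴ mm²/s sits within ~2% of the generating 1.0×10⁻³ mm²/s.

A command-line interface with the same functionality (subcommands
`simulate`, `features`, `train`, `segment`, `evaluate`, `dce`, `adc`)
ships at `inst/cli/svml.R`:

```sh
Rscript inst/cli/svml.R simulate phantom --out out/ --seed 7
Rscript inst/cli/svml.R --help
```

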