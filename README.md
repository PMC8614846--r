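# kneejsw

Automated joint-space-width (JSW) assessment of knee radiographs, and
JSW-based prediction of knee osteoarthritis severity and progression.

Radiographic knee osteoarthritis is staged with the Kellgren-Lawrence
(KL) grade, whose main quantitative correlate is the width of the
tibiofemoral joint space. Clinics usually record a single number — the
minimum JSW of the medial compartment — but a single site discards the
morphology of the rest of the joint. `kneejsw` implements the full
automated measurement chain and its evaluation machinery:

- **Segmentation.** A four-class (background / femur / tibia / fibula)
  residual encoder-decoder network ("ResU-Net-18": an 18-layer residual
  encoder with a skip-connected, width-mirroring decoder and independent
  sigmoid output channels), trained with mean per-channel binary
  cross-entropy, Adam (lr 0.001, weight decay 1e-5), rotation/shift/
  flip/jitter augmentation and early stopping (patience 10). The
  network, its hand-derived backward pass and the training loop are
  implemented in the package (BLAS matrix products + compiled im2col
  kernels) and verified by finite-difference gradient checks.
- **Contours.** Continuous femoral and tibial articular margins traced
  per column from the label mask, at pixel-edge (half-integer row)
  precision.
- **JSW measurement.** A normalized tibial-plateau frame `x ∈ [0, 1]`
  (medial compartment at high `x`); multi-point JSW at fixed sites in
  the lateral `[0.10, 0.30)` and medial `[0.70, 0.90)` windows with
  spacing `0.4/n` (8/16/32/64-point grids nest dyadically); minimum JSW
  as the exact brute-force minimum Euclidean distance between margin
  points with `x ∈ [0.7, 0.9]`; millimetre calibration from DICOM pixel
  spacing or an explicit factor.
- **Agreement.** Pearson r / R², Bland-Altman bias and 1.96-SD limits
  of agreement, ICC(2,1), and signed/absolute error summaries.
- **Prediction.** Gradient-boosted trees (XGBoost) on JSW features for
  5-class KL severity and binary 48-month progression (KL 0-1 → 2-4),
  grid-searched with stratified 5-fold CV, evaluated with a
  subject-grouped 8:2 split and 100 bootstrap resamples (macro F1, AUC,
  95% CIs, Welch t-test between models).
- **Phantoms.** A generator of synthetic radiograph/mask pairs whose
  joint gap `g(x)` is known analytically (the rendered pixel gap equals
  the quantized `g` exactly, by construction), plus synthetic observer
  pairs and synthetic KL cohorts — so every stage is validated against
  ground truth without clinical data.

## Worked example

Measure a phantom whose true gap profile is `g(x) = 2 + 8 (x − 0.8)²`
mm (medial minimum 2.0 mm at `x = 0.8`), at 0.2 mm/pixel:

```r
library(kneejsw)

ph <- make_phantom(phantom_spec(gap = function(x) 2 + 8 * (x - 0.8)^2,
                                mm_per_pixel = 0.2, tibia_coef = 0.55))
res <- measure_mask(ph$mask, laterality = "right", mm_per_pixel = 0.2,
                    n_points = 16)
res$min
#> <kj_min_jsw> 2.000 mm at x_f=0.800, x_t=0.800 (window 0.7-0.9)
head(res$profile, 3)
#>   site     x width_mm imputed
#> 1    1 0.100      6.0   FALSE
#> 2    2 0.125      5.6   FALSE
#> 3    3 0.150      5.4   FALSE
```

The minimum JSW is recovered exactly at the true location, and the
16 profile widths track `g` within pixel quantization (`width_at`
quantizes to 0.2 mm here). Agreement statistics against a reference
series:

```r
obs <- make_observer_pairs(10000, bias = 0.61, sd = 0.9, seed = 7)
agreement(obs$a, obs$b)
#> <kj_agreement> n=10000
#>   Pearson r=0.8197 (p=0), R^2=0.6719
#>   Bland-Altman bias (a-b) = -0.6177, LoA = bias +/- 1.7736
#>   ICC(2,1) = 0.7377
#>   |error|: mean 0.8838, SD 0.6475
```

A command-line front end over the same functions lives in
`inst/cli/kneejsw.R` (`simulate`, `preprocess`, `contours`, `measure`,
`agree`, `predict`).

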