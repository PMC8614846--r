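---
title: "Methods: automated joint-space-width assessment in kneejsw"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated joint-space-width assessment in kneejsw}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneejsw)
```

## The measurement problem

Radiographic knee osteoarthritis is conventionally staged with the
Kellgren-Lawrence (KL) ordinal scale, and the width of the tibiofemoral
joint space is its main quantitative correlate: as cartilage is lost the
projected gap between the inferior femoral condyle margin and the
superior tibial plateau margin narrows. Clinical practice usually
reports a single number, the *minimum* joint space width (JSW) in the
medial compartment. This package implements an automated pipeline that
(i) segments the bones of a knee radiograph, (ii) extracts continuous
articular margins from the segmentation, (iii) measures JSW both at the
medial minimum and at many fixed, normalized locations across the whole
joint ("multi-point JSW"), and (iv) uses those measurements to predict
KL severity and 48-month progression. The scientific question the
multi-point profile addresses is whether whole-joint morphology carries
predictive information that the single medial minimum discards.

## Coordinate conventions

Rasters are row-major matrices with rows increasing downward, so the
femur lies at *smaller* row indices than the tibia. Pixel `(r, c)`
occupies the square `[r - 0.5, r + 0.5] x [c - 0.5, c + 0.5]`; articular
margins therefore sit on pixel edges and are reported at half-integer
rows (femoral margin = bottom edge of the lowest femur pixel in a
column, tibial margin = top edge of the highest tibia pixel). Pixel
spacing is carried per axis (`row_mm`, `col_mm`) so anisotropic
resampling stays consistent: vertical widths use `row_mm`, Euclidean
pair distances use both.

The tibial plateau defines a normalized coordinate `x` in `[0, 1]`
through an affine map of its column extent. The medial compartment is
always placed at high `x`. Laterality metadata decides whether the map
must be mirrored (in this package's orientation convention a right knee
carries its medial compartment at high image columns); when laterality
is unknown the caller must state the medial side explicitly, because a
mask alone cannot distinguish the compartments.

## Segmentation network

Bones are segmented by a four-class (background, femur, tibia, fibula)
encoder-decoder network. The encoder is the standard 18-layer residual
topology (7x7 stride-2 stem, 3x3/2 max-pool, four stages of two basic
residual blocks with widths 64/128/256/512); the decoder upsamples by
nearest-neighbour 2x, concatenates the matching encoder stage and
applies a 3x3 convolution-BN-ReLU whose width mirrors that stage,
followed by a final 1x1 convolution. The head uses four *independent
sigmoid* channels — deliberately not a softmax — and training minimizes
the mean per-channel binary cross-entropy
`-(y log p + (1 - y) log(1 - p))`; the label map is the per-pixel
argmax with exact ties resolved to the lowest class index. A 50-layer
bottleneck encoder variant is available for capacity comparison
(`resunet_param_count(50)` is ~4.5x larger); the default build contains
no dilated convolutions.

Because no deep-learning framework is assumed, the network and its
training loop are implemented in the package itself: convolutions are
im2col + BLAS matrix products with compiled gather/scatter kernels, and
the backward pass of every operator is hand-derived and verified against
central finite differences in the test suite (relative error < 1e-4 on
sampled parameters of every layer type).

Training follows a fixed recipe: Adam (`lr = 0.001`,
`weight_decay = 1e-5`), per-epoch augmentation (rotation within ±5°,
shifts within ±10% of the side, horizontal flips, ±10% multiplicative
contrast/brightness jitter; bilinear resampling for images, nearest for
masks), and early stopping when the validation loss has not strictly
decreased for 10 epochs, returning the weights of the best validation
epoch. Any strict decrease counts as improvement (no minimum delta).
Batch size defaults to 4 and the epoch budget to 300; both are
implementation defaults, as is the jitter amplitude. A NaN loss aborts
with a diagnostic rather than continuing silently. All randomness flows
through the configuration seed, so runs are bit-reproducible.

The package's standing verification of the training loop is a
controlled overfit: five synthetic 128x128 phantoms must reach a mean
IoU of at least 0.95 when the network is trained on them directly
(augmentation off, `target_train_iou = 0.95`); this completes in a few
minutes on one CPU core. Intensity preprocessing for real radiographs
truncates the histogram between the 5th and 99th percentiles and maps
the clipped range affinely to `[0, 1]`; percentiles are order statistics
(inverse ECDF) rather than interpolated quantiles, a deliberate choice
that makes normalization *exactly* idempotent — re-normalizing a
normalized image is a no-op, which interpolated quantiles only achieve
approximately. Constant images map to zero. Images are resized to
1024x1024 for the full-scale pipeline (bilinear; nearest for masks so
labels stay categorical), with pixel spacing rescaled per axis.

## Margin extraction and JSW measurement

On a labelled mask the articular margins are obtained by per-column
boundary tracing: for every column shared by femur and tibia, the
femoral margin is the lowest femur boundary edge and the tibial margin
the highest tibia boundary edge. On a binary raster this coincides with
what an edge filter would produce, but it is deterministic and
parameter-free, which is why tracing replaces a tunable edge detector.
Margins are restricted to the longest contiguous run of shared columns,
so the returned curves are continuous with exactly one row per column.
Masks without shared columns, or with the femur below the tibia, are
rejected with specific errors.

Multi-point JSW samples the vertical inter-margin distance at fixed
normalized sites. The two compartment windows are `[0.10, 0.30)`
(lateral) and `[0.70, 0.90)` (medial), sampled half-open with spacing
`0.4 / n`: for 8, 16, 32 and 64 points this yields intervals of 0.05,
0.025, 0.0125 and 0.00625 respectively, and dyadic grids nest exactly
(every n-point site is also a 2n-point site, with identical measured
widths). Equal-width windows are the unique convention that reproduces
all four canonical point counts from those intervals; an alternative
lateral window starting at 0.15 can be configured, but its spacing is
then inconsistent with the canonical counts. Each site is measured at
the pixel column nearest its exact fractional column; exact half-column
ties are broken toward the medial side, which keeps measurements
equivariant under horizontal mirroring. Sites falling outside the
margin overlap are imputed from the nearest valid site and flagged, and
a profile with more than 25% missing sites is rejected. Negative gaps
(crossing margins, plausible in grade-4 bone-on-bone joints) clamp to
zero with a warning.

The minimum JSW is the smallest Euclidean distance
`sqrt((dr * row_mm)^2 + (dc * col_mm)^2)` over *all pairs* of margin
points whose `x` lies in the medial search window `[0.7, 0.9]`. The
implementation is exact brute force; the test suite holds it equal —
bit for bit — to an independent double-loop oracle. Pixel quantization
flattens the minimum into a set of exactly tied pairs; the reported
minimizer is the tied pair of median `x` (the central minimizer), which
avoids the edge bias a plain first-minimum rule would introduce.
Conversion to millimetres is a scale factor taken from DICOM pixel
spacing or supplied explicitly; radiographic magnification calibration
is accepted as that single factor and is not estimated by the package.

## Agreement statistics

Two paired measurement series (for example automated vs radiologist
minimum-JSW) are compared with the standard method-comparison toolkit:
Pearson correlation with two-sided p-value (and `R^2 = r^2`),
Bland-Altman bias `mean(a - b)` with 95% limits of agreement
`bias ± 1.96 SD(a - b)` (n-1 denominator), and the intraclass
correlation coefficient. The ICC form is ICC(2,1) — two-way random
effects, absolute agreement, single measurement — the conventional
inter-observer reliability coefficient; it is computed from the ANOVA
mean squares in closed form and the tests pin it to an independent
`stats::aov` computation at 1e-10. Because "measurement error" is often
quoted as a magnitude, the summary reports both the signed difference
(mean, SD) and the absolute difference (mean, SD of `|d|`, the folded
distribution).

## Severity and progression prediction

JSW features (the 64-, 32-, 16- or 8-point profile, or the minimum
alone) feed gradient-boosted decision trees (XGBoost). Two tasks are
supported: 5-class KL severity at baseline, and binary progression,
defined as a transition from an unaffected knee (KL 0-1) to a confirmed
case (KL 2-4) within 48 months; knees already confirmed at baseline and
knees lost to follow-up are excluded. Hyperparameters (`max_depth`,
`alpha`, `lambda`) are chosen by grid search with stratified 5-fold
cross-validation scored by macro F1; the default grids pair a shallow
setting with the deep optima reported for full-cohort tuning (severity
30/1/1, progression 25/0.5/1). Evaluation uses an 8:2 split that keeps
both knees of a subject on the same side (bilateral knees are
correlated; splitting them would leak), then 100 bootstrap resamples of
the test set with a fixed fitted model; resamples missing a class are
redrawn (at most 1000 attempts). Reported metrics are macro F1 and AUC
(macro one-vs-rest for multiclass), each as the bootstrap mean with a
95% CI half-width of `1.96 SD` of the bootstrap samples. Two models'
AUC sample vectors are compared with a Welch unpaired two-sided t-test;
if both vectors are constant the p-value is defined as 1 for equal
means and 0 otherwise. Everything is seeded and single-threaded, so a
configuration and a seed determine the report exactly.

## The phantom: what it does and does not emulate

Synthetic ground truth drives all quantitative validation. A phantom is
built from a smooth tibial margin curve and a gap profile `g(x)` in mm:
the femoral margin is *derived* as the tibial margin minus the
pixel-quantized gap, so the rendered per-column pixel gap equals
`round(g / mm_per_pixel)` exactly, with no interpolation error, and the
analytic profile is known everywhere. The default gap has a 2.0 mm
medial minimum at `x = 0.8` widening laterally, emulating
medial-dominant disease; bones render bright on a dark background with
seeded additive Gaussian noise (masks stay noise-free so geometry tests
are isolated from segmentation), and an optional small disjoint fibula
region exercises the fourth class. What the phantom deliberately does
*not* emulate: trabecular texture, projection physics, the double
anterior/posterior tibial rim of real radiographs, osteophytes, or
soft-tissue shadows. Passing phantom tests therefore demonstrates that
the measurement chain is correct on its own terms — margins recovered
exactly, widths within pixel quantization of the analytic gap — not
that the segmentation network generalizes to clinical images.

Synthetic observer pairs (`b = a + bias + N(0, sd^2)`) validate the
agreement statistics against closed-form expectations, and synthetic
cohorts validate the prediction stack: a latent severity `u` narrows a
chosen compartment (3 mm at full severity, Gaussian-shaped in `x`, on a
base profile of 4-5.5 mm with subject-level offsets shared by knee
pairs and 0.15 mm site noise), and KL is either the deterministic grade
implied by `u` (probability `signal_strength`) or drawn independently
from a typical baseline KL distribution (38.6/18.1/26.4/13.7/3.2%).
`signal_strength = 1` thus makes grades learnable from the features and
`0` makes any classifier's expected AUC 0.5. The package's analogue of
the multi-point-vs-minimum comparison constructs a cohort whose
narrowing is *lateral*: the medial minimum is then uninformative by
construction, and 16-point features must beat it by at least 0.05 AUC.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: constant images normalize to
zero, flat histograms fall back to min-max, masks missing a bone raise
"no joint overlap", plateaus narrower than 10 columns are rejected, and
BCE predictions are clipped at `eps = 1e-7`. Default test and
verification sizes are chosen for single-core desk-scale runs: 256x256
phantoms for measurement tests, 128x128 phantoms (5 of them) for the
training overfit check, cohorts of 150-1250 knees for the prediction
properties, and 100 bootstrap iterations, matching the reference
protocol, wherever a report is produced. The vignette's sizes are the
package's own verification choices, stated so results can be reproduced
exactly with `scripts/acceptance.R`.

## Known limitations

The package measures masks; it does not locate knees in bilateral
radiographs, correct rotation or beam flexion, or detect which side is
medial without metadata. Margin extraction trusts the mask's topmost
tibial boundary as the articular rim, which on real radiographs
requires the annotation convention to have resolved the
anterior/posterior rim ambiguity. Millimetre calibration is an input,
not an estimate. Training at clinical scale (thousands of 1024x1024
images) is out of scope for the bundled CPU implementation, which is
sized for controlled experiments and verification.
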