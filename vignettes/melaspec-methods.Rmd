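---
title: "Spectroscopic melanoma classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectroscopic melanoma classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melaspec)
```

## The measurement and the data model

A combined polarized/unpolarized light-spectroscopy probe records, for
every skin sample, six CCD frames of 32 × 512 intensities: two probe
placements inside the lesion and one on nearby normal skin, each
acquired in the parallel-polarized channel (P, dominated by
single-scattered light from superficial layers) and the cross-polarized
channel (V, dominated by multiple-scattered light from deeper tissue).
Row 15 of the frame carries the bright detector line; columns are the
spectral axis. Because the probe touches only spots inside the lesion,
there is no background skin in the frame and no segmentation step.

`melaspec` models this as a `sample_record`: six `spectral_scan`
objects keyed `p1, p2, p3, v1, v2, v3` plus a class label coded +1
(melanoma, the positive class) and −1 (benign). Scans travel on disk in
two portable layouts — headerless little-endian float32, row-major
(`.f32`), or a plain CSV matrix — because the original vendor encoding
is not recoverable from a "binary format" description; any real
acquisition would be converted upstream.

## Preprocessing

Three stages, in a fixed order:

1. **Median filter** (default 3 × 3, reflection padding). The CCD picks
   up isolated impulse pixels; a median over an odd window removes them
   while returning only values already present in the image. The window
   is configurable per axis; whether the original system filtered along
   the spectral axis only is unknown, so the default is the standard
   2-D minimal denoiser.
2. **Min-max normalization** per image: $(I - \min)/(\max - \min)$, so
   the minimum maps to exactly 0 and the maximum to exactly 1. Each
   image is normalized against its own extremes, which makes the result
   invariant to positive affine transforms of the raw counts — this is
   what removes detector gain and the per-subject multiplicative
   baseline. A constant frame is rejected as an acquisition failure
   rather than silently mapped to zero. Filtering must precede
   normalization: an unremoved impulse would otherwise pin the
   normalization extremes.
3. **Corrected intensity**: $\bar I = (s_1 + s_2)/2 - s_3$, the average
   of the two normalized lesion scans minus the normalized normal-skin
   scan, computed separately per channel. Subject-level structure
   common to lesion and normal skin (skin colour, age, sex, coupling)
   cancels; what remains is the lesion-specific signal. Values are
   signed in $[-1, 1]$ and are **not** clipped — the downstream
   statistics handle sign explicitly.

## Features

Each corrected image (one P, one V) is summarized by five statistics
over its $m \times n$ pixels: the mean $\mu$, the population standard
deviation $\sigma$ (divisor $mn$, exactly as the defining formula is
printed — not $mn - 1$), the mean absolute deviation, the $L_1$ norm
$\sum |\bar I_{ij}|$ and the $L_2$ norm $\sqrt{\sum \bar I_{ij}^2}$.
The 10-dimensional feature vector is ordered
`p_mean, p_sd, p_mad, p_l1, p_l2, v_mean, v_sd, v_mad, v_l1, v_l2`;
the original feature order is unrecorded, so this documented order is
fixed by the package. No feature selection is performed.

## Classifiers

All three classifiers are implemented in the package itself, mirroring
the configurations of the classic Java workbench the original analysis
used, because those configurations (not a generic fit) are the object
of study:

* **Gaussian naive Bayes.** Class priors from class frequencies; one
  normal density per feature and class, with the class-conditional
  standard deviation floored at `precision/6`, where `precision` is the
  mean gap between consecutive distinct sorted training values of the
  feature. The floor keeps degenerate (constant-within-class) features
  from producing infinite densities; the factor is configurable and
  recorded in the model file. Posteriors are normalized to sum to one;
  exact ties resolve to benign, the conservative call.
* **3-NN.** Brute-force Euclidean search over the memorized training
  set, unweighted majority vote, features min-max scaled to $[0, 1]$ by
  training ranges. Distance ties are broken by training-set position,
  making predictions deterministic; vote ties cannot occur for binary
  classification with odd $k$.
* **Back-propagation network.** 10 → 6 → 2 sigmoid units (hidden size
  ≈ half of inputs + outputs), features scaled to $[0, 1]$ by training
  ranges, one-hot targets, weights and biases initialized uniformly in
  $[-0.5, 0.5]$ from a seed (default 0), online (per-sample) gradient
  steps in table order with learning rate 0.3 and momentum 0.2 on the
  previous update, for 500 full epochs. No validation split is
  configured, so early stopping is inert.

Class imbalance (19 melanoma vs 168 benign) is deliberately **not**
reweighted; the study applied no correction, and reproducing its
behaviour — including the poor minority-class sensitivity of the
network and 3-NN — is part of the contract.

## Evaluation protocol

The cohort is repeatedly split into 60 training and 127 test samples
(alternatively 30/157) by random sampling without replacement, 25
times; per-run sensitivity (true-positive rate on melanoma),
specificity and accuracy are averaged arithmetically. Tables render to
one decimal with halves rounded away from zero; internal arithmetic is
full precision.

Splits are **stratified by default**: every published per-run
sensitivity is an integer multiple of 100/13, which is only possible if
every test set contained exactly 13 melanoma cases — the fingerprint of
proportion-preserving sampling (6 of 60 training cases melanoma). An
unstratified mode is available and the choice is recorded in the report
configuration. Each run draws its split from an independent substream
of the master seed, so any single run can be reproduced in isolation;
split lists are resampled per experiment rather than shared across
classifiers (nothing in the published tables distinguishes the two).

The published "probability of error" values (0.16/0.24/0.26) match
`1 − accuracy` for no table row; their definition is unrecoverable, so
the package reports `error_rate = 1 − accuracy/100` and leaves the
printed values alone.

## The synthetic cohort generator

The clinical scans are not deposited, so the package ships a generator
whose defaults emulate the study conditions: 19 melanoma + 168 benign
samples of 32 × 512 frames. Each scan is built as

> baseline surface × (1 + texture) + lesion effect + impulse noise,

where the baseline is a deterministic row profile (dark frame edges, a
bulk-tissue level, the bright detector line at `peak_row = 15`) times a
smooth spectral envelope along the columns; the texture is a smooth
random surface (six low-frequency sinusoid modes, RMS-normalized so
every image carries the same noise power — this keeps image summary
statistics varying smoothly and near-normally across samples); all six
scans of a sample share one log-normal multiplicative subject shift
(`subject_shift_sd`, default 0.1), which the normalization plus
lesion-minus-normal correction must cancel — the mechanism the method
claims. Lesion spots add a small lift for benign samples and an
additional broad, spatially varying lift scaled by `effect_size` for
melanoma; normal spots (`p3`, `v3`) carry no lesion effect. At
`effect_size = 0` a melanoma sample is constructed exactly like a
benign one. Impulse (salt-and-pepper) noise is injected at
`noise_rate` (default 0.001 per pixel) — impulse rather than Gaussian
noise because the pipeline's denoiser is a median filter, and the noise
must be something that stage demonstrably removes.

The design targets per-image intensity distributions: a normalized
benign lesion scan concentrates the majority of its pixels in
$[0.2, 0.4]$, while a melanoma scan spreads over $[0, 1]$ with heavy
mass at high intensities (the published class-conditional histograms
pool all images per class; the per-image reading is the stricter one
and is what the tests check). What the generator does **not** emulate:
physical light transport (no photon propagation or multilayer optics),
wavelength-dependent absorption features, detector saturation, probe
pressure artefacts, or between-patient covariate structure (age, sex,
skin type). Passing tests therefore demonstrate that the pipeline
recovers a planted lesion-vs-normal intensity shift under realistic
baseline variation — not that it would reach any particular accuracy on
new clinical data.

## Numerical choices and degenerate inputs

* Median windows must be odd and no larger than the image; a 1 × 1
  window is the identity.
* Constant images are errors at the normalization stage (undefined
  rescaling), reported with the offending scan slot.
* The float32 scan layout round-trips exactly at stored precision;
  generation and featurization in memory are double precision.
* Run substreams derive as
  `(seed mod 1000003) · 8191 + run · 524287 (mod 2147483629)`, keeping
  every derived seed a valid 32-bit integer.
* Stratified training counts use half-up rounding of the class share,
  clamped so both classes stay feasible.

## Problem sizes used by the shipped tests

The unit suite exercises 16 × 64 frames (the geometry is fully
parameterized, so nothing depends on the frame size), with full
32 × 512 frames wherever a contract names them. The acceptance suite
and `scripts/acceptance.R` run the full study conditions: 187-sample
cohorts of 32 × 512 frames, 25 stratified 60/127 repetitions for all
three classifiers, and a 3-level effect-size sweep at 10 repetitions.

## Known limitations

* **Zero-effect naive Bayes calibration.** With no class signal, the
  ideal decision is "always benign" (accuracy 114/127 ≈ 89.8%).
  Gaussian naive Bayes trained on 6 melanoma vs 54 benign samples
  systematically over-calls melanoma under the null: the five
  statistics per channel are intrinsically redundant
  ($L_2 \approx \sqrt{mn}\,\sigma$, $L_1 \approx mn\,\mathrm{MAD}$ or
  $mn\,\mu$ by construction), and near-duplicate features multiply the
  log-likelihood ratio, overwhelming the $\log(54/6) \approx 2.2$ prior
  margin for 5–13% of null samples. Simulation shows even ten perfectly
  independent Gaussian features would sit within half a point of the
  three-point calibration band, and every feasible correlation
  structure of these statistics falls below it. Zero-effect accuracy
  therefore lands around 76–84% rather than within three points of the
  baseline, independent of the generator's noise design; the
  corresponding acceptance assertion fails and is documented rather
  than weakened. The practical reading: under heavy class imbalance,
  this naive Bayes configuration trades specificity for sensitivity
  even when there is nothing to detect.
* The MLP loss surface makes its minority-class sensitivity highly
  seed-dependent at realistic effect sizes, mirroring the poor
  published network sensitivity.
* The generator's effect model is a location/scale lift, so classifier
  accuracy saturates quickly in `effect_size`; the monotonicity
  property is tested with a tolerance for split-sampling noise.
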