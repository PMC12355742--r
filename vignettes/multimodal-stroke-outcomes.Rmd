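---
title: "Multimodal prediction of stroke outcomes: models, phantoms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal prediction of stroke outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After an acute ischemic stroke, two outcomes matter to very different
audiences: the inpatient length of stay (LOS, an operational outcome for the
hospital) and the 90-day modified Rankin Scale (mRS, a functional outcome for
the patient). Both are routinely dichotomized for risk modeling — a poor
outcome is LOS strictly greater than 8 days, or 90-day mRS strictly greater
than 2 (mRS 2 is "needs no assistance", a natural cut). `neurofuse`
implements a complete framework for predicting these binary outcomes from
two modalities:

* **volumetric diffusion-weighted MRI (DWI)** — a stack of 2D slices handled
  as a 3D volume, already registered to a common template and
  intensity-normalized, with a binary brain mask and a manually segmented
  lesion mask; and
* **tabular clinical features** — demographics, admission scores such as the
  NIHSS, medication and condition history, plus two image-derived features
  (IDF): lesion volume in cm³ and thrombus location.

The modeling surface mirrors a three-arm design. The *clinical* arm trains a
single-layer classifier on encoded tabular features. The *image* arm
extracts information from the volume either with a 3D ResNet-10 (trained by
transfer learning, fine-tuning, or from scratch, optionally with a
squeeze-and-excite layer after the last residual stage) or with a
convolutional autoencoder whose bottleneck embedding summarizes the volume.
The *combined* arm freezes the image branch and retrains the single-layer
classifier on the concatenation of image features and tabular features. A
DAFT (Dynamic Affine Feature Map Transform) baseline conditions the last
ResNet feature map on the tabular vector through a per-channel affine
transform. Every arm runs with and without the IDF block.

Because severe outcomes are the minority class (18.91% for LOS > 8 in the
motivating cohort, 38.50% for mRS > 2), the area under the precision–recall
curve (AUPRC) is the primary model-selection and comparison metric; AUC,
recall, specificity and F1 complete the report. Metrics are aggregated as
mean (SD) over three stratified shuffle folds, with a single untouched
stratified 20% hold-out test set shared by all experiments.

## The classifier, in notation

Every arm ends in the same single-layer network: for an input block
$x \in \mathbb{R}^p$ (any concatenation of image embedding or backbone
features, encoded EHR, and encoded IDF),

$$\hat p = \sigma(w^\top x + b), \qquad \sigma(z) = \frac{1}{1+e^{-z}},$$

trained with class-weighted binary cross-entropy (positive weight
$n_-/n_+$, configurable off). The checkpoint with the best validation AUPRC
across epochs is kept, and the hold-out test set is scored exactly once from
that checkpoint.

## The synthetic lesion-phantom cohort

Real post-stroke MRI with linked outcomes is restricted-access, so the
package ships a generator (`phantom_config()`, `generate_cohort()`) that
emulates the *structure* of such a cohort well enough to exercise every
stage of the pipeline:

* **Volumes.** One template brain — a centered ellipsoid occupying ~38% of
  the grid — shared by all subjects, because registration upstream of the
  published data removes anatomy-scale variation. Intensities are emitted on
  the normalized unit scale (base 1.0, Gaussian noise SD 0.05), again
  because the emulated data is intensity-normalized before publication; no
  further normalization is applied by default (an optional per-volume
  z-score or brain-mean flag exists for non-normalized inputs). Each subject
  carries a single ellipsoidal lesion of contrast +0.6 — the strong
  diffusion hyperintensity of acute infarcts — with semi-axes driven by a
  latent severity variable.
* **Tabular features.** Marginals mimic a published stroke cohort: age ~
  Normal(62.28, 14.05), BMI ~ Normal(29.28, 7.47), NIHSS-like severity ~
  Normal(6.21, 6.65) truncated at 0 and correlated with lesion size through
  the shared latent severity, male 53.9%, thrombolysis 67.1%, four-level
  race and thrombus location with explicit Missing levels, and
  semicolon-separated medication/condition strings. Continuous clinical
  features receive MCAR missingness (default 5%, capped below 20%).
* **Outcomes.** A logistic model on standardized lesion volume, NIHSS and
  age (default weights 1.2 / 0.7 / 0.3), with the intercept bisected until
  the mean predicted probability matches the target prevalence (0.1891 for
  LOS, 0.3850 for mRS) to 1e-4. Continuous outcomes are then drawn
  consistently with the binary labels, so dichotomization recovers them
  exactly — the generator's own truth is a round-trip test.

What the phantom does **not** emulate: MRI physics, partial-volume effects,
multifocal strokes, scanner differences, registration artifacts, and any
claim about the real joint distribution of clinical and imaging features.
Passing tests on phantoms therefore demonstrate that the machinery is
correct and that planted signal of realistic geometry is recoverable — not
that any particular real-data performance will be attained.

## Architectures

* **ResNet-10** (`resnet_spec()`): 7³ stride-2 stem with batch
  normalization, ReLU and 3³ max-pool; four stages of one basic residual
  block each, widths (64, 128, 256, 512), strides (1, 2, 2, 2); global
  average pooling to 512 features; single-logit head. Optionally a
  squeeze-and-excite layer (reduction 16) after the last stage. About 14.4M
  parameters. Input grids of at least 16³ keep all spatial dimensions
  positive.
* **Autoencoder** (`autoencoder_spec()`): three stride-2 3³ conv blocks with
  channels (8, 16, 32), then a dense bottleneck to a 64-dimensional latent
  vector; the decoder mirrors the encoder using nearest-neighbour upsampling
  followed by 3³ convolutions ("resize convolution") and a linear output.
  We prefer resize convolution over strided transposed convolution: it
  avoids checkerboard artifacts and reuses the same convolution kernels,
  and the shape contract — decoder output shape equals encoder input
  shape — is unchanged. Trained with mean squared reconstruction error
  using the volumes as both input and target; the encoder is then run alone
  to produce embeddings.
* **DAFT block** (`build_daft()`): the pooled last-stage feature map is
  concatenated with the tabular vector, passed through a small dense
  bottleneck, and emits per-channel $(\alpha_c, \beta_c)$ applied as
  $v'_c = \alpha_c v_c + \beta_c$. The output layer is zero-initialized so
  the block starts as the exact identity, and gradients flow to both the
  image and tabular paths.

All layers are implemented in the package with explicit forward and backward
passes (the 3D convolution and pooling inner loops are compiled C++), so
parameter groups — stem, stage1..4, se, daft, encoder, decoder, head — are
individually freezable, and a frozen group is bit-identical after any number
of training steps.

## Optimization choices

The learning rates are the canonical published settings per regime: 0.01
constant for classifier-only training (clinical arm, transfer learning,
combined-arm retraining), 0.001 with a scheduler for fine-tuning, and 0.1
with a scheduler for training from scratch. The CNN regimes use plain
momentum-free stochastic gradient descent — the optimizer family for which
those rates are calibrated; 0.1 is not a meaningful adaptive-moment rate.
The classifier head and the autoencoder, whose rates we set ourselves, use
Adam (0.01 and 2e-3). The scheduler is reduce-on-plateau on validation loss
(factor 0.1, patience 5), the learning rate never increases, and training
stops early after 15 epochs without a validation-AUPRC improvement.
Class-imbalance handling weights positives by $n_-/n_+$ in the loss.

Transfer learning and fine-tuning require a pretrained backbone. When the
user supplies none, `surrogate_backbone()` fits the ResNet to a
self-supervised pretext — regressing the z-scored mean of each volume's top
5% brightest voxels, a hyperintensity summary computable without outcome
labels. It is labeled a surrogate throughout: it stands in for, and does not
reproduce, any published pretrained weights.

## Splits, preprocessing and leakage control

The cohort for each outcome is the subjects with that outcome available.
One stratified 20% hold-out is drawn first; the remainder is shuffled into
three stratified folds of 80% training / 20% validation (shuffle-split
semantics: folds are independent draws, not a partition, so training sets
may overlap across folds — the test set is identical everywhere). The plan
serializes to JSON and its hash is stamped into every run record;
training/validation logs carry subject ids so the no-leakage property (no
hold-out id in any log) is checkable mechanically.

Tabular preprocessing is fitted on fold-training rows only: continuous
features are mean-imputed and standardized by training mean and population
SD (a zero-variance column gets SD 1 with a warning); binary features treat
absence as false; categoricals one-hot over declared levels with an explicit
Missing level where the schema declares one (thrombus location does);
medication/condition strings become fixed indicator blocks that are all-zero
when the string is absent; unseen categories encode as zero vectors with a
warning. The default schema encodes to exactly 40 clinical columns and 5
IDF columns. Image-side feature blocks (embeddings, backbone features) are
standardized by fold-training statistics before entering the classifier.

## Evaluation

`auc()` is the rank-based Mann–Whitney estimator (ties count one half);
`auprc()` is step-wise average precision over distinct thresholds with no
trapezoidal interpolation — the standard estimator under class imbalance,
whose null value is the prevalence. Both are verified against exhaustive
brute-force definitions on hundreds of small instances to 1e-12.
Thresholded metrics default to 0.5 (configurable; the operating threshold is
an open question in the motivating work). Fold aggregation uses the sample
(n−1) SD — with three folds a population SD would understate spread.
Between-cohort demographic comparisons use two-sided permutation tests
(default n = 1000) with the add-one p-value estimator, so the smallest
attainable p is 1/(n+1).

## Grad-CAM and its desk-scale caveat

`gradcam()` computes channel weights as the spatial mean of the gradient of
the logit with respect to the target layer's activations, rectifies the
weighted channel sum, upsamples trilinearly to the input grid, and
normalizes the maximum to 1. The default target is the last residual stage,
matching where the SE layer sits. One caveat matters at desk scale: on a
32³ input the last stage is a 2³ map whose receptive field covers the whole
volume, so its activations are spatially constant and the saliency
degenerates to a uniform map (localization exactly at chance). For 32³
phantom work the lesion-localization analyses therefore probe the second
residual stage (8³, where spatial support survives); on full-resolution
grids the default last stage is appropriate. The autoencoder-embedding
classifier has no spatial feature map at the classifier and is rejected
with an informative error. Slice exports pick the lesion-centroid slice —
reproducible, unlike random slice selection.

## Embedding informativeness

The latent space is audited with a linear probe: ridge regression
(`embedding_probe()`, cross-validated over a fixed penalty path with
deterministic fold ids) from embeddings to true lesion volume, scored as R²
on held-out subjects. Ridge rather than OLS because the embedding width
(64) is comparable to a fold's training size; the probe remains a linear
readout. On 200-subject phantoms, five epochs of autoencoder training
already yield held-out R² above 0.5.

## Numerical and reproducibility notes

* All tensors are double-precision R arrays of shape (depth, height, width,
  channel, batch); convolution lowers to compiled direct loops, dense
  algebra to BLAS.
* Every stochastic step (initialization, shuffling, Bernoulli draws,
  splits) consumes an explicit seed, and RNG state is saved and restored
  around every seeded routine, so package calls never perturb a user's RNG
  stream. Suite reruns with the same configuration are bit-identical.
* Batch normalization keeps running statistics (momentum 0.1) and is
  deterministic in inference mode; frozen groups always run in inference
  mode.
* Bisection for the outcome intercept brackets on [−30, 30] and stops at
  1e-4 on the prevalence scale, erroring after 200 iterations.
* Degenerate inputs are handled explicitly: zero-variance features (SD→1
  with warning), single-class training folds (error), all-zero volumes
  (autoencoder converges to the zero map), empty heat maps (localization
  score 0 by convention), masks validated as binary to 1e-6.

## Problem sizes

The package defaults target desk-scale experimentation: 32³ grids,
200-subject cohorts, single-digit epoch budgets for the volumetric branches
and ~80 epochs for the (tiny) classifier head. These sizes are the package's
own study conditions — large enough for the planted-signal, calibration and
localization properties to be decidable, small enough to iterate on a
laptop. All of them are configuration knobs (`suite_config()`,
`phantom_config()`), and real MNI-resolution volumes pass through the same
code paths by changing the grid.

## Known limitations

* Single-lesion phantoms; multifocal disease is out of scope for the
  generator.
* The ResNet regimes' surrogate backbone is a pretext-task stand-in, not a
  reproduction of published pretrained weights; transfer-learning results
  with it say nothing about the value of the published backbone.
* No confidence intervals or calibration metrics; the reporting mirrors the
  mean (SD) across three folds.
* The exact clinical feature list of the motivating cohort is not public;
  the default schema reproduces its encoded width (40) with plausible
  blocks, and a real list can be dropped in via the schema.
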