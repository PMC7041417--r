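---
title: "Methods: patch-based 3D U-Net segmentation of intra-tumor glioma regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based 3D U-Net glioma segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gliomaseg)
```

## The problem

High-grade gliomas are segmented on multi-parametric MRI into three nested
regions: the **enhancing tumor** (ET, bright on post-contrast T1), the
**tumor core** (TC = ET plus the necrotic/non-enhancing center), and the
**whole tumor** (WT = TC plus peritumoral edema, bright on FLAIR/T2). Manual
delineation is slow and inter-rater variability is high, which motivates a
fully automatic pipeline. The central statistical difficulty is extreme
class imbalance: on BraTS-style 240×240×155 grids roughly 99% of voxels are
background or healthy tissue, so a naive voxel-wise learner collapses onto
the majority class and loses precisely the thin tumor boundaries a clinician
cares about.

This package implements the complete pipeline natively in R: intensity
normalization, weighted boundary-biased 3D patch extraction, a three-level
3D U-Net trained with a multi-class soft Dice loss, non-overlapping tile
inference, connected-component post-processing, and region evaluation —
plus a synthetic glioma phantom generator so every stage is testable at desk
scale without clinical data.

## Pre-processing

Inputs are skull-stripped, co-registered FLAIR/T1/T2/T1ce volumes at 1 mm
isotropic resolution. Each channel is z-scored: subtract the mean and divide
by the **standard deviation** so the result has zero mean and unit variance.
Two choices here are deliberate:

* Statistics are computed over **brain-mask voxels only** (the mask is the
  support of nonzero voxels, valid because skull-stripped data has
  exact-zero background). Whole-grid statistics would be dominated by the
  ~60–70% background zeros and would shift with head size.
* The **population** (n) rather than sample (n−1) standard deviation is
  used. At volume scale the difference is negligible; fixing it makes tests
  bit-reproducible.

Normalization never touches out-of-mask voxels, so background stays exactly
zero — several later stages rely on that invariant. Bias-field correction is
available only as a hook that shells out to an external N4 executable; it is
never re-implemented.

## Weighted patch extraction

Training operates on 64³ four-channel patches (32³ in the reduced desk-scale
configuration). Two sampling streams are combined:

1. **Equidistant grid seeds.** A regular lattice of patch corners covers the
   volume after zero-padding each axis up to the next multiple of the patch
   size (240×240×155 → 256×256×192; 240 and 155 are not multiples of 64, and
   zero is the semantically neutral fill for skull-stripped data). Patches
   whose brain fraction is not **strictly greater than 60%** are discarded so
   the model does not overfit to background. The training stride is
   configurable and defaults to the patch size (non-overlapping tiles).
2. **Boundary-weighted patches.** Grid sampling systematically
   misclassifies voxels on the tumor rim. The whole-tumor boundary is
   extracted as the *thick* 6-connected interface — voxels on either side of
   a WT/non-WT face — and a random **30%** of boundary voxels (uniform,
   without replacement, seeded) each become the *center* of an extra patch,
   with corners clipped into the padded grid near edges. Duplicate corners
   across streams are kept: the oversampling is the point.

The 60% filter is *not* applied to boundary patches by default (they exist
precisely to cover boundary-heavy, background-heavy neighborhoods); a flag
restores it. For desk-scale studies a `max_boundary` cap subsamples the
boundary stream (again seeded) — at full scale 30% of a WT boundary is tens
of thousands of patches, which is the intended training regime but not a
laptop one.

All sampling randomness flows through one explicit seed recorded in the
patch set, so a patch inventory is a pure function of (volume, labels,
config, seed).

## Network

A three-level 3D U-Net with 48/96/192 feature maps:

* Encoder level: two zero-padded 3³ convolutions, each followed by ReLU;
  2³ max-pool between levels. All convolutions preserve spatial shape, so
  input and output grids match exactly.
* Decoder level: nearest-neighbour 2× upsampling followed by a 3³
  convolution, concatenation with the same-level encoder features (skip
  connection), then two 3³ conv+ReLU layers.
* Head: a 1³ convolution to four maps (background, necrosis, edema,
  enhancing) fused by per-voxel softmax; the predicted label is the argmax,
  with ties broken toward the lowest class index. Softmax (not independent
  sigmoids) because the four classes are mutually exclusive.
* Dropout at rate 0.25 after each encoder block, active during training
  only.

The intra-block layer count (2), the pooling operator (max), and the
upsampling operator (nearest + 3³ conv) are conventional U-Net choices and
are all exposed in `unet_config()`. Batch normalization is not used. The
network, including backpropagation, is implemented in this package directly:
convolutions run as offset GEMMs over one-voxel zero-halo activation buffers
(with an independent im2col implementation kept as a cross-check), and the
whole gradient is verified against central finite differences in the test
suite. Patch edges must be divisible by 2^(levels−1); weight initialization
is He-scaled and seeded, so two builds from the same config agree in
architecture and parameter count exactly.

## Training

The loss is the smoothed multi-class soft Dice,
$L = 1 - \frac{1}{4}\sum_c \frac{2\sum_v p_{cv} t_{cv} + \epsilon}
{\sum_v p_{cv} + \sum_v t_{cv} + \epsilon}$, macro-averaged over the four
classes with $\epsilon = 10^{-5}$ — the standard choice when class
frequencies span two orders of magnitude, since each class contributes
equally regardless of size.

Optimization is mini-batch SGD with momentum 0.9 (velocity
`v ← m·v − lr·g`), batch size 8, for 100 epochs. The learning rate starts at
0.001 and is **stepped down once by a factor of 10 after epoch 60**; the
motivating observation (Dice loss plateaus around epoch 60) describes a step
event, so a single multiplicative decay is used rather than a continuous
ramp. Patches are reshuffled every epoch; shuffling, dropout and
initialization all derive from one seed, so training runs are
bit-reproducible on CPU. No early stopping: the epoch budget is fixed and
the loss history is recorded for inspection.

## Inference and post-processing

A volume is predicted by tiling the padded grid with non-overlapping
patches, predicting each tile, concatenating the label patches and cropping
back to the input shape — an exact partition, so tiling/assembly is the
identity on label volumes. Two cleanup steps then remove false positives:

1. **Largest connected component** of the binary whole-tumor mask under
   26-connectivity (configurable to 6/18). Components are computed on the
   WT mask, not per class, so a necrotic core disconnected from its
   enhancing rim is never deleted. Size ties break to raster discovery
   order. This step is known to harm genuinely multifocal tumors — the
   bifocal phantom test demonstrates exactly that behavior — and a
   `min_size_fraction` option keeps all components above a size fraction
   instead.
2. **Brain-mask AND**: any tumor label outside the brain mask (e.g. in the
   padding margin) is set to background.

Both operations are idempotent and can only remove tumor voxels, never
create them.

## Evaluation

Per region (ET = label 4; TC = labels 1∪4; WT = labels 1∪2∪4):

* Dice `2|P₁∩T₁|/(|P₁|+|T₁|)` (identical to the F1 score),
  sensitivity `|P₁∩T₁|/|T₁|`, specificity `|P₀∩T₀|/|T₀|`.
* HD95: surface voxels are mask voxels with a 6-adjacent outside neighbour;
  directed nearest-surface distances are computed both ways (honoring
  anisotropic spacing, in mm) and HD95 is the **maximum of the two directed
  95th percentiles**, the challenge-tooling convention; a pooled-percentile
  variant sits behind a flag.
* A metric with an empty denominator (region absent on both sides, or empty
  masks for HD95) is an `NA` sentinel. Cohort aggregation (mean, sample SD,
  median, 25th/75th percentiles with linear interpolation) scores an
  undefined Dice/sensitivity as **zero** by default — matching challenge
  scoring of hallucinated or missed regions — with an exclusion policy
  behind a flag; undefined HD95/specificity values are always excluded
  because no finite penalty is defined for them.

Percentile interpolation is fixed to linear (R quantile type 7) and SD to
the n−1 estimator for reproducibility.

## The phantom generator

The generator emulates the *data regime*, not MR physics: a zero-background
brain ellipsoid containing nested deformed spheroids — necrotic core (label
1) inside an enhancing rim (label 4) inside edema (label 2) — with
tissue-specific mean intensities per channel plus seeded Gaussian noise
(default SD 0.05 on tissue means of order 0.15–0.9). The intensity table
qualitatively honors clinical contrasts (edema bright on FLAIR/T2, enhancing
rim bright on T1ce, necrosis dark on T1ce) and is validated against those
constraints. Tumor surfaces are modulated by a smooth low-order directional
polynomial (amplitude 0.15, clamped) so the model cannot simply learn a
sphere prior. A second focus (for post-processing tests) is placed mirrored
through the brain center at 0.45× the radii.

Defaults scale with grid size: at 240×240×155 the non-tumor fraction lands
near 99%, the imbalance regime of real data; the 96³ default used in tests
carries ~1.7% tumor. What the phantom does **not** model: bias fields,
scanner/protocol variation, infiltrative margins, heterogeneous textures,
multi-rater label noise. Passing the desk-scale tests therefore demonstrates
that the pipeline's machinery — sampling, optimization, tiling, evaluation —
is correct and learnable, not that full-scale clinical accuracy is
reproduced; the latter requires the real cohorts and GPU-scale training.

## Desk-scale study sizes

The end-to-end learnability study (test suite and acceptance script) uses a
reduced configuration chosen once: 2 levels with 8/16 features, one
convolution per block, 32³ patches, dropout 0, learning rate 0.02 stepped
×0.1 before the final epoch, batch 8, six epochs over ≈200 patches drawn
from four 96³ phantoms (grid seeds at stride 32 filtered at 60%, plus 43
boundary patches per phantom), evaluated on a fifth held-out phantom. The
full-scale hyperparameters (0.001→0.0001 at epoch 60, 100 epochs, dropout
0.25, 48/96/192 maps, 64³ patches) remain the package defaults; the reduced
run exists to exercise the whole stack on one CPU. Dropout is disabled and
the learning rate raised in the reduced study because a 6-epoch budget on an
easy, low-noise task neither needs regularization nor survives the
full-scale learning rate; both remain ordinary config fields. The
boundary-sampling comparison trains three seed-paired runs per arm (grid
stride 16 with vs. without 25 boundary patches, three epochs) and compares
the median Dice restricted to the true WT boundary shell.

## Numerical notes and limitations

* All coordinates are 1-based (R convention); patch corners refer to the
  low corner, boundary patches are center-indexed before clipping.
* Label files use the 0/1/2/4 convention; the network internally uses
  contiguous classes 0–3, converted losslessly at the boundary.
* `keep_largest_component` on an all-background volume returns its input
  with a zero component count rather than erroring: an empty prediction is
  a legitimate (if poor) pipeline outcome.
* The soft Dice loss has a known flat region when a small class is never
  predicted; at desk scale the reduced model reliably learns background and
  edema (hence WT) within six epochs, while the thin enhancing rim and the
  necrotic core may stay unlearned. The full-scale configuration with its
  much larger patch inventory and 100-epoch budget is the intended regime
  for those classes.
* Tile inference is strictly non-overlapping with no averaging; overlapping
  inference, data augmentation and model ensembling are deliberately out of
  scope.
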