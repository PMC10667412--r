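---
title: "Focused-view CTA: models, phantoms, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Focused-view CTA: models, phantoms, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A head-and-neck CT angiography (CTA) acquired for acute-stroke triage
covers far more anatomy than the question requires. "Focused view" CTA
blanks every voxel outside two structures to air (−1000 HU): class 1, the
brain with the cranial cavity (including intracranial arteries), and
class 2, the extracranial stroke-related arteries from the aortic arch to
the skull base. The result is a CTA in which only the vasculature relevant
to large-vessel-occlusion assessment, plus the brain, remains visible.

`focusedcta` implements the full production pipeline for this
transformation: a patch-based 3D segmentation network (basic and
dual-attention U-Net variants) trained with the categorical Dice loss
under 5-fold cross-validation with early stopping, sliding-window
inference with overlap averaging, an averaging ensemble, the masking and
DICOM-export step, a random hyperparameter search over the pipeline's
configuration space, and the statistical toolkit for reader-study
evaluation of the output. A synthetic phantom generator supplies paired
volumes and ground-truth labels, so every stage is exercisable and
testable without patient data.

## The segmentation model

The network maps an image patch (default window 160 × 160 × 48 voxels
after preprocessing) to per-voxel probabilities over the three classes,
softmax-normalized at every voxel. The encoder halves resolution
`depth` times (3 × 3 × 3 convolutions, optional instance normalization,
ReLU, 2 × 2 × 2 max pooling), the decoder mirrors it with
nearest-neighbour upsampling, a channel-reducing 1 × 1 × 1 up-convolution,
skip concatenation, and two further convolutions; a 1 × 1 × 1 head plus
softmax produces the probability field.

The *dual-attention* variant adds two parallel blocks at the bottleneck: a
position-attention block (affinity between all flattened bottleneck
voxels, transformer-scaled softmax) and a channel-attention block
(affinity between channels); each is gated by a coefficient learned from
zero and their outputs are summed into the bottleneck features. The
original description of the pipeline names the dual-attention U-Net
without specifying block placement or count; placing the canonical
position/channel pair at the bottleneck only is this package's design
choice — it gives global spatial context (useful for "inside the skull"
decisions) at workstation-scale memory, and the zero-initialised gates
mean an untrained dual-attention network starts from the basic U-Net
function. The entire network and its backpropagation are implemented in
vectorised R over BLAS matrix products, with compiled im2col/col2im
data-movement kernels; gradients are verified against central finite
differences in the test suite.

## Training procedure

Training follows the original recipe. Scans are resampled in-plane to the
configured spacing (0.5/0.7/1.0 mm; the through-plane axis is never
resampled) and normalized per volume (z-normalization over all voxels, or
division by 1000); the normalization statistics are computed once, before
cropping, so inference applies the identical transform. Randomly sampled
window-shaped crops from the training fold are augmented (in-plane
rotation, small out-of-plane tilt, additive Gaussian noise in normalized
units, each applied independently at its configured frequency) and
optimized against the mean categorical Dice loss over the two foreground
classes (smoothing constant 1e-6). After each epoch the mean foreground
Dice over the *full* validation scans — sliding-window prediction, not
patch samples — is recorded; the best-scoring weights are retained and
training stops after `patience_epochs` (default 50) epochs without
improvement. Whether the original per-epoch validation used full-scan or
patch-level Dice is unstated; full-scan Dice was chosen because it is the
quantity the protocol reports per validation fold.

Because patch sampling has no natural epoch boundary, an "epoch" is
defined as a fixed number of sampled batches (configurable, default 50).
Background-only crops are re-drawn up to a bounded number of times by
default; whether the original sampling rejected such crops is unstated,
so both behaviours are available.

Cross-validation assigns each of the five folds a disjoint random 10%
validation set, the remaining 90% forming that fold's training set —
the 90/10 × 5 arithmetic of the protocol, under which half the scans
serve as validators. (A conventional 5-fold partition would instead give
20% validation folds; the stated 90/10 split was followed.) The per-fold
best models combine into an averaging ensemble: the prediction is the
arithmetic mean of member probability maps, which needs no
renormalization.

Rotation and tilt *magnitudes* are not part of the searched space (only
their frequencies are); defaults of ±15° in-plane and ±5° out-of-plane
were chosen as modest anatomy-preserving ranges and are exposed in the
configuration. The augmentation noise factor is interpreted as the
standard deviation of additive Gaussian noise in post-normalization
intensity units, since it appears in the searched space alongside the
normalization strategy and its optimal value (0.003) is the right order
for z-normalized data.

## Inference and masking

Sliding-window inference places windows at stride
`window × (1 − overlap)` per axis, snapping the final window to the far
edge, and averages probabilities per voxel over all covering windows —
unweighted, since the protocol specifies averaging and nothing more; the
default overlap of 0.5 is a package choice. Volumes smaller than the
window are padded with the normalized image of −1000 HU. Discrete labels
are the per-voxel argmax with ties broken toward background. Predictions
computed on the resampled grid are mapped back to the native grid by
nearest neighbour, because the mask is applied to the *original* CTA:
`apply_focus_mask()` keeps labelled voxels bit-exactly and sets the rest
to exactly −1000. DICOM export fixes RescaleIntercept at −1024 with slope
1 so that −1000 HU is an exact stored integer and survives the round trip
bit-exactly.

## The phantom generator

The phantom emulates the annotation protocol's two label classes on a
simplified head-and-neck geometry: an air background at −1000 HU, a
soft-tissue body contour, a vertebra-like segmented bone column with a
spinal canal, an ellipsoidal bone skull shell with a skull-base opening,
a brain-filled cranial cavity (class 1: the full cavity interior,
matching the cavity-level rather than vessel-level first annotation
step), and tortuous contrast-opacified vessels ascending from the
inferior "aortic arch" region through the neck into the cavity
(extracranial lumina: class 2). Vessel centerlines are cubic splines
through jittered waypoints with a helical perturbation near the skull
base, so vessels run close to bone — deliberately recreating the
configuration reported hardest to segment (small-caliber, tortuous,
near-bone segments).

Default material means are air −1000, soft tissue 40, brain 30, bone
1000, opacified vessel 400 HU — plausible CTA values, configurable, and
not claimed from any source — with 10 HU additive Gaussian noise as a
typical contrast-CT noise level. The phantom does *not* model named
vessel anatomy (C1–C7/V1–V4 geometry), bolus dynamics, beam hardening, or
metal artifacts; tests passing on phantoms therefore demonstrate that the
pipeline's machinery is correct and that the training loop can learn
intensity-plus-context segmentation, not that clinical performance
transfers. In particular the brain (30 HU) and soft tissue (40 HU) means
differ by the realistic margin of 10 HU under 10 HU noise, so the cavity
class is learnable only from bone-shell context — by design.

## Scaled-down study conditions

The original model trains on 100 annotated patient scans at a
160 × 160 × 48 window with ~10⁶-parameter networks; the package's test
suite and acceptance script run the identical code path at desk scale:
20 phantoms of 48³ voxels at 1 mm spacing, a dual-attention U-Net with a
32 × 32 × 16 window, 8 base filters, and depth 2, trained for at most 30
epochs of 30 two-patch batches (Adam, learning rate 10⁻³, early-stopping
patience 10). The test suite requires a held-out mean Dice of at least
0.8 (cranial cavity) and 0.6 (extracranial arteries) under these
conditions — thresholds far below the reported 0.99/0.94 on real data,
as befits a reduced network, minutes of CPU training, and a phantom
whose cavity contrast is deliberately marginal. The phantom grid was
chosen so the cranial cavity is several window depths thick; on much
smaller grids the cavity becomes a thin lens whose voxels are almost all
boundary voxels, capping the achievable overlap for geometric rather
than methodological reasons. The
hyperparameter-search, ensembling, and statistical stages run at
similarly reduced sizes (single-point or few-trial searches on 16³
phantoms, 2000-replicate null simulations for test calibration).

## Numerical and statistical choices

* Dice loss smoothing ε = 1e-6; an "improvement" for early stopping is
  any increase in the validation metric.
* Weight initialisation is He-normal; L2 regularization applies to
  convolution and attention kernels, not biases or normalization
  parameters. Optimizers are Adam and RMSProp in their standard forms.
* The Wilcoxon signed-rank test drops zero differences (the Pratt variant
  is available), ranks with midranks, and uses exact enumeration (by
  convolution over sign assignments, valid under ties) up to 25 pairs,
  otherwise the tie-corrected normal approximation. The reference
  reader-study analysis does not state which variant produced its
  p-values, so both are provided.
* The Mann-Whitney U test uses the exact distribution for small tie-free
  samples and the tie-corrected normal approximation otherwise; the 2 × 2
  chi-square test applies the Yates continuity correction with the
  continuity term floored at zero.
* Cohen's weighted kappa defaults to linear weights (quadratic available):
  the reference analysis names weighted kappa without the scheme, and the
  reference software offers both.
* Score summaries use inclusive linear interpolation (type-7 quantiles),
  which reproduces half-integer medians on small even samples, formatted
  as `median (IQR: a-b, range: c-d)`.
* The hyperparameter search samples uniformly (log-uniformly for learning
  rate, L2, and noise factor); no adaptive/tree-structured sampler is
  used. Random search must still recover a planted optimum within a
  factor of two, which the test suite checks.

## Known limitations

* The phantom's realism bounds what the tests can show (see above);
  acceptance of the pipeline never rests on phantom realism beyond its
  stated invariants.
* Pure-R training is CPU-bound and desk-scale; full-scale windows
  (160 × 160 × 48, depth 4) run but are not practical to train here.
* DICOM support is deliberately minimal: single-series explicit-VR
  little-endian CT Image Storage, no networking, compression, or
  anonymization.
* No test-time augmentation, connected-component post-filtering, or
  learning-rate schedules — none are part of the described pipeline.
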