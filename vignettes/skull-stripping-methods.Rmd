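---
title: "Slice-wise U-Net skull stripping: model, phantom and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-wise U-Net skull stripping: model, phantom and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Skull stripping — removing every voxel of scalp, muscle and skull signal
from a head MR volume so that only brain remains — is the gatekeeper of
rodent neuroimaging pipelines: registration and group analysis fail when
non-brain signal leaks through. In rats and mice the task is harder than
in humans. The brain-to-scalp distance is a handful of voxels, tissue
contrast around the skull is weak at high field, and the skull itself is
a thin, nearly signal-free gap rather than a thick bright structure.
Intensity- and morphology-driven extractors consequently fail first in
the brainstem, the olfactory bulb and the inferior brain, where signal is
weakest.

`rodentstrip` treats the problem as slice-wise semantic segmentation. A
2D U-Net maps each axial slice to a per-pixel brain probability; a
thresholded stack of slices is the brain mask.

## The model

The network is a standard U-Net: a contracting path of convolutional
blocks, an expanding path that upsamples and concatenates the
same-resolution contracting feature map (copy skip connections), and a
single-channel sigmoid output. The contracting feature-map counts are
32, 64, 96, 128 and 256. Where the architecture's published description
leaves internals open we use the conventional choices and record them
here as our own: two 3x3 "same" convolutions + ReLU per block, 2x2 max
pooling between levels, nearest-neighbor 2x upsampling followed by a 3x3
convolution, decoder feature counts mirroring the encoder
(128, 96, 64, 32), a logistic output squashing, and no batch
normalization (the `batch_norm` flag exists so the choice is visible in
the configuration record, but only the plain variant is implemented).
"Same" padding is used so a 128x128 patch maps to a 128x128 output.

Training minimizes the Dice-coefficient loss rather than cross-entropy,
which removes the foreground/background class-imbalance problem of thin
structures:

    loss = 1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)

with smoothing `eps = 1` on the summed-counts scale. The smoothing keeps
the loss defined — and zero — when a sampled patch contains no brain at
all, so background-only patches still teach the network. The loss is
computed per patch and averaged over the batch. The soft overlap
`sum(p * t)` uses raw probabilities (no thresholding inside the loss) so
the loss stays differentiable.

The forward and backward passes, the Adam optimizer (learning rate
1e-3, batch size 16) and global gradient-norm clipping at 1 are
implemented in the package; the convolution inner loops are im2col +
GEMM in single precision via RcppArmadillo, the precision segmentation
frameworks train in. Weight initialization is He-normal, drawn
deterministically from a seed, so two builds from the same
configuration are identical parameter for parameter.

## Normalization and resampling

Two normalizations precede the network. Spatially, every volume is
resampled slice-by-slice to 0.1 mm x 0.1 mm in-plane with
nearest-neighbor interpolation; nothing is resampled across slices
because the model is 2D. Nearest-neighbor is used for images and masks
alike so both travel the same code path and masks stay binary. In
intensity, each 3D image (not each slice) is min-max normalized to
[0, 1] and stored at single precision.

Numerical rules the resampler commits to:

* output dimension = `round(dim * spacing / target)`, rounding half up
  (deterministic, unlike banker's rounding);
* the source pixel for output pixel `i` (0-based) is
  `floor((i + 0.5) / factor)` — pixel-center alignment, exactly
  invertible for integer factors;
* a constant image cannot be min-max scaled and maps to all zeros with
  a warning rather than NaN;
* slices smaller than the 128-pixel patch after resampling are
  symmetrically zero-padded (mask padding is background).

`restore_resolution()` maps a working-grid mask back to the native grid
by the same pixel-center rule; for integer resampling factors
resample-then-restore reproduces a mask exactly, which the tests assert
bit for bit.

## Training protocol

Splitting is always by subject, never by slice, so no animal contributes
slices to both sides of a split; the split can be stratified (e.g. by
strain) with `round(n * fraction)` of each stratum in training. Both
contrasts of a subject stay on the same side. One epoch shuffles the
training slices and samples one random 128x128 patch per slice, so every
slice contributes once per epoch in expectation; patches with no
foreground are kept. The inner train/validation procedure is repeated
(default five times), each repeat re-seeding both the split and the
weight initialization — the underlying protocol does not say whether the
repeats re-draw weights, so we re-draw both — and the model with the
highest averaged validation Dice is selected ("validation accuracy" is
read as validation Dice, the pipeline's loss and headline metric).
Validation segments whole slices through the tiled-inference path after
every epoch. There is no early stopping and no augmentation; the epoch
count is a configuration value so runs are reproducible.

## Tiled inference

At inference every axial slice is covered by overlapping 128x128 patches
on a 16x16 in-plane stride; overlapped predictions are averaged with
uniform weights. Patch origins step by the stride and the final origin
per axis is clamped to `dim - patch_size`, so the last pixels are
covered by real data instead of zero padding — the slice border is where
intensity extractors fail, and predicting on padded zeros there would
reintroduce exactly that artifact. The averaged probability map is
binarized at 0.5 with a strict `>` (a pixel exactly at threshold is
background; the cut is exposed as an option), and the binary mask — not
the probability map — is resampled back to the native grid, because
nearest-neighbor restoration requires a label image. An optional
largest-connected-component cleanup exists but is off by default; the
raw network output is the method's output.

## The phantom

The synthetic rodent-head phantom exists so every stage of the pipeline
can be exercised and verified without downloading data. It emulates the
failure-mode structure of real rodent MRI, not anatomy: an ellipsoidal
brain with an anterior olfactory-bulb lobe and a posterior, ventrally
shifted brainstem taper; a scalp/muscle shell separated from the brain
by a 0.3 mm near-zero skull gap; attenuated signal (default x0.7) in
the inferior third of the brain; a smooth multiplicative bias field
(exponential of a random quadratic, normalized to a +/-0.2 log
amplitude) standing in for residual coil inhomogeneity after bias
correction; and Rician noise, the magnitude-image noise law of MR.
Two presets mirror the two training contrasts: `rare_aniso`
(0.1 x 0.1 x 1 mm, 96 x 96 in-plane) and `epi_coarse`
(0.32 x 0.32 x 1 mm, 40 x 40 in-plane, which resamples to exactly
128 x 128 at the working resolution). Intensity defaults (brain 1.0,
scalp 0.55, background and gap 0.08, noise sigma 0.04) give the strong
but imperfect contrast of bias-corrected T2-weighted data.

Everything is a deterministic function of the seed; dataset subjects
use `seed + i` plus a +/-10% jitter of the brain semi-axes and a fresh
bias-field orientation, alternating the two presets. Real data differ
from the phantom in ways the tests therefore cannot probe: no partial
voluming, no susceptibility dropout or EPI distortion, no anatomical
texture inside the brain, and a geometry far simpler than a real head.
Passing the recovery study shows the pipeline's machinery — sampling,
optimization, tiling, resampling, evaluation — is correct and the model
class is adequate for high-contrast segmentation; it does not certify
accuracy on any real scanner protocol.

## Evaluation suite

With `A` the reference voxel set and `B` the prediction:
`Dice = 2|A n B| / (|A| + |B|)`, `Jaccard = |A n B| / |A u B|`,
`PPV = |A n B| / |B|`, `SEN = |A n B| / |A|`. The Hausdorff distance
`max(h(A,B), h(B,A))` with `h(A,B) = max_a min_b d(a,b)` is estimated
only in-plane (through-plane sampling is non-uniform) in voxel units,
and a subject is scored by its worst slice. Distances are computed on
boundary pixels only — the maximum is always attained there — and the
tests verify this optimization agrees exactly with the all-voxel
definition and with an exhaustive all-pairs oracle. Slices where
exactly one mask is empty contribute no distance; they are skipped and
counted in the report. An empty prediction makes PPV undefined; it is
reported as 0 with a warning so batch evaluation never aborts. Group
statistics are out of scope; reports are plain CSV so any stats package
can take over.

## The recovery study

`phantom_recovery_study()` is the desk-scale validation experiment and
what `scripts/acceptance.R` runs: simulate 24 phantoms, hold out 4,
split the remaining 20 subjects 80/20 (16 training subjects x 12 slices
= 192 training slices), train, then skull-strip the 4 held-out phantoms
at native resolution and score all five metrics. The study-size choices
— a reduced 8/16/24/32/48 feature schedule and 18 epochs (~220
optimization steps) — were fixed after observing on an independent run
that validation Dice plateaus at 0.92-0.96 after roughly 150 steps;
they make the study train a meaningful model on a single CPU in a few
minutes while the optimizer constants (learning rate, batch size,
clipping, patch size, stride) keep their standard values. Expected
outcome: mean held-out Dice >= 0.90 with SEN and PPV >= 0.85 and finite
Hausdorff distances — numbers the test suite and the acceptance script
recompute from scratch; nothing is stored.

## Known limitations

* 2D slice-wise modelling ignores through-plane context by design; the
  3D trade-off is explicitly out of scope.
* Inputs are assumed bias-corrected; the residual-bias robustness of the
  phantom is a probe, not a substitute for correction.
* A 4D functional series must be reduced to one 3D frame (or a temporal
  mean) upstream; the loader rejects 4D files with an explicit error
  rather than guessing a frame.
* The float32 GEMM path makes gradients reproducible bit-for-bit on one
  platform, but not across differing BLAS builds.
* Images whose in-plane matrix is below 128 after resampling to 0.1 mm
  are zero-padded; extreme fields of view far smaller than a rodent head
  have not been exercised.
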