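---
title: "Methods: a channel-attention shifted-window transformer for 3D brain-tumour segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a channel-attention shifted-window transformer for 3D brain-tumour segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Gliomas are evaluated in multi-modal MRI over three nested subregions:
the whole tumour (WT, everything abnormal), the tumour core (TC, the
non-edema part) and the enhancing tumour (ET, the contrast-enhancing rim),
with ET ⊆ TC ⊆ WT. Four co-registered sequences (T1, T1-contrast, T2,
T2-FLAIR) carry complementary contrast for these regions, so segmentation
networks take a 4-channel volume and emit three *overlapping* binary
channels — which is why the output head is a per-channel sigmoid, never a
softmax.

`catseg` implements a hybrid transformer/CNN encoder-decoder for this task:

1. **Shifted-window transformer encoder.** The volume is partitioned into
   2×2×2 patches and linearly embedded (width 48 by default). Four stages
   of two transformer blocks each follow; the blocks compute multi-head
   self-attention inside local 3D windows (7×7×7 tokens by default),
   alternating between a regular and a half-window-shifted partition so
   that information crosses window borders. Stages 2–4 are preceded by a
   patch-merging layer that concatenates 2×2×2 token neighbourhoods and
   projects them to twice the width; a final merge after stage 4 yields the
   deepest map. Together with a 1×1×1 projection of the raw input at full
   resolution ("level 0"), the encoder exposes six feature maps at
   resolutions 1, 1/2, …, 1/32 with widths 48, 48, 96, 192, 384, 768.
   Level 0 is required to make the counts close: six encoding blocks and
   five decoder blocks only wire up if one encoder output lives at full
   resolution, and its stated width (48 at H×W×D) matches exactly this
   projection.
2. **Channel shuffle.** Each of the five transformer-derived maps is
   passed through a parameter-free channel permutation: channels are
   reshaped into G groups (default G = 4, matching the four modalities),
   the group and within-group axes are transposed, and the result is
   flattened. This lets information flow between channel groups and acts
   as a structural regulariser. It is exactly invertible
   (`shuffle(shuffle(x, G), C/G) = x`) and is disabled by a single config
   flag for ablations.
3. **CAT encoding blocks.** Each of the six maps then passes through a
   convolutional encoding block: 3×3×3 convolution (stride 1, padding 1,
   preserving extent), 3D batch normalisation, a channel-attention module,
   and a LeakyReLU. The attention module is squeeze-and-excitation style:
   global average pooling per channel, a bottleneck pair of fully
   connected layers C → C/r → C (r = 4), and a sigmoid gate multiplying
   each channel.
4. **Residual decoder.** Five decoder blocks walk back up the ladder: the
   deeper map is upsampled 2× per axis (transposed convolution by default,
   trilinear interpolation + 1×1×1 convolution as an option), concatenated
   with the CAT output at the shallower level, and passed through a
   residual unit (two 3×3×3 conv + batch-norm layers around a projected
   shortcut). A 1×1×1 convolution and sigmoid produce the three subregion
   probabilities.

Training follows the published recipe: soft Dice loss, AdamW, and a
single-cycle cosine-annealed learning rate
`lr_t = lr_min + (lr_max − lr_min)(1 + cos(π E_curr/E_max))/2`.

## Why pure R

No deep-learning framework is assumed. The package carries a small
reverse-mode automatic-differentiation core (`R/autograd.R`): every layer
is a BLAS-backed matrix operation with a hand-written vector-Jacobian
product, and each one is verified against central finite differences in
the test-suite. Feature maps travel as (voxels × channels) matrices;
convolutions, patch partitions and window partitions reduce to cached
integer index tables, so the same code path serves inference (plain
matrices) and training (tape-wrapped leaves).

## Design choices where the published description is open

* **Label codes.** The subregions are named but their integer codes are
  not; the BraTS convention is used ({1: necrotic core, 2: edema,
  4: enhancing}; WT = 1∪2∪4, TC = 1∪4, ET = 4) behind a replaceable code
  table. Nesting violations in data are *reported* (warning + attribute),
  never silently repaired.
* **Preprocessing.** Only the input extent (128×128×96×4, i.e.
  (z,y,x) = (96,128,128) channel-first) is fixed by the architecture;
  normalisation and resizing are not specified. The package z-scores each
  modality over its nonzero (foreground) voxels — zero-variance channels
  map to zeros with a warning — and centre-crops/zero-pads to the target
  extent. Crop/pad (rather than resampling) keeps label topology exact.
* **Global average pooling in 3D.** The attention equation is printed in
  2D (mean over W×H); the network is volumetric, so the mean is taken over
  W×H×D. The printed form is read as notational shorthand.
* **One vs two attention FC layers.** The architecture section says one
  fully connected layer, the discussion says two. Two layers with a
  reduction bottleneck (r = 4, configurable) are implemented — the
  squeeze-and-excitation form both readings point at.
* **LeakyReLU slope** 0.01 everywhere (unstated), also as the
  nonlinearity between the attention FCs.
* **Windows.** 7×7×7 windows, clipped per level to the token grid; shifted
  blocks shift by half the (clipped) window with cyclic shift + additive
  attention masking. Grids are right-padded to window multiples and pad
  tokens are masked out of attention entirely. Learned relative-position
  biases are indexed so a clipped window addresses a subset of the full
  window's table.
* **No key bias.** The packed qkv projection carries biases only for
  queries and values: a constant shift of every key cancels in the softmax,
  so a key bias is a provably dead parameter (its gradient is identically
  zero). Omitting it keeps the "every parameter receives gradient"
  invariant meaningful.
* **Patch merging factor.** "Downsamples the number of patches by a factor
  of 2" is read as a factor of 2 *per axis* (8× fewer tokens), the only
  reading consistent with the printed 768-at-1/32 ladder.
* **Decoder internals.** The residual decoding blocks are unspecified;
  a Swin-UNETR-style unit is used (concatenation merge, two conv+BN
  layers, projected shortcut), with transposed-convolution upsampling by
  default.
* **Scheduler bookkeeping.** The learning-rate formula names `lr_max` as
  "the maximum number of epochs" — an evident typo for `E_max`. The
  schedule is stepped once per epoch ("at each validation"), single cycle;
  warm restarts are not implemented (`E_curr` is epochs since start).
* **AdamW details.** Only the optimiser name and the initial rate 5×10⁻⁵
  are given. Weight decay 0.01 with default betas, applied (decoupled) to
  weight matrices/tensors only — biases, norm affines and position tables
  are not decayed.
* **Metric conventions.** Empty-vs-empty DSC/IoU score 1 (a correctly
  absent region, which happens with small ET); a Hausdorff distance
  against an empty mask returns a configured penalty (default: the grid
  diagonal in mm) and flags the case. Both directed (as printed) and
  symmetric Hausdorff are available, plus HD95; reports default to the
  symmetric maximum. Standard deviations are sample (n−1) statistics.
  Distances use voxel spacing in mm. Soft-Dice smoothing ε = 10⁻⁵.

## The synthetic-data generator

`generate_phantom()` emulates the *structure* of BraTS-style data, not MR
physics: a homogeneous background (level 100), three concentric (optionally
ellipsoidal) subregions whose contrast offsets accumulate per modality in
the canonical directions (edema bright on T2/FLAIR, enhancing rim bright on
T1-contrast, core dark on T1), plus additive Gaussian noise (σ = 4 by
default; salt-and-pepper available to mimic heavier acquisition
artefacts). Masks are the exact noise-free geometry, so nesting holds by
construction. `generate_cohort()` jitters radii, centre, contrast and
optionally noise through one seeded stream in a documented draw order, so
any case is replayable from the cohort seed.

What a green test on phantoms does establish: shapes, gradients,
optimisation behaviour, metric semantics, serialisation, determinism. What
it does not: clinical segmentation accuracy — phantoms have none of the
anatomy, bias fields, resolution anisotropy or annotation noise of real
cohorts, and the published benchmark numbers (means over hundreds of
external cases after GPU-scale training) are out of reach at desk scale by
design.

## Desk-scale defaults

The test-suite and the acceptance script run a reduced geometry
(`catseg_tiny_config()`: embedding width 8, 16³ volumes, 4×4×4 windows, two
heads per stage) that keeps the complete six-level architecture. At this
size AdamW needs a much larger step than the full-scale recipe, so
`tiny_train_config()` uses `lr_max = 10⁻²` (cosine to 0), chosen once as a
standard small-network Adam rate; four phantoms overfit to a training mean
DSC above 0.95 in well under 200 epochs on one CPU.

Two numerical notes. Batch normalisation with volume-wise batches of one
normalises over the voxel population; running statistics use the standard
momentum-0.1 update and are what inference consumes. And on a 1³ token
grid, attention over a single key and batch norm over a single voxel have
*identically* zero gradients for the position bias/query path and the norm
gain — a property of the degenerate geometry, not a dead branch; the
gradient-coverage test therefore probes an extent (64×32×32) where no
level collapses to a single voxel.

## Known limitations

* CPU-bound pure-R training is practical at phantom scale only; full-width
  forward passes are feasible but slow, and full-scale training is not the
  package's purpose.
* Single-window inference: volumes are processed whole (padded to
  divisibility by 32 internally); no sliding-window tiling.
* No pretrained weights, no test-time augmentation, no DICOM ingestion,
  no bias-field or registration preprocessing (assumed done upstream, as
  in the released datasets).
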