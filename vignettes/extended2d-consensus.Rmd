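---
title: "Extended-2D consensus segmentation: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended-2D consensus segmentation: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The method

`e2dseg` segments small bilateral brain structures (the motivating case is
the hippocampus) in T1-weighted MRI using an ensemble of three 2D
fully-convolutional networks, one per anatomical plane. Each network sees
*extended-2D* input: the slice to be segmented plus its two neighbouring
slices stacked as three channels, which gives a planar model a slab of
volumetric context — much as a radiologist flips between adjacent slices
before deciding whether a voxel belongs to the structure.

The pipeline for one volume is:

1. **Canonical reorientation.** The voxel axes are permuted/flipped (never
   resampled) so that axis 1 runs left–right, axis 2 posterior–anterior,
   axis 3 inferior–superior. The transformation is recorded and inverted at
   the end, so the output mask is always on the input grid with the input
   affine.
2. **Per-volume minmax normalization** of intensities to $[0,1]$ — over all
   voxels of the volume, not per slice, and with no percentile clipping. A
   constant volume is an error rather than a silent zero.
3. **Slice-wise prediction** per orientation. Each full slice is
   center-cropped to the largest size divisible by $2^D$ (the network's
   downsampling depth), forwarded, and the resulting probability map is
   written back at the recorded crop offsets; voxels outside the crop stay
   exactly 0. The bookkeeping is bit-exact: with an identity stub model the
   assembled activation equals the input inside the crop window.
4. **Consensus**: the voxelwise arithmetic mean of the three activation
   volumes.
5. **Binarization** at a threshold $t$ (default 0.5), with strict `>`: a
   voxel exactly at the threshold is background. The strictness is a
   deterministic tie rule, not a tuned choice.
6. **Largest-component filtering** under 26-connectivity: up to 2
   components are kept (the structure is bilateral), or 1 if a second is
   not present. Ties at the size cut go to the component appearing first in
   column-major scan order, making the output reproducible.

## Networks

Each orientation's network is an encoder–decoder with skip concatenations.
Every level is a double block of [3×3 same-padded bias-free convolution →
batch normalization → ReLU] ×2, with a parallel 1×1 convolution from the
block input added to the block output (a residual path that also adapts
channel counts). Downsampling is 2×2 max pooling, upsampling a 2×2
stride-2 transposed convolution (the upsampling operator is a design
choice; nothing in the method constrains it), and the head is a 1×1
convolution into either a single sigmoid channel (used with the Dice loss)
or a two-channel softmax (used with the generalized Dice and boundary
losses). Default depth is $D = 4$ with a configurable base width
(default 16, doubling per level); the test and demo configuration uses
width 8, depth 3, which is ample for the phantom task and fast on one CPU.

There is no deep-learning framework dependency: forward, backward and the
Adam optimizer are implemented in the package (im2col + BLAS GEMM for the
convolutions, with the gather/scatter kernels in C++). Backpropagation is
verified against central finite differences through the entire network in
the test suite, and evaluation-mode inference is a pure function —
bit-reproducible across runs on the same platform.

An encoder-initialization hook (`network_config(encoder_init = ...)`)
accepts a function that can overwrite encoder weights, e.g. with
pretrained values; by default initialization is seeded He-normal draws.

## Training

Training patches are sampled *at runtime*, never pre-materialized, so the
network effectively never sees the same patch twice across epochs. A
configurable fraction (default 0.8) of patches is **positive**: centered
on a voxel of the structure's inner border (mask voxels with a background
6-neighbour; the mask minus its erosion). The rest are **negative**:
centered anywhere in the head, defined as normalized intensity above 0.05.
Border-centered positives concentrate learning where segmentation is
decided; negatives teach what the structure is *not*. Patch windows are
clamped to lie inside the slice, and the three channels replicate the edge
slice at the volume boundary (avoiding artificial zero channels).

Augmentation draws, per patch: an intensity shift in $[-0.05, 0.05]$, a
rotation in $[-10°, 10°]$ and a scale change in $[-10\%, 10\%]$ (applied
jointly as one bilinear warp to all channels and the target, the target
re-binarized at 0.5), plus pixelwise Gaussian noise with mean 0 and
variance 0.0002 on the channels only, with final clipping to $[0,1]$. A
zero-range configuration is exactly the identity.

Three loss functions are provided:

* **Dice loss** $1 - \frac{2\sum p_i g_i}{\sum p_i^2 + \sum g_i^2 + \varepsilon}$
  (squared-denominator soft Dice) on the sigmoid head.
* **Generalized Dice loss** on the softmax pair, with label weights
  $w_l = 1/(\sum_i g_{li} + \varepsilon)^2$ countering the
  background/foreground imbalance. $\varepsilon = 10^{-6}$ throughout.
* **Boundary loss** $B = \alpha\,G + (1-\alpha)\,S$, where $S$ is the mean
  of the predicted foreground probability times the target's signed
  Euclidean boundary-distance map (negative inside, zero on the inner
  boundary, positive outside), and $\alpha$ anneals linearly from 1 in the
  first epoch to 0 in the last. The linear schedule is a design choice:
  only the endpoints are prescribed, and the schedule function is
  pluggable. Patches whose target is empty or full have no defined
  distance map; such patches (legitimate among negatives) contribute
  through the regional term only, rather than being discarded.

Losses are computed batch-wise by summing voxel sums over the whole batch
before the ratio ("batch Dice"), which stabilizes patches containing
little foreground. Optimization uses Adam at learning rate $10^{-3}$
(batch 16); model selection keeps the parameters with the best validation
soft Dice, computed each epoch on patches drawn from the validation
subjects with an epoch-fixed seed. Every random stream (splits, sampling,
augmentation, initialization) derives from one master seed through named
substreams, so any component can be reproduced in isolation.

The hold-out protocol is stratified (80/10/10 by default; any fractions
are supported, e.g. 70/10/20 for mixed-cohort experiments) with
largest-remainder rounding per stratum; k-fold plans have pairwise
disjoint test sets that partition the cohort. Multi-cohort training is the
same code path — only the split plan differs.

## The phantom generator

Real T1 cohorts with manual labels cannot ship with a package, so the
study conditions are emulated by a seeded phantom: a smooth ellipsoidal
"brain" at intensity 0.3, two mirror-placed *curved* (bent prolate)
ellipsoids at 0.6 (a straight ellipsoid would present unrealistically
isotropic borders to the border-centered sampler), Gaussian noise with
$\sigma = 0.03$, and per-subject jitter in structure size, position and
curvature. Patient phantoms have one structure removed and replaced by a
dark cavity whose rim keeps a textured shell plus a few small nodular
remnants at full structure intensity. That rim is deliberate: false
positives in resection cavities are attributed to residual structure-like
texture in the structure's location, and the phantom reproduces exactly
that trap for models trained on intact anatomy — a rim that merely
brightens toward background level does not fool a well-trained ensemble,
so the remnants carry genuine structure intensity.

What the phantom does **not** model: MRI physics (bias fields,
partial-volume effects), anatomical surround (other bright structures,
skull, neck), inter-scanner intensity distributions, or genuinely
pathological atrophy. Passing the end-to-end tests therefore demonstrates
that the pipeline's machinery — sampling, optimization, consensus,
post-processing, evaluation conventions — works and that the domain-shift
signature (resection false positives) emerges; it does not certify
clinical-grade accuracy on real MRI.

## Evaluation conventions

Per subject we report Dice over both structures and over the left and
right halves separately (the grid is split at the mid-sagittal plane;
mid-plane voxels of an odd extent go to the left half), plus voxelwise
precision and recall. Component-based laterality assignment was rejected:
it would silently absorb exactly the contralateral false positives the
per-side metrics are meant to expose. Conventions for empty masks: Dice is
1 when both masks are empty and 0 when only one is; precision/recall 0/0
denominators give 1 only when both masks are empty, else 0. These
conventions are what make a hallucinated mask on a resected side score 0
and drag the cohort mean down. Summaries are mean ± population standard
deviation per cohort tag.

## Problem sizes and numerical choices

The reference experiment (`run_phantom_demo()`, also what
`scripts/acceptance.R` runs) uses 64³ phantoms: 20 training + 4 validation
+ 8 held-out control subjects and 8 resected patients, three width-8
depth-3 networks trained for 15 epochs × 512 patches with the Dice loss.
These sizes were chosen as the smallest study at which the full method —
three orientations, runtime sampling, consensus, post-processing, per-side
evaluation — is exercised meaningfully on a single desktop CPU core.

Training patches in the demo are 32² rather than the package default of
64²: on a 64³ grid a 64² patch *is* the whole slice, which would collapse
the distinction between border-centered positive patches and head-sampled
negative patches; 32² keeps the patch sampler's semantics intact at
phantom scale. For real-resolution volumes (≈180² slices) the 64² default
stands. The boundary and generalized Dice losses are fully implemented and
verified (limit identities, gradient checks, training smoke tests); the
demo trains with the plain Dice loss, the simple and robust default for a
single-structure task.

Other fixed numerical choices: the final 1×1 convolution is initialized at
one tenth of the He scale, keeping initial output probabilities near 0.5 —
region losses drive saturated-but-wrong pixels through a vanishing
sigmoid/softmax gradient, and a confident random head can freeze such
pixels irrecoverably; batch-norm $\varepsilon = 10^{-5}$ with
running-statistics momentum 0.1; binarization threshold 0.5 with strict
inequality; 26-connectivity for 3D labeling; component ties broken by scan
order; Dice stabilizer $\varepsilon = 10^{-6}$ (which is why a perfect
prediction scores $1 - O(\varepsilon)$ rather than exactly 1 in the soft
form, while the binary evaluation Dice is exact).

## Limitations

* MNI152 registration is not performed internally; a command-template hook
  (`--register` / `--apply-inverse` on the predict subcommand) lets an
  external tool align oblique volumes, and reorientation handles only
  axis permutations and flips. Volumes whose affine is so oblique that no
  dominant axis mapping exists are rejected rather than silently guessed.
* Native grids are sliced as-is; there is no resampling to isotropic
  spacing, bias-field correction, or skull stripping.
* The consensus is an unweighted mean of exactly three orientations;
  learned consensus generators and test-time augmentation are out of
  scope, as are surface-distance evaluation metrics.
* CPU-only by design: practical for the phantom-scale studies here and for
  single-volume inference; training at clinical resolution would want a
  GPU framework.
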