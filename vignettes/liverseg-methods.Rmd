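---
title: "Adversarial 2.5D VNet liver segmentation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial 2.5D VNet liver segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liverseg)
```

## The problem and the model

Liver segmentation in abdominal CT labels every voxel of a 3D scan as liver
or background. Full 3D convolutional networks capture through-plane context
but are expensive; pure 2D networks ignore it. This package implements a
*2.5D* compromise: each axial slice is presented to the network together
with its upper and lower neighbours, and the network predicts the centre
slice only. Anisotropic kernels factorize feature extraction into an
intra-slice 1x3x3 convolution followed by an inter-slice 3x1x1 convolution
(each with batch normalization and ReLU) -- a separable alternative to a
3x3x3 kernel with roughly a third of the parameters.

The segmentation network is a VNet-style encoder-decoder:

* five encoder stages at channel widths 32, 64, 128, 256, 256, each two
  series convolution blocks plus a short-range residual connection;
* strided 1x3x3 convolutions (stride 2 in-plane) instead of pooling between
  stages;
* four decoder stages, each a stride-2 transposed convolution that doubles
  the in-plane size, channel concatenation with the skip feature, and a
  residual series block;
* *chained residual pooling* (CRP) on every skip connection: two chained
  units of size-preserving 1x5x5 max pooling followed by a 1x3x3
  convolution, batch normalization, ReLU and dropout, each unit added to a
  running sum that starts at the skip input. CRP enlarges the receptive
  field of the skip pathway at constant resolution; with zero convolution
  weights it degenerates to the identity, so it can only add information;
* a final 1x1x1 projection read out at the centre slice through a sigmoid
  (or a channel softmax when a two-channel head is configured).

Training is adversarial in the Wasserstein GAN sense. A small CNN critic
scores fused (candidate mask, annotation) stacks with a single unbounded
linear output; its capacity is constrained by clipping every weight into
`[-c, c]` after each update. The critic minimizes
`mean(fake scores) - mean(real scores)`; the generator receives
`-mean(fake scores)` as an adversarial term on top of its segmentation
loss.

## Losses

The segmentation objective is a weighted composite of a region term and a
boundary term,

```
L = alpha * L_Dice + (1 - alpha) * L_BD,    alpha = 0.1 by default,
```

with the soft Dice loss `L_Dice = 1 - 2 sum(p t) / (sum(p) + sum(t))` and
the boundary loss `L_BD = mean(phi_G * p)`, where `phi_G` is the signed
Euclidean distance map of the ground-truth region `G`: zero on the boundary
pixels of `G` (foreground pixels with a 4-adjacent background neighbour),
negative strictly inside, positive outside. The boundary loss rewards
probability mass inside `G` in proportion to its depth and penalizes mass
outside in proportion to its distance, so it is minimized exactly by the
indicator of `G`; it is zero when the prediction coincides with `G`.

Numerical conventions worth stating:

* The boundary integrand is **averaged** over the image domain (a `"sum"`
  reduction is available). Averaging keeps the balance implied by `alpha`
  independent of image size; whether the continuous integral is normalized
  is a genuinely open choice and this is ours.
* The distance transform is the exact Euclidean distance to the boundary
  pixel set, computed per 2D slice (the network predicts one centre slice
  at a time), with the image border not treated as background.
* The Dice smoothing constant (1e-6) enters only when both regions are
  empty, so the identities `dice_loss(m, m) = 0` and
  `dice_loss = 1 - dice_coefficient` hold exactly on binary inputs.
* An optional linear `alpha` schedule is deliberately **not** provided: the
  composite is static; the boundary term's share of the total naturally
  grows during training as the Dice term saturates.

Degenerate slices -- masks that are all background or all foreground --
have no boundary, so their signed distance map is undefined. Such slices
contribute the Dice term only during training, and `signed_distance_map()`
refuses them with an error.

For ablation studies the training loop also exposes thin baseline
objectives (`loss_config(type = ...)`): Dice alone, boundary alone, soft
IoU, and binary cross-entropy. These mirror the usual loss-comparison
experiment structure; the composite is the method and the default.

## Parameter accounting

`count_parameters()` counts exactly the trainable scalars. Batch
normalization here is non-affine (pure standardization): the adjacent
convolutions carry bias and scale freedom, so the learnable gamma/beta
would be redundant, and with this convention layer counts reproduce the
biased closed forms `Cin * K * Cout + Cout` (convolutions) and
`Fin * Fout + Fout` (fully connected) with no hidden terms. Both kernel
modes are implemented: `series` (the method's separable kernels, the
default) and `full3d` (single 3x3x3 kernels), the latter matching the
published per-layer counts such as 442496 for a 128-to-128 block and
3539456 for the 256-to-512 deconvolution. The published decoder counts are
consistent only with channel *concatenation* at the skip fusion (e.g.
5308672 = 768 x 27 x 256 + 256 for the block after the first
deconvolution), which is why concatenation rather than addition is used.

## The network core

No deep-learning framework is attached: the package carries a compact
layer-based network core with explicit reverse-mode differentiation.
Tensors are plain arrays in `(channels, height, width, depth, batch)`
layout; convolutions are evaluated as a single BLAS GEMM over an im2col
patch matrix, transposed convolutions as zero-dilation followed by a
stride-1 convolution, and 1x5x5 max pooling separably (rows then columns).
The backward pass of every layer is checked against central finite
differences in the test-suite; the only tolerated disagreements are
subgradient ties at ReLU/max-pool kinks, which finite differences cannot
resolve. The optimizer is RMSProp, the customary companion of
weight-clipped Wasserstein critics (momentum interacts badly with
clipping); rates default to 5e-5.

## The synthetic phantom generator

Phantoms stand in for clinical CT so that every component is testable
without external data. Each phantom is a randomly oriented ellipsoid whose
semi-axes are drawn from `radius_range` (a fraction of each volume extent),
deformed by a low-frequency sinusoidal perturbation of the radius. Because
the perturbation is radial about the centre and its relative amplitude is
capped below 1, the region stays star-shaped and hence a single connected
component. Intensities are two plateaus plus Gaussian noise: foreground 100,
background -50, noise SD 15 -- liver-like contrast *after* CT windowing,
placed inside the default [-200, 250] HU display window so the
window-normalization defaults exercise a realistic dynamic range. Per-case
seeds are derived from the dataset seed by a Lehmer-style integer mix, so
cases are independent yet the whole dataset is a pure function of its spec;
repeated runs are byte-identical on disk.

What the phantoms deliberately do not emulate: tumors, vessels, multi-organ
context, beam hardening, partial-volume effects, or anisotropic spacing.
Passing tests on phantoms therefore establishes that the architecture,
losses, gradients and I/O behave as specified -- not that clinical-grade
accuracy is reached on real scans, which requires the full training
datasets and far more compute.

## Verification runs and problem sizes

The package verifies itself at desk scale, with sizes chosen to keep the
full suite fast while still exercising every code path:

* signed-distance maps are compared with an exhaustive
  nearest-boundary-pixel search over sampled binary masks on all grid sizes
  up to 6x6;
* the overfitting run trains the full adversarial loop (one critic update
  with clipping per generator step, lambda = 0 so the segmentation loss is
  the sole generator signal) for 200 steps on the 8 slice-triplets of one
  32x32x8 phantom, using a slimmed generator (stage widths 4, 8, 16, 16,
  16) and critic; it reaches a training-set Dice well above 0.90, which
  establishes that the loss/gradient plumbing works end to end. The
  learning rate for this run is 1e-3: deliberately hotter than the
  conservative 5e-5 training default, appropriate for rapid memorization of
  eight samples;
* data I/O round trips are checked for bit-exactness on integer masks and
  noiseless volumes.

## Data handling choices

* Axis convention `(depth, height, width)`, axial slices along the first
  axis, 1-based indices as is natural in R. NIfTI files store the usual
  x/y/z order; readers and writers permute so round trips are exact.
* Edge slices of a volume get their missing neighbour by edge replication,
  so predictions cover every slice.
* DICOM series are ordered by the projection of the image-position vector
  onto the slice normal -- never by filename; files lacking position tags
  fall back to instance numbers with a warning. Rescale slope/intercept are
  applied on read.
* The HU window defaults to [-200, 250] (a typical liver window) and is
  configurable; no claim is made that this matches any particular published
  preprocessing, which is typically unstated.
* In-plane sizes must be divisible by 16 (four halvings); other sizes are
  zero-padded with a note and cropped back on output.

## Known limitations

* CPU-only and single-threaded by design of the plain-R core; training
  throughput is suited to method verification and small studies, not to
  full-scale clinical training runs (which the CLI nevertheless supports
  operationally).
* The critic scores (mask, annotation) pairs; conditioning on the CT slice
  itself is available by setting `in_channels = 3` in `critic_spec()` but
  is off by default.
* No resampling or in-plane resizing is performed: volumes are segmented
  at native resolution, zero-padded to a multiple of 16 when necessary and
  cropped back.
* Plain weight clipping is the only Lipschitz device (no gradient penalty
  or spectral normalization).
* MRI-specific intensity normalization is not provided; generic min-max
  windowing applies.
* The published channel narration for the critic (64, 64 then 32, 32)
  shrinks capacity with depth, which is unusual; it is implemented as
  stated rather than corrected. Likewise the final two decoder
  deconvolution rows of the published parameter table cannot be
  reconstructed from the text and are not modelled.
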