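---
title: "Feature-aligned decoding for pneumothorax CT segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-aligned decoding for pneumothorax CT segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Pneumothorax — air in the pleural cavity — appears on axial chest CT as a
low-attenuation crescent between the collapsed lung and the chest wall.
Automatic pixel-level segmentation supports fast triage, but clinical
deployments also need small models. `efanet` implements an encoder–decoder
network built for that trade-off:

* **Encoder.** A single-channel stem (3×3 convolution, stride 2) followed by
  five stages of mobile inverted bottleneck convolutions (MBConv: 1×1
  expansion, 3×3 depthwise convolution, squeeze-and-excitation gating, 1×1
  projection, residual skip when shape-preserving). Taps after the stem and
  after stages 2–5 yield a five-level feature pyramid
  $F_i \in \mathbb{R}^{C_i \times H_i \times W_i}$ at strides 2, 4, 8, 16, 32 —
  for a 256×256 input, spatial sides 128/64/32/16/8.
* **Feature-alignment decoder.** Each pyramid level is mapped by a learned
  1×1 convolution to a common latent width $C$ and its feature vectors are
  treated as *latent codes* $z$ placed at continuous coordinates $x$ (pixel
  centers) in the unit square. For a query coordinate $x_q$, the decoder
  gathers, at every level $i$, the nearest code $z_i^*$, the offset
  $\delta x_i = x_q - x_i^*$, and its sinusoidal position encoding
  $\psi(\delta x_i) = (\sin \omega_1 \delta x_i, \cos \omega_1 \delta x_i,
  \ldots, \sin \omega_L \delta x_i, \cos \omega_L \delta x_i)$, then applies a
  shared MLP:
  $D(x_q) = f_\theta\big(\{z_i^*\}_{i=1}^5, \{\psi(\delta x_i), \delta x_i\}_{i=1}^5\big).$
  Because $D$ is defined at *every* coordinate, masks can be decoded at any
  output resolution from one forward pass of the encoder, with no bilinear
  upsampling (whose smoothing the alignment approach avoids) and no
  retraining.

The decoder input width is exactly $5\,(C + 4L + 2)$; with the package
defaults $C = 64$, $L = 8$ that is 490.

## Coordinate frame and numerical conventions

Several conventions are deliberate, documented choices; all are exercised by
the test suite:

* **Global frame.** All levels and query grids share the unit square with the
  pixel-center convention: cell $(r, c)$ (1-based) of an $H \times W$ grid
  sits at $((r-0.5)/H,\,(c-0.5)/W)$. This makes offsets across levels
  commensurable. Rows run top to bottom, columns left to right, everywhere.
* **Nearest-code ties.** A query equidistant from several codes resolves to
  the smallest row, then the smallest column. On an axis-aligned grid the
  two axes decide independently, so this matches lexicographic tie-breaking
  of the full Euclidean argmin (verified against brute-force search).
* **Frequencies.** $\omega_l = 2e^l$, $l = 1 \ldots L$, taken literally; the
  base and $L$ are configurable through `pe_spec()` (a base of 2 recovers
  the power-of-two ladder common in coordinate networks) but the printed
  natural-exponential ladder is the default and is not silently switched.
* **Offsets** are expressed in the global frame, not rescaled per level, so
  their magnitude at level $i$ is bounded by half a cell, $0.5/H_i$.
* **Argmax ties** in mask prediction go to the background class.
* **Stride-2 padding** is "same": one zero pixel on every side of a 3×3
  kernel, output side $\lceil H/2 \rceil$.
* **Batch normalization** follows each convolution (biased batch variance,
  momentum 0.1 running statistics; inference uses the running statistics).
  Activations are swish in the encoder, rectifiers in the read-out MLP.

## Preprocessing

CT slices are read from DICOM (a minimal explicit-VR little-endian reader
and writer are built in, with rescale slope/intercept applied on read) or
NIfTI (via RNifti, header scaling applied). Hounsfield windowing is a linear
ramp with clipping: `clip((HU - (center - width/2)) / width, 0, 1)`.

The protocol's printed window pair is width 1500 / center 600, and
`window_spec()` keeps those defaults. The conventional lung window, however,
places the center at −600 HU; with a center of +600 everything below
−150 HU — lung parenchyma, pleural air and background air alike — clips to
zero and the lung fields vanish. Because the two readings differ only in the
sign of the center and the positive reading destroys the very structures
being segmented, the phantom training pipeline defaults to the lung window
(`lung_window()`, width 1500, center −600), under which the phantom's three
HU anchors map to distinct, ordered intensity bands. Both choices remain
run-time configurable.

Images are resized to the model grid (512 → 256 in the clinical protocol)
with pixel-center-aligned bilinear interpolation; masks use nearest-neighbor
so they stay binary.

## Synthetic phantoms

The clinical dataset behind the method (60 patients, axial slices with
pixel-level annotations) is private, so the package ships a phantom
generator that emulates its geometry at the level the pipeline needs: a
soft-tissue body ellipse (+40 HU) on air (−1000 HU), two lung ellipses
(−800 HU, roughly collapsed-lung attenuation), and, with probability 0.72
(matching the clinical slice mix of roughly 12.5k lesion slices in 17.3k),
a pleural-air crescent at −950 HU formed as the set difference between a
lung ellipse and a shrunken, rim-shifted copy of itself, plus Gaussian HU
noise (sd 20). The crescent is the mask. Every sample derives
deterministically from `(seed, index)`, so datasets are order-independent;
patient-style grouping ids support patient-level splits.

What the phantom does *not* emulate: real parenchymal texture, mediastinal
anatomy, partial-volume effects, 3-D continuity between slices, scanner
artifacts. Passing tests therefore demonstrate that the implementation
learns and decodes correctly on separable synthetic data — not clinical
performance, whose headline numbers require the private dataset.

## Training

Softmax cross-entropy over two output channels (resolving the protocol's
one-vs-two-channel ambiguity in favor of two-class logits), Adam with a
constant learning rate of 0.001, batch size 16 by default (the ablation
protocol's value; desk-scale runs use 8). All randomness — weight
initialization, data order, query sampling — flows from explicit integer
seeds, and training is bit-reproducible on CPU. When validation data is
given, the best-validation-Dice parameters are retained.

Coordinate read-outs permit two sampling levers. First, instead of
evaluating the loss at every output pixel, each step may sample a random
subset of query coordinates per image (`queries_per_step`); uniform
sampling keeps the loss an unbiased estimate of the full-grid loss. Second,
because lesions occupy only a few percent of pixels, the sampler can draw a
fixed fraction of each image's queries from its lesion pixels
(`positive_fraction`) — class-balanced query sampling, the coordinate-space
form of class-weighted cross-entropy and the standard remedy for foreground
imbalance in segmentation. Both are off by default (plain full-grid
cross-entropy, as in the clinical protocol); the desk-scale runs below
enable them.

Desk-scale problem sizes used throughout the test suite and the acceptance
script — chosen so a laptop-class single core trains in minutes: phantoms
rasterized directly on the 64×64 model grid; the "tiny" encoder (channels
8/8/16/24/32/48, one block per stage, expansion 2); latent width 32;
read-out hidden layers 128/128; L = 8. The memorization check overfits 8
phantoms for 300 steps at the protocol learning rate with 2048 sampled
queries per image. The generalization run trains on 160 phantoms (8 more
for validation) for 110 epochs with 512 balanced queries per image at
learning rate 0.003, then evaluates 64 phantoms the model has never seen.
The "b5like" preset reproduces an EfficientNet-B5-style schedule for larger
runs. The printed model-size figures of the source protocol (≈0.43M
parameters, ≈1.5G FLOPs) cannot be reconciled with a stock B5 encoder, so
the package treats model size as a *reported* quantity —
`count_parameters()` and `estimate_flops()` (MACs of convolutions and dense
layers; normalization, activations and pooling excluded) — rather than a
target.

Two observations worth recording for users training at desk scale. With
plain cross-entropy on heavily imbalanced masks, lesion logits rise in a
calibrated fashion and cross the argmax threshold very late: loss falls
long before Dice moves, and balanced query sampling is what makes short
runs produce usable masks. And with few, geometrically diverse training
images, the deep pyramid levels' position information gives the read-out a
pixel-identity shortcut — small training sets memorize lesion *locations*
rather than appearance. Training-set diversity (more phantoms, which cost
nothing to generate), not architectural surgery, is the remedy; the
generalization run's 160 training phantoms were sized accordingly.

## Design decisions on open points

* The deepest pyramid tap is the final stage output at stride 32.
* $\psi$ is one shared encoding applied per level (levels differ in their
  offsets, not their frequency ladder).
* Per-level offset rescaling (multiplying $\delta x_i$ by $H_i$) exists as a
  switch but defaults off, keeping the printed formulation.
* Aggregated evaluation reports both pooled confusion counts (headline) and
  per-slice means, since the protocol does not state which its tables use;
  degenerate denominators follow a documented convention (empty prediction
  of an empty reference counts as a correct rejection).
* Lesion-free slices are included in training by default, as in the
  clinical slice mix; a switch excludes them.

## Limitations

The implementation is pure R (BLAS-backed); it trains desk-scale models in
minutes but is not a GPU training stack. DICOM support is the minimal
explicit-VR little-endian subset the pipeline needs. The phantom is a
geometric stand-in, and no claim about clinical accuracy follows from it.
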