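---
title: "Sparse-label 3D axon segmentation: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-label 3D axon segmentation: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Light-sheet fluorescence microscopy of cleared mouse brain produces 3D
volumes in which fluorescently labeled axons appear as thin bright tubes on
a dim background. Expert annotation of such volumes is so costly that labels
are typically drawn on only a sparse subset of z-slices (here: every 20th
slice, starting at 0-based slice 15 of a 160-slice cube, i.e. 8 annotated
slices per cube). `axseg` implements a complete, desk-scale pipeline for
fine-tuning and evaluating a 3D convolutional segmentation model under this
sparse-annotation regime:

* a synthetic **phantom generator** that stands in for annotated microscopy
  cubes, so every stage is testable without the (unreleased) imaging data;
* **edge-class derivation** and the sparse-slice mask;
* **corner sampling** of training windows with foreground oversampling;
* co-registered **spatial and intensity augmentation**;
* a compact **3D encoder–decoder** with layer-selective fine-tuning and a
  masked, class-weighted cross-entropy loss;
* **sliding-window inference** with Gaussian-weighted overlapping-window
  fusion; and
* **edge-tolerant evaluation** restricted to labeled slices.

## Annotation model and the edge class

Label volumes are categorical with codes 0 = unlabeled, 1 = background,
2 = axon, 3 = imaging artifact, 4 = edge. Unlabeled voxels exist only on
slices that were never annotated; they are masked out of both the loss and
the evaluation, which is what makes sparse annotation workable.

The **edge class** is derived, not drawn: on each labeled slice, every
background voxel 8-adjacent in-plane to an axon voxel becomes an edge voxel
(`generate_edges()`). Because annotation exists only on isolated slices, a
3D boundary is undefined across the unlabeled gaps, so edges are computed
per 2D slice; 8-connectivity gives a closed one-voxel ring. Edges never
overwrite artifact voxels, preserving the four-class weighting. The ring
absorbs annotator boundary uncertainty twice over: it is strongly
down-weighted in the loss, and the evaluation forgives it via the EA
correction (below).

## Loss

Each voxel of the output window contributes `w(code) * BCE(p, y)` where `y`
is the axon indicator and the weights default to axon 1.5, background 0.2,
artifact 0.8, edge 0.05, unlabeled 0. The mean is taken over voxels with
nonzero weight, so the scale of the loss does not depend on how many
unlabeled voxels a window happens to contain. An all-unlabeled window gives
loss 0 with a warning rather than NaN.

## Window geometry and sampling

Training windows are 64^3 input cubes with a concentric label window of
64 − 2·14 = 36^3: convolutions see full context around every predicted
voxel, and the network head crops the 14-voxel margin. The same arithmetic
makes a 188^3 padded input cube predict exactly its central 160^3 labeled
region at inference.

Window placement follows the corner convention: the top-left-back (0-based)
corner is drawn uniformly from `[0, dim − 64]` per axis, so windows never
need padding. With probability 0.3 the corner is instead drawn from the
list of axon-labeled voxels (clamped into the valid corner range), biasing
training toward foreground; an empty list falls back to the uniform draw.
The default of 100 samples per cube means seven training cubes yield 700
volumes per epoch and, at batch size 6, 116 optimization steps.

## Augmentation

Axis flips, rotations, and elastic deformation are applied with one
geometric mapping to the input and to the input-sized label window, after
which the target is re-cropped — transforming labels at input resolution
avoids boundary artifacts in the small target window. Inputs are resampled
trilinearly (out-of-domain voxels filled with the window median, a robust
background estimate); labels use nearest-neighbour resampling (which cannot
invent codes) and fill with background. The elastic field is a
uniform(−1, 1) displacement smoothed by a Gaussian of width σ ∈ [9, 13]
voxels and scaled by α ∈ [0, 200] — with these ranges the *realized*
displacements are on the order of one voxel, because smoothing white noise
at σ ≈ 10 shrinks its amplitude by roughly two orders of magnitude.
Rotations default to ±15° per axis. The magnitudes are not dictated by the
underlying method, so they follow the conventions of the widely used
batch-augmentation codebases and are configurable. When rotation and
elastic deformation are both enabled, each is applied with an independent
per-sample probability of 0.5 (a documented choice; the source method does
not state one).

Intensity augmentation is deliberately minimal: divide by 65535, multiply
by s ∈ [0.8, 1.2], add c ∈ [−0.05, 0.05]. Z-score normalization is
deliberately **not** offered — removing raw intensity scale makes dim axons
indistinguishable from background in this modality.

## Network, fine-tuning, and training

The network is a configurable-depth 3D encoder–decoder (default 3 levels,
channel doubling, max-pooling, nearest-neighbour upsampling, concatenation
skips, batch normalization, ReLU) with a 1×1×1 sigmoid head and a central
crop realizing the 64^3 → 36^3 contract. The underlying method treats the
architecture as given and its contract as the I/O geometry plus an ordered
list of convolutional layers; this package does the same. With depth 3
there are six convolutional layers: enc1, enc2, bottleneck, dec2, dec1,
head.

Layer-selective fine-tuning (`apply_layer_selection()`) marks `first2`,
`middle2` (the two layers straddling the list midpoint — for six layers,
indices 3 and 4 in 1-based R terms), `last2`, or `full` as trainable.
Batch-norm parameters are always trainable, and by default frozen-layer
running statistics keep updating during fine-tuning; both follow the
observation that freezing normalization statistics hurts transfer.
Frozen parameters are bit-identical after any number of steps (tested).

Training uses Adam with cross-entropy as above, learning rate 1e-4 by
default (1e-3 being the original-training alternative), and either a fixed
rate or reduce-on-plateau (×0.1 after `patience` epochs without validation
improvement, default patience 10, floor 1e-6 — common defaults, since the
method states only the factor). The checkpoint kept is the epoch with the
**lowest** weighted validation loss; the alternative reading ("highest")
contradicts every other statement about stable lower validation curves and
is treated as a slip.

## Inference

Whole-cube prediction slides the 64^3 window so that output windows tile
the central region; remainder windows at far faces are shifted inward to
end flush, guaranteeing coverage. Overlapping predictions are fused as a
weighted mean, each window weighted by a Gaussian importance map
`exp(−‖v − center‖² / 2σ²)` (σ = output_size/8, the convention of the
framework that popularized the technique; the method itself states no σ).
Plain mode uses abutting windows; Gaussian mode half-overlaps by default.
Because the fusion is an exact weighted mean, a constant predictor passes
through unchanged, fused values are convex combinations of the covering
windows' predictions, and Gaussian and uniform fusion agree wherever a
voxel is covered once — all asserted in the test suite. Mirrored test-time
augmentation is intentionally out of scope. Binarization is strictly
"above 0.5".

## Evaluation

Confusion counts are accumulated over annotated voxels only (code ≠ 0);
axons are positives, background/artifact/edge negatives. `EA` counts edge
voxels predicted positive and is subtracted from FP in the two
edge-corrected metrics:

* Edge Precision = TP / (TP + FP − EA)
* Edge F1 = 2 · Recall · Edge Precision / (Recall + Edge Precision)

so a positive prediction within one voxel of an annotated axon is not
penalized. Metrics with zero denominators are reported as `NA`, never as a
silent 0. Artifact voxels predicted positive receive no such forgiveness —
the correction is defined for edges only. Metrics are computed per cube,
matching per-cube validation/test reporting.

## The phantom generator

`generate_phantom()` emulates the *geometry and statistics* of annotated
light-sheet cubes: a 160^3 labeled core inside a 188^3 padded input cube
(both configurable), bright tubular axons (piecewise-linear random walks
with bounded turning angle, dilated by a spherical element of radius 1–3
voxels), optional bright spheroid artifacts, background ≈ 800 and axon
≈ 6000 mean intensity with Gaussian noise (sd 300) on the 16-bit scale —
contrast chosen to resemble antibody-labeled axons after clearing, where
foreground is clearly brighter than the parenchyma yet far below sensor
saturation. `sparsify_labels()` then reduces dense truth to the every-20th-
slice-from-15 scheme.

What the phantom does **not** model: optical point-spread anisotropy,
tiling/stitching seams, depth-dependent attenuation, autofluorescence
texture, or the morphological difference between neurotransmitter systems.
Passing tests therefore demonstrate that the pipeline's mechanics (masking,
weighting, geometry, fusion, metrics, optimization) are correct, not that
any particular accuracy transfers to real microscopy data.

## Numerical choices and degenerate inputs

* Probabilities are clipped to [1e-7, 1 − 1e-7] inside the loss; the
  training gradient is taken with respect to the logits.
* Batch-norm uses ε = 1e-5 and momentum 0.1 on running statistics.
* Weight init is He-scaled Gaussian, seeded; identical seeds give
  bit-identical networks, phantoms, and training runs.
* Slice and corner indices are 0-based throughout the public API (the
  natural convention of the imaging stack this mirrors); R arrays remain
  1-based internally. "The 15th slice" is read as index 15 — the one-slice
  ambiguity affects no algorithm.
* Degenerate cases: empty axon-corner list → uniform draws; all-unlabeled
  loss window → 0 with warning; zero-denominator metrics → `NA`; value
  exactly at the binarization threshold → negative; odd input/output
  difference → error.

## Problem sizes used in the tests

Unit tests run on 16^3–32^3 windows with depth-2 networks and verify the
analytic gradients against central finite differences. The end-to-end
check trains the 64^3-window, base-filters-4, depth-3 network for 10 epochs
of 8 samples (batch size 1, learning rate 1e-3) on a phantom with a 64^3
labeled core, then runs Gaussian-fused sliding-window inference and
compares Edge F1 against the all-positive baseline. Batch normalization is
disabled for that tiny from-scratch run: with ~80 optimizer steps the
running statistics used at inference cannot yet track the training-mode
batch statistics, so predictions are systematically mis-calibrated — a
property of batch normalization at tiny step counts, not of this
implementation (the BN path is exercised and gradient-checked separately).
This is also why genuine fine-tuning from a converged model, where running
statistics are already calibrated, is the regime the method targets.

## Known limitations

* Pure-R + Rcpp training is CPU-bound; the package targets method-level
  correctness and desk-scale experiments, not GPU-scale training of
  100-epoch, 700-volume runs.
* The phantom's realism limits (above) mean quantitative results on real
  tissue require real annotated cubes.
* Inference materializes the fused accumulator in memory; terabyte-scale
  streaming is out of scope.
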