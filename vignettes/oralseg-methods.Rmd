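---
title: "Tooth-level instance segmentation of dental CBCT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tooth-level instance segmentation of dental CBCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(oralseg)
```

## The problem

Cone-beam computed tomography (CBCT) is the workhorse 3D modality of
digital dentistry. Clinical planning — implants, orthodontics,
orthognathic surgery — needs each anatomical structure identified
*individually*: not "teeth versus bone" but *which* tooth, plus the
maxilla, the mandible, and the two mandibular canals that carry the
inferior alveolar nerves. That is a 37-class (36 foreground + background)
volumetric instance segmentation problem with severe class imbalance
(a canal is a few thousand voxels in a multi-million-voxel scan),
near-identical appearance of neighbouring classes (adjacent teeth), and
frequent structural absences (missing teeth, restorations, implants).

This package implements a complete, trainable framework for that
problem: the hybrid network, the training protocol, sliding-window
whole-volume inference, the evaluation and present/absent accounting
suite, inter-rater agreement statistics, NIfTI/NRRD input/output, and a
procedural dental phantom generator so that the entire pipeline runs and
is testable at desk scale without any patient data.

## Label scheme

Labels follow the FDI two-digit tooth numbering. Internal class indices
are fixed once and serialized with every output: teeth in FDI quadrant
order (11..18, 21..28, 31..38, 41..48) are classes 1–32, maxilla 33,
mandible 34, left mandibular canal 35, right canal 36; 0 is background.
"Left" is patient-left (radiological display mirrors it). The semantic
merge collapses these to 5 classes (background / teeth / maxilla /
mandible / canal) by pure voxelwise relabelling, so foreground volume is
conserved exactly.

## The network

The model is a U-shaped encoder–decoder. Input is a single-channel,
min–max normalized patch (64³ at the clinical configuration). A 2×2×2
strided patch embedding halves resolution; four encoder stages follow,
each fusing two complementary branches at the same scale:

* **Shifted-window attention branch.** Two transformer blocks per stage
  compute multi-head self-attention within 3D local windows (7³ by
  default, clipped to the stage grid when larger), with learned relative
  position bias over the (2w−1)³ possible voxel offsets. The second
  block shifts the partition by half a window per axis; cyclic shifting
  with additive masks (computed from region identifiers, with padded
  voxels isolated in their own region) keeps attention exact at borders
  while letting information cross window boundaries. Each block is
  pre-layer-norm with a 2× GELU MLP and residual connections.
* **Spatial state-space branch.** Two 3D convolution paths (1×1×1 and
  3×3×3 kernels — detail and context) are fused additively, instance-
  normalized, and activated. The fused features then drive a selective
  state-space scan: input-dependent step sizes (softplus of a pointwise
  projection), input and readout projections of state dimension 16, and
  a stable diagonal state matrix A = −exp(A_log). The same (tied)
  parameters are applied along the x, y and z voxel orderings —
  unidirectional forward scans, one per axis — and the three outputs are
  summed and projected back onto the convolutional path as a residual.
  With tied parameters the scan-sum commutes with axis transposition,
  which the test suite checks directly.

The two branch outputs are concatenated and projected back to the stage
width by a 1×1×1 convolution (addition is available via
`model_config(fusion = "sum")`); a strided 2×2×2 convolution then halves
resolution and doubles width. Channel widths double from
`embed_size = 48` (48/96/192/384); the per-head attention dimension is
`feature_dim = 8`, so stage *s* runs `width_s / 8` heads. Ablations
`swin_only` and `smamba_only` drop the other branch (the fusion
projection then maps C→C instead of 2C→C), which is how the
architecture's two-branch contribution is isolated in comparisons.

The decoder mirrors the encoder: nearest-neighbour ×2 upsampling with a
1×1×1 channel-halving projection, concatenation with the same-scale
skip, and residual blocks (two 3×3×3 convolutions with instance
normalization and a projected shortcut). Skip/decoder shape agreement is
asserted at run time, not assumed. The final stage runs at full
resolution: a 3×3×3 stem convolution on the raw input provides a
voxel-scale skip that is concatenated with the upsampled decoder
features and refined by a residual block before the 1×1×1 head emits
the 37-channel map. The full-resolution stage matters: without it the
last spatial convolution happens at half resolution, and structures a
few voxels across (mandibular canals, root apices) lose most of their
attainable Dice to boundary blur.

### Output head: softmax, not sigmoid

The architecture description ends in a per-channel sigmoid, but 37
mutually exclusive labels decoded by argmax need a normalized
assignment, and the training loss is a Dice + cross-entropy composite
over exclusive classes. We therefore emit softmax probabilities by
default and keep the literal per-channel sigmoid behind
`model_config(head = "sigmoid")` for fidelity. This is the one place the
implementation deliberately departs from the stated architecture, and it
is configurable.

### Other interpretation choices

* The attention window size is not specified; 7³ (the standard
  shifted-window choice) is the default and is configurable.
* The state-space parameterization beyond "two fused convolution scales,
  concurrent in all three spatial dimensions" is unstated; we implement
  a standard selective recurrence with configurable state dimension
  (default 16) and document it as interpretation. Scans are
  unidirectional; bidirectional scanning would double the cost.
* "Stacked" branch fusion is read as concat + 1×1×1 projection.
* Instance normalization is used throughout the convolutional parts
  because the protocol trains at batch size 1. A numerical guard treats
  channels whose variance sits at the rounding floor as exactly
  constant (output = the affine offset); without it the normalizer's
  epsilon floor amplifies float noise ~300-fold per layer and a constant
  input stops propagating as constant.
* Batches are single volumes (batch size 1 is part of the protocol), so
  the forward API takes one patch and returns `(1, 37, X, Y, Z)`.

## Training protocol

`train_config()` encodes the protocol: random 70/20/10
train/validation/test split (validation and test sizes are `round(n f)`,
the remainder trains, so n = 100 gives exactly 70/20/10); random 64³
patch per case per epoch; random flips, axis-aligned 90° rotations
(label-exact by construction; free-angle rotation about z is available
behind a flag), multiplicative intensity scaling 0.9–1.1 and additive
shift ±0.1 (our defaults — the augmentation families are protocol, the
ranges are not stated); DiceCE loss; AdamW at peak learning rate 1e-5
with a linear warm-up into cosine annealing; 2500 epochs at clinical
scale (desk default 50; warm-up defaults to 2% of epochs, matching 50 of
2500).

The DiceCE loss is
`w_d (1 − mean_k softDice_k) + w_ce mean_vox(−log p_target)` with 1:1
weights and smoothing 1e-5 in the soft-Dice numerator and denominator;
a uniform predictor's CE term is exactly ln 37, and a one-hot correct
prediction has Dice term 0 — both are asserted analytically in the
tests. All randomness flows from the config seed; the model's forward
and backward passes consume no RNG, so ablation arms see the identical
patch stream, two runs with one config produce identical curves, and a
checkpoint (which carries optimizer and RNG state) resumes
bit-for-bit. "Accuracy" curves are logged as training/validation macro
Dice (the curve metric is not defined by the protocol; we state ours).
Validation, when enabled, runs sliding-window inference on whole
volumes so curves reflect deployment behaviour rather than patch
statistics.

## Inference

`predict_volume()` reproduces the one-click deployment path: the input
spacing is checked against the training spacing (0.3 mm; relative
difference above 1% triggers trilinear resampling in and
nearest-neighbour label resampling back out, so the output grid always
equals the input grid), intensities are min–max normalized, and the
volume is tiled into overlapping windows (default 64³ at 50% overlap)
whose softmax maps are blended with Gaussian weights (σ = window/8;
constant blending available). Blending weights are renormalized by their
accumulated sum, so they form an exact partition of unity at every
voxel including borders — seam artifacts at window boundaries are the
failure mode this addresses. Volumes smaller than a window are
zero-padded symmetrically and cropped back. Decoding is voxelwise
argmax with ties broken toward the lower class index (background wins
an all-equal tie). An optional largest-component cleanup per class
exists but is off by default: the deployment path applies no
post-processing, so neither do we by default. An ROI box restricts
computation and embeds the result in a background-filled full grid.

## Evaluation and accounting

Per-class metrics are one-vs-rest voxel counts: Dice, IoU, accuracy,
precision, sensitivity, and F1 (for binary voxel counts F1 is
algebraically identical to Dice, and the suite asserts it). Macro
averages are unweighted means over the included classes
(`mEM = (1/N) Σ EM_i`), with `N` reported alongside.

Two conventions are explicit rather than implicit:

* **Background** (class 0) is excluded from macro averages by default —
  background dominance inflates accuracy-type metrics — and can be
  included via `metrics_policy(include_background = TRUE)`.
* **Empty classes.** A class empty in both truth and prediction carries
  no voxel evidence: it is excluded from macro averages and routed to
  the identification tally. A class empty in truth but predicted
  non-empty counts as a *false identify* (scoring it as Dice 0 inside
  the macro is available via `score_false_identify = TRUE`, covering
  the other reading). A class present in truth but predicted empty is a
  *missing segment* and forces Dice 0. "Predicted present" means at
  least `min_voxels` predicted voxels (default 1; the threshold for
  ignoring noise blobs is a stated knob, not a hidden one). The tally
  invariant `correct + false = #gt-empty` is asserted.

Per-case reports aggregate across cases by unweighted mean, with the
per-case table emitted so any other aggregation can be recomputed.

## Inter-rater agreement

`pairwise_label_dsc()` computes per-label Dice between two raters'
maps. `icc()` implements ICC(2,1) — two-way random effects, absolute
agreement, single measures — from the mean-squares decomposition, and
returns MSR/MSC/MSE for audit. The ICC form and its input quantity are
not stated in the protocol this mirrors; we use the standard choice for
two interchangeable raters and feed it per-label structure volumes
(voxel count × voxel volume), and we name both choices in the output.
`perturb_annotation()` simulates a second rater by flipping
label-boundary voxels to a neighbouring label with a given probability —
interior voxels are untouched, so per-label Dice decreases
monotonically in the flip probability, which is tested.

## The phantom: what it emulates and what it does not

`generate_phantom()` builds a parametric-analytic dental scene: two
arches of up to 32 teeth placed on semi-elliptic arch curves (ellipsoid
crowns; 1–3 tapered-cone roots according to tooth type — incisor/canine
1, premolar 1–2, molar 2–3 — penetrating the jaw), maxilla and mandible
slabs with a cortical shell / trabecular core intensity split, two
tubular canals threaded inside the mandible, per-material mean
intensities with additive Gaussian noise, and optional metal-streak
(radial high-intensity spokes through a chosen crown) and motion-blur
(Gaussian) artifacts. Geometry is analytic rather than atlas-based so
that generation is a pure, seeded function of the spec and the
ground-truth labels are exact by construction. Real dentitions are not
clone sets, and the phantom reflects that: every tooth carries a seeded
morphological signature (crown semi-axis/height jitter, default ±12%
of the `shape_jitter` parameter's nominal 0.12) and a brightness
signature (multiplicative, default ±5%), and the two canals differ in
calibre, depth and lumen brightness (`side_jitter`). Besides realism, these signatures
give instance identity a local footprint — without them a phantom
molar and its mirror twin are voxel-identical up to reflection, which
real teeth never are. Crown radii are capped by the distance to the
nearest present neighbour (so instance labels never overlap) and crown
heights by the interocclusal gap (so opposing crowns never
interpenetrate); a post-pass keeps each tooth's largest 6-connected
component, since voxelization can graze off single diagonal voxels at
crown surfaces.

The default desk grid is 128×128×96 at 0.3 mm — the clinical
440×440×344 acquisition grid at the same spacing remains a configuration
choice — chosen so that a full-dentition phantom generates in seconds
and CPU tests stay fast.

What the phantom does *not* emulate: real CBCT physics (beam hardening,
scatter, Hounsfield calibration), anatomical shape variation beyond its
parametric families, pathology, and the texture statistics of real bone.
Consequently, passing tests demonstrate that the pipeline is *correct
and trainable* — gradients flow, the decoder reconstructs, inference
tiles and decodes, accounting is exact — not that the network reaches
clinical accuracy on real scans; the headline clinical numbers require
the private patient dataset and GPU-scale training, both outside this
package's scope.

## The desk-scale learnability experiment

`learnability_run()` is the package's end-to-end sanity check: a reduced
network (embedding 24, 5³ windows, state dimension 8) is trained for at
most 400 optimizer steps on two phantoms with 32³ patches, then
evaluated by whole-volume sliding-window inference against the exact
ground truth. Its design follows from what a 400-step budget can
demonstrate:

* **Scene.** A severely reduced dentition — two first molars (FDI 16
  and 36, diagonal quadrants, which incidentally makes left and right
  distinguishable in every view), both jaws, and both mandibular canals
  on an 80×80×56 grid at 0.4 mm. With a full dentition the budget
  spreads over ~36 classes and none of the small ones converges; with
  six classes the same budget overfits all of them. Severe partial
  edentulism is a clinically real case mix.
* **Data schedule.** Training cycles the *deterministic inference
  tiling* of each phantom (36 tiles of 32³, visited 11 times each = 396
  steps) rather than drawing fresh random crops: a fresh crop every
  step means no input is ever repeated, which tests generalization
  across offsets — a much harder property than the overfitting this
  experiment is meant to demonstrate. Evaluation then runs the same
  tiling through the blended sliding-window path, so the end-to-end
  figure also exercises tiling, blending and decoding.
* **Optimizer.** Peak learning rate 1e-2 on the same warm-up-cosine
  shape (evaluated continuously in fractional epochs so a short run
  does not burn its first epoch at the zero end of the ramp), weight
  decay off, AdamW beta2 = 0.99. The clinical protocol's 1e-5 over
  2500 epochs barely moves a network in 400 steps.
* **Phantom signatures.** The per-tooth brightness signature is raised
  to 12% so instance identity has a strong local footprint, and canal
  calibre is set to 1.4 mm (the upper end of the normal mandibular
  canal range) so the thinnest structures are several voxels across at
  0.4 mm.

These are harness constants, stated here once. The run reports the
final epoch's training foreground macro Dice and the whole-volume macro
Dice against ground truth, averaged over the two phantoms.

## Numerical choices, degenerate inputs, tie-breaks

* Min–max normalization maps a constant volume to all zeros (any
  constant carries no signal; avoids 0/0). Optional percentile clipping
  (p0.5–p99.5) is off by default — plain 0–1 normalization is the
  protocol; clipping is a documented extension.
* Resampled shapes round half away from zero (`round(n·s/t)`, min 1);
  libraries disagree here, so the rule is stated and tested. Labels are
  always nearest-neighbour resampled and so never gain values.
* Decoding ties break toward the lower class index, so background wins
  an all-equal tie.
* Internal voxel order is RAS; LPS files are flipped on read and
  restored on write, so voxel operations never see mixed conventions.
  Only axis-aligned RAS/LPS orientations are supported; anything else
  is refused loudly.
* The degenerate-variance guard in instance normalization is described
  above.
* The classification head is initialized near zero (weights at 5% of
  the usual He scale), so initial class scores are near-uniform. A hot
  random head hands the early optimization a confident but arbitrary
  labelling; rare classes (the canals, a lone incisor) can collapse
  against it and never recover within a short run.
* BLAS threading defaults to a single thread
  (`options(oralseg.blas_threads = n)` overrides): the network issues
  thousands of small-to-medium GEMMs per step, and an oversubscribed
  thread pool slows them several-fold.

## Problem sizes used by the shipped checks

The test battery and the acceptance script run the metric-suite oracle
on 200 random ≤8³ label pairs, architecture checks at 64³ (forward) and
32³ (gradient) for all three ablations, the 400-step learnability run
above, a 20-case constructed accounting suite, tiling checks at one to
twelve windows, and agreement fixtures of 6×2 and ~30×2. These sizes are
the package's desk-scale choices, balancing coverage against the
patience of anyone running `R CMD check` on a laptop.

## Known limitations

* The autodiff engine, optimizer and layers are purpose-built for this
  architecture: dense double precision, batch size 1, CPU only. They are
  the substrate of the contribution, not a general-purpose framework.
* No deep supervision, no test-time augmentation, no DICOM ingestion,
  no surface-distance metrics (HD95/ASSD) — all outside the protocol
  this package implements.
* Checkpoints are R serializations with a JSON sidecar; weights from
  other implementations of this architecture cannot be imported (layer
  naming is unknown).
* The phantom's limitations above bound what desk-scale results say
  about clinical data.
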