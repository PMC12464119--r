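# oralseg

Tooth-level instance segmentation of dental cone-beam CT (CBCT) volumes
in R: a trainable hybrid deep network, its full training and inference
protocol, a segmentation evaluation and accounting suite, inter-rater
agreement statistics, and a procedural dental phantom generator so the
entire pipeline runs at desk scale without patient data.

## Who this is for

Researchers in dental/maxillofacial image analysis who need a complete,
inspectable reference implementation of tooth instance segmentation —
the 37-class problem of labelling each of the 32 FDI-numbered teeth plus
maxilla, mandible and both mandibular canals — including every piece
around the network: label scheme, NIfTI/NRRD i/o, patch pipeline,
metrics, and present/absent accounting for missing teeth.

## The model

The network is a U-shaped encoder–decoder over 3D patches. Each of the
four encoder stages fuses two branches at the same scale:

* volumetric **shifted-window self-attention** (3D windows with relative
  position bias; alternate blocks shift the partition by half a window,
  with exact masking at borders), capturing global context;
* a **spatial state-space (Mamba-style) block**: 1×1×1 and 3×3×3
  convolution paths fused and fed through a selective state-space scan
  run along each of the three spatial axes with tied parameters
  (`h_t = exp(Δ_t A) h_{t−1} + Δ_t B_t x_t`, `y_t = C_t·h_t + D x_t`,
  with `A = −exp(A_log)` for stability), capturing fine spatial
  structure.

Branch outputs are concatenated, projected, and downsampled ×2 per
stage (widths 48/96/192/384); the decoder mirrors this with skip
concatenation and residual blocks down to a 1×1×1 head over 37 class
channels. Training uses the DiceCE composite

    L = w_d · (1 − (1/K) Σ_k softDice_k) + w_ce · mean_vox(−log p_target)

with AdamW and a warm-up–cosine learning-rate schedule; evaluation
reports per-class Dice/IoU/accuracy/precision/sensitivity/F1 and their
macro averages `mEM = (1/N) Σ EM_i`, plus an identification tally
(correct / false / missing) for classes empty in the ground truth.
Agreement between raters uses per-label DSC and ICC(2,1) from the
two-way ANOVA mean-squares decomposition.

The network, reverse-mode autodiff, and optimizer are implemented in
R with C++ kernels (im2col convolution, windowed attention, selective
scans) — dense double precision, batch size 1, CPU.

## Worked example

```r
library(oralseg)

# a synthetic CBCT-like case: two arches, jaws, canals, seeded geometry
ph <- generate_phantom(phantom_spec(seed = 3))
ph$labels
#> <oralseg labels> 128x128x96 voxels @ 0.3x0.3x0.3 mm (RAS), 36 labels [0,1,2,3,4,5,6,7,8,9,10,11]

# simulate a second annotator and measure agreement
rater2 <- perturb_annotation(ph$labels, boundary_flip_prob = 0.25, seed = 1)
round(mean(pairwise_label_dsc(ph$labels, rater2)), 3)
#> [1] 0.795
tab <- ratings_table(list(list(ph$labels), list(rater2)))
round(icc(tab)$estimate, 4)
#> [1] 1

# evaluate a (perturbed) prediction against ground truth
res <- evaluate_case(rater2, ph$labels)
res$report
#> <metrics report> N=36 classes: mDice=0.7951 mIoU=0.6631 mAccuracy=0.9994 mPrecision=0.7599 mSensitivity=0.8347 mF1=0.7951
res$tally
#> <identification tally> correct 0 / false 0 (of 0 gt-empty); missing 0
```

Here `mDice` is the unweighted mean of the 36 per-structure Dice
coefficients (background excluded) — flipping a quarter of all boundary
voxels costs about 0.2 Dice on these small structures — and the ICC is
computed on per-label structure volumes, which boundary flips barely
change (the perturbation reassigns voxels between neighbouring labels).
The tally reports how structures empty in the ground truth (missing
teeth) were accounted for.

Training and whole-volume inference:

```r
model <- build_model(model_config(embed_size = 24, attention_window = c(5, 5, 5)),
                     init_seed = 1)
cohort <- list(ph)
cfg <- train_config(lr = 1e-3, epochs = 10, patch = c(32, 32, 32), seed = 1)
run <- fit(model, cohort, cfg)
pred <- predict_volume(ph$volume, model,
                       inference_config(window = c(32, 32, 32),
                                        target_spacing = 0.3))
```

A command-line wrapper over the same functions is installed at
`system.file("cli", "oralseg.R", package = "oralseg")` with subcommands
`simulate`, `train`, `infer`, `evaluate`, `agreement`.

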