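---
title: "Multi-exit knowledge distillation for single-cell cytology images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-exit knowledge distillation for single-cell cytology images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the method

Cervical cytology screening produces large numbers of single-cell images that
must be sorted into morphological classes (in the five-class setting:
superficial-intermediate, parabasal, metaplastic, koilocytotic,
dyskeratotic). Deep classifiers do this well but tend to be over-parameterized
for the modest labeled datasets available, and a single network rarely learns
every discriminative feature view. cytodistill implements a training recipe
that addresses both problems at once:

1. **Transfer learning.** A backbone is pretrained with plain cross-entropy
   on a source domain (stage 1, `pretrain()`), and its weights are carried
   into the target model (`transfer_load()`), with every class-dependent head
   freshly initialized.
2. **Knowledge distillation (KD).** A stronger, frozen teacher supplies
   temperature-softened class distributions ("soft labels"), and the student
   is trained to match them in addition to the ground-truth labels
   (stage 2, `finetune_distill()`).
3. **Multi-exit self-distillation (SD).** The student is a staged residual
   backbone with a classifier exit after each stage. The deepest exit acts as
   an internal teacher: its softened outputs and its feature map supervise
   every shallower exit.
4. **Ensemble inference.** At test time the exits' temperature-1 softmax
   outputs are averaged (`ensemble_predict()`); the averaged distribution is
   the final classifier.

### The objective

Let `S_m` be the raw logits of exit `m` (with `S_n` the deepest exit), `t`
the teacher's distribution softened at temperature `tau`
(`soften()`, `t_k = exp(z_k/tau) / sum_k exp(z_k/tau)`), and `y` the labels.
Each exit contributes a knowledge-distillation term

    KD_m = tau^2 * KL(S_m, t) + CE(softmax(S_m), y) + CE(softmax(S_n), y)

and each shallow exit additionally a self-distillation term

    SD_m = tau^2 * KL(S_m, S_n) + lambda * MSE(mu_m(F_m), F_n)

where `mu_m` is exit m's bottleneck that maps its feature map to the deepest
exit's feature shape, and the total objective is `sum_m (KD_m + SD_m)`. The
`tau^2` factor keeps the KL gradient magnitude comparable across
temperatures. All of this is exposed both as loss functions
(`cross_entropy()`, `kl_distill()`, `exit_kd_loss()`, `self_distill_loss()`,
`total_loss()`) and through the training loop.

Three points in this objective are genuinely open to reading, and the
package makes each one a switch rather than a silent choice:

* **KL direction.** The printed form of the distillation divergence places
  the *student's* softened distribution in the log numerator (forward KL
  from the student), which is the reverse of the most common distillation
  convention. The default (`kl_direction = "student_to_teacher"`) follows
  the printed form; `"teacher_to_student"` selects the conventional
  direction. On the separable synthetic fixtures the two behave
  indistinguishably; on hard real data the conventional direction is the
  safer choice, which is why the switch exists.
* **Deep cross-entropy duplication.** Summing `KD_m` over all n exits counts
  `CE(S_n, y)` n times. The default implements that literal summation;
  `dedup_deep_ce = TRUE` counts it once (the two objectives differ by
  exactly `(n-1) * CE(S_n, y)`, which is also a test invariant). The
  duplication effectively up-weights the deepest exit's supervised signal —
  harmless here, but worth controlling for.
* **Stop-gradient.** The self-distillation terms treat `S_n` and `F_n` as
  constants: the deep classifier teaches the shallow ones and is not pulled
  toward them. This is not stated in the source description of the loss; we
  chose it because the opposite coupling lets weak early exits drag the
  deepest exit during the first epochs. The gradient tests verify the
  convention explicitly.

### The student architecture

`build_student()` assembles a staged residual backbone
(`student_config(backbone_id = ...)`): an 18-layer configuration
(`"resnet18"`, with a 3x3 stem suited to small crops), a widened variant
used as a default heavyweight teacher (`"resnet18_w96"`), and two
reduced-depth configurations (`"tiny"`, `"tiny_wide"`) for desk-scale
work on small images. Exits tap the last `n_exits` stages, so the deepest
exit is always the backbone's own head path.

Each exit branch applies:

* a **global context (GC) block**: a 1x1 convolution scores every spatial
  position, a softmax over all positions forms an attention map, the
  attention-weighted sum pools one context vector per image, a two-layer
  channel bottleneck (reduction ratio `gc_reduction_ratio`, layer
  normalization + ReLU inside) transforms it, and the result is fused back
  into every position. Additive fusion is the default: together with
  zero-initialization of the final transform layer it makes the block an
  exact identity at initialization, so the multi-exit network starts
  equivalent to the plain backbone and learns context only as needed. An
  element-wise product fusion (`fusion_mode = "multiply"`) is available
  where the literal "dot product" reading is wanted.
* a **scale-unifying bottleneck**: one stride-2 residual unit per
  factor-of-two spatial ratio between the tapped stage and the deepest
  stage, at the tapped stage's width, followed by a 1x1 projection to the
  deepest stage's channel count. Keeping the downsampling at the tap width
  and projecting once at the end keeps the exit branches light — the
  multi-exit student grows by roughly 2.4 M parameters over the plain
  11.2 M backbone in the default configuration — while still making all
  unified features shape-compatible with `F_n` for the feature loss.
* global average pooling and a single fully connected head.

The deepest exit's feature map `F_n` is taken *after* its GC block,
consistent with every exit branch carrying one.

### Optimization

SGD with momentum 0.9, weight decay 1e-4, initial learning rate 0.1
multiplied by 0.1 at epochs 100 and 150, 180 epochs, batch size 128,
`tau = 3`, `lambda = 0.03` — these are the `distill_config()` defaults.
A single optimizer updates the union of backbone and exit parameters.
Model selection is by best ensemble validation accuracy (for stage 1, best
plain validation accuracy); the selection rule is a package choice, as is
the mean (rather than sum) reduction of the feature MSE, which makes
`lambda` independent of feature-map resolution.

## The synthetic generator

`generate_dataset()` renders five-class single-cell images so the entire
pipeline can be exercised, trained and tested in minutes without any
download. Each image contains one cell: a cytoplasm disk whose boundary is
a low-order-harmonic radial perturbation of a circle, an interior nucleus
disk, rotationally symmetric radial texture inside the cytoplasm, and
clipped i.i.d. Gaussian intensity noise; grayscale content is replicated to
3 channels so synthetic and real (RGB) data share one code path. The five
default classes (`default_cell_classes()`) are ordered by increasing
nucleo-cytoplasmic ratio — the main axis separating normal from abnormal
cervical cells — and additionally differ in boundary irregularity and
texture frequency. Defaults: image size 64 (32 for the fastest tests),
noise sd 0.03, background level 0.08, centre jitter 4% of the image side.

What the generator does *not* emulate: staining variation, cell clumps and
overlaps, debris, out-of-focus blur, and the intra-class appearance
diversity of real smears. Passing the desk-scale training tests therefore
demonstrates that the optimization, losses and architecture work end to
end on a learnable five-class morphology problem; it does not certify
real-data accuracy.

## Numerical choices and degenerate inputs

* Softmax is always computed with a per-row maximum shift; log arguments in
  the losses are clamped at 1e-12 (a clamp at the true class raises a
  warning).
* Batch normalization uses batch statistics in training mode and running
  statistics (momentum 0.1) at evaluation; layer normalization inside the
  GC transform uses eps 1e-5. Early in training the running statistics are
  still converging, so validation accuracy can lag the training loss for a
  few epochs.
* The GC block rejects channel counts not divisible by the reduction ratio;
  the bottleneck rejects spatial sizes not divisible by its total stride.
  A 1x1 spatial input is legal: the attention weight is then exactly 1.
* All randomness (weight init, split shuffling, batch order, augmentation,
  rendering) flows through derived seeds from a caller-supplied master
  seed; identical seeds reproduce training bit-exactly, which is itself a
  test.
* Stratified splitting uses largest-remainder apportionment within class
  (ties resolved in train/val/test order), so per-class counts equal the
  exact proportions up to one item.
* "Mirror flip" in the augmentation set is read as a vertical flip,
  distinct from the horizontal flip; both probabilities are configurable,
  and magnitudes (crop scale 0.7–1.0 of the area, rotation ±15°) are
  conventional mild defaults since only the operation names are prescribed.
  Normalization constants are computed from the training split rather than
  hard-coded, because synthetic and cytology intensity statistics differ
  from natural-image ones.

## Desk-scale problem sizes

The end-to-end checks train the `"tiny"` reduced-depth student (widths
4/8/16/32, one block per stage, downsampling at every stage) on the default
synthetic fixture: 84 images per class, i.e. 250/85/85 under the 3:1:1
split, at 64x64, for 30 epochs, batch 64, learning rate 0.05 decayed by
0.1 at epochs 17 and 25 — the full-scale schedule's milestones (100 and
150 of 180 epochs, i.e. 55% and 83% of the run) scaled proportionally to
the shorter run; without the decay the composite objective, whose gradient
is several times a single cross-entropy's, keeps oscillating near the
optimum. The `"tiny_wide"` teacher is first trained with plain
cross-entropy on the same data under the same schedule. Under these conditions the distilled
student's ensemble validation accuracy reaches 0.9 or better on the
majority of seeds and its mean matches or beats the cross-entropy-only
multi-exit baseline — the directional claim the full-scale experiments make
for the method. The smaller unit-test fixtures use 32x32 images and a few
epochs only.

## Known limitations

* The tensor engine is plain R on BLAS; it is deliberately sized for
  desk-scale experiments and small images. Full-scale training (224x224,
  hundreds of epochs) is out of its performance envelope.
* Teachers are pluggable but the package ships no pretrained weights; any
  frozen classifier producing `(batch, C)` logits qualifies, including
  checkpoints trained with `pretrain()`.
* Inference-time early exit (stopping at a confident shallow exit) is not
  implemented; the method averages all exits at test time.
* Reported parameter totals depend on exit-branch design details that are
  not fully pinned down externally; the package asserts parameter
  *orderings* (plain < multi-exit < teacher), not absolute counts.
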