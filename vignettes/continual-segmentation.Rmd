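---
title: "Continual segmentation with contiseg: models, strategies and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continual segmentation with contiseg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(contiseg)
```

## The problem

Segmentation models for biomedical images are usually trained *statically*:
all data is pooled, shuffled, and the model is tested on in-distribution
samples. Deployed models face a different reality: data arrives
sequentially from different scanners, sites and patient populations, and
earlier data may no longer be available when later data arrives. Training
naively on each new dataset in turn causes *catastrophic forgetting* — a
collapse of performance on earlier domains.

`contiseg` is a desk-scale laboratory for this problem. It treats each
acquisition domain as a *task* `T_1, ..., T_n`, trains one compact
segmentation network sequentially over an ordered task sequence under a
choice of continual-learning strategies, and measures the outcome with the
evaluation vocabulary of continual learning: per-class Dice, backward and
forward transfer, inter-task matrices, and training trajectories tracked on
every task's validation set.

The scenario is *domain-incremental*: the label set is constant across
tasks (after alignment) while the input distribution shifts. Task identity
is assumed known at inference time; inferring it from image statistics is
out of scope.

## Synthetic tasks as scanner domains

Real multi-site corpora are large, externally hosted and GPU-scale. The
built-in generator replaces them with seeded synthetic tasks that preserve
the *structure* of the problem:

* **Anatomy**: a parametric foreground shape per case — an ellipsoid, a
  bilobed structure (two overlapping lobes, each with its own raw label,
  emulating a head/body sub-structure pair that must later be merged), or
  an annular ring (a myocardium-like shell). Position, orientation,
  eccentricity and size are drawn per case.
* **Scanner shift**: a piecewise-constant intensity model — per-case class
  means drawn from task-level `(mean, sd)` — modulated by a smooth
  multiplicative bias field (first-order polynomial with pairwise
  interactions, amplitude 0.15) plus additive Gaussian noise. Tasks differ
  in their intensity statistics; the strongest expressible shift is a
  contrast inversion (foreground/background means swapped), which the
  `highshift_pair` preset uses.
* **Label-scheme heterogeneity**: labels beyond what the shape family
  needs are rendered as small distractor structures, so a task can carry
  an irrelevant label that alignment must map to background.

Everything is a pure function of `(spec, seed)`; per-task seeds inside a
sequence are tied to the task id, so permuting the declared specs permutes
the outputs without changing per-task content.

What the generator does **not** emulate: MRI physics, partial-volume
effects, anisotropic spacing, inter-rater label noise, or anatomical
variability beyond affine shape jitter. Passing behavioural tests on these
tasks therefore demonstrates that the training and evaluation machinery
behaves as designed under controlled distribution shift — not that any
strategy will rank the same way on clinical data.

### Study conditions

The packaged presets fix the desk-scale study conditions: 2-D images of
64 × 64 voxels, 30 cases per task, a region-of-interest fraction of 0.1,
and noise sigma 0.3 on a 0.5 intensity gap. The ROI fraction is larger
than the 1–5% of typical volumetric corpora so that short training budgets
reach stable Dice; the noise level is chosen so that static
in-distribution Dice lands in the 0.9–0.98 band typical of published
segmentation results rather than saturating at 1.0 (a saturated model has
numerically zero Fisher information, which would degenerate the
importance-based strategies). 20% of each task's cases are held out as its
test split, rounded half away from zero, and the split is stored with the
dataset so every experiment sees the same partition.

## The network

The segmentation network is a compact U-Net-style encoder–decoder, fixed
rather than auto-configured: three resolution levels, one 3^d convolution
per level on each path, instance normalization with affine parameters,
leaky ReLU (slope 0.01), 2× average pooling down, nearest-neighbour
upsampling with skip concatenation up, and a final 1 × 1 per-class
projection. The default width is 8 first-level channels (doubled per
level). Whole images are used as inputs — no patch sampling, deep
supervision or test-time augmentation.

The final projection is the **head** (parameter prefix `seg_head`);
everything before it is the shared **body**. The architecture
configuration — dimensionality, width, class count, input shape — is
frozen from the *first* task of a sequence, which is the only realistic
choice in a prospective continual setting; later inputs of a different
shape are resampled (nearest-neighbour) by the data path.

The loss is the sum of voxel-wise cross-entropy and soft Dice over
foreground classes (smoothing constant 1e-5), the composite that
high-performing segmentation pipelines use. The optimizer is plain SGD
with momentum 0.9 and a fixed learning rate (default 0.05) — no schedule,
so continual strategies are compared without learning-rate confounds.
Arg-max decoding breaks score ties toward the lowest class index.

Engine notes: images travel as `(voxels, channels)` matrices; convolution
is im2col gather + BLAS matmul with all index tables precomputed per image
shape; its input gradient is expressed as another im2col against the
flipped kernel, so no scatter operations appear anywhere. The im2col
gather and a fused instance-norm/leaky-ReLU kernel are implemented in C++
(Rcpp); gradients are verified against finite differences in the test
suite.

## Multi-head management

In multi-head mode the head is replicated at each task boundary (a value
copy of the active head, so predictions are identical at the moment of
creation), the new head is trained with the shared body, and inference
selects the head matching the task. Single-head mode re-keys the one
shared head instead. Optionally the body can be frozen after the first
stage, after which body parameters are bitwise constant. Outside LwF's
joint phase, only the active head receives gradients; earlier heads are
never touched (head isolation is asserted in the tests). With a single
task, single- and multi-head runs are bitwise identical by construction.

## Continual strategies

All six regimes share one SGD loop; each strategy only adds ingredients:

* **sequential** — the forgetting baseline; nothing is added.
* **rehearsal** — before each stage after the first, `round(fraction ×
  |train_j|)` cases are drawn uniformly without replacement from every
  previous task's train split (default fraction 0.25) and pooled with the
  current task's cases at equal per-case weight. No buffer optimization or
  re-balancing is attempted.
* **ewc** — after each stage, the diagonal empirical Fisher information is
  computed from the gradients of the log-likelihood of the model's own
  hard-predicted label maps (sum over voxels, mean over up to 10 sampled
  train cases), and the parameters are anchored. Each completed task
  contributes its own `(anchor, Fisher)` pair and the penalties sum — the
  canonical multi-task form. Default λ = 0.4. In multi-head mode only body
  parameters are penalized (heads are task-private); in single-head mode
  the head is penalized too.
* **rw** — an online variant: the Fisher is an exponential moving average
  of squared gradients (`alpha = 0.9`), and a path-integral score
  accumulates the per-parameter loss decrease normalized by the Riemannian
  path length, clipped at zero (damping `xi = 1e-3`). Total importance is
  Fisher + path score; the anchoring penalty is as in EWC (λ = 0.4).
* **lwf** — three phases per stage (multi-head only): the previous-boundary
  model's temperature-T outputs on the *new* task's train images are
  recorded once; for the first 10% of epochs the body and old heads are
  frozen while the new head warms up; for the remaining 90% body and all
  heads train jointly, old heads supervised by the recorded outputs
  through temperature-T distillation scaled by T² (default T = 8).
* **mib** — distillation against the previous network's probabilities
  hardened by the exponent 1/α with renormalization (default α = 0.9,
  distillation weight 1). Its modified cross-entropy term is implemented
  literally, but with an identical label set across tasks (our
  domain-incremental regime) it reduces exactly to the standard
  cross-entropy, as documented in `mibLosses()`.

### Numerical choices

Three choices deserve justification:

1. **Proximal anchoring.** The quadratic EWC/RW penalty is not applied as
   an explicit gradient: with momentum SGD that update is unstable once
   `lr × λ × Ω` crosses the stability limit, and a strongly weighted
   penalty (λ ≳ 4 at this scale) diverges. Instead the anchoring term is
   applied as a proximal (implicit) step after each SGD update, solving
   `θ = θ' − lr λ (B θ − A)` for θ with `B = Σ_t Ω_t`,
   `A = Σ_t Ω_t θ*_t`. This is algebraically the backward-Euler step of
   the same penalty, unconditionally stable for every λ, and pins θ to the
   importance-weighted anchor mean as λ → ∞ — which makes the
   rigidity/plasticity trade-off monotone in λ, as a regularizer should
   be. At λ = 0 the step is skipped entirely, preserving the bitwise
   reduction to sequential training.
2. **Fisher scale.** The log-likelihood whose gradient enters the Fisher
   is the *sum* over voxels, not the mean: importances then live on the
   scale at which λ values in the common range (0.1–1) are meaningful.
3. **Per-stage RNG.** Each stage draws from a stream seeded by
   `hash(run seed, stage index)`; buffer sampling, Fisher-case sampling
   and data generation each use their own derived streams. Adding or
   removing a method therefore never perturbs another method's data
   order — which is what makes the reduction identities (rehearsal
   fraction 0, λ = 0) exact to the bit.

Tie-breaks, degenerate inputs and conventions: both-empty Dice is defined
as 1 (perfect agreement on absence), empty-prediction against nonempty
truth is 0; relative transfer metrics are percentages and are flagged
undefined (NA) when the reference Dice is below 1e-3; arg-max ties go to
the lowest class index; split sizes round half away from zero.

## Evaluation

The performance matrix `dice[s, j, c]` stores the mean test Dice of class
c on task j after stage s. From it:

* **BWT_i** = `F_final(T_i) − F_at_i(T_i)` — negative means forgetting.
* **FWT_i** = `F_at_i(T_i) − F_indep_i(T_i)` — the independent reference
  model shares the architecture, configuration and training budget of the
  continual model and differs only in having seen task i alone; negative
  FWT signals plasticity loss.

Per-class metrics are kept separate; aggregation over classes is an
unweighted mean over foreground classes. Reported ± values are standard
deviations over test cases. The inter-task matrix trains one independent
model per task and cross-evaluates all pairs. During every stage the mean
foreground Dice on *every* task's test split is recorded after each epoch,
so trajectories expose forgetting and recovery around task boundaries
without storing model states.

## Design decisions that were genuinely open

* Earlier heads receive no gradient outside LwF's joint phase; whether
  they should is unclear in general, and training only the active head is
  the conservative reading of head isolation.
* LwF records teacher outputs once per stage rather than recomputing them
  each epoch — a memory/time trade-off; at desk scale the recorded soft
  maps are small.
* The exact normalization of the RW path integral varies between
  published descriptions; the update used here (see `rwUpdate()`) is
  isolated behind one function so it can be substituted.
* The MiB distillation weight is not universal; the default of 1 keeps the
  task loss and the distillation term on comparable scales at this image
  size.
* The generator's "shift level" (intensity-mean gap) is this package's
  construct and is not calibrated against any real multi-site corpus; the
  zero-gap and swapped-gap presets bracket it from both ends.

## Problem sizes used in tests and reproduction

The bundled tests and the reproduction script run entirely on synthetic
tasks at the preset scale: 64 × 64 images, 30 cases per task, 200
optimization steps per stage (10 epochs × 20 steps, batch 2), 3 run seeds
for behavioural checks; unit tests use 16 × 16 tasks with a handful of
cases. These sizes are the package's chosen study conditions; all
behavioural claims in the documentation are claims about these conditions.

## Known limitations

* The network is deliberately small and fixed; no automatic architecture
  or hyperparameter configuration is attempted.
* 3-D tasks are supported end to end but default documentation and presets
  are 2-D; spacing/resolution metadata is not modelled.
* Rehearsal stores raw cases; privacy-preserving buffer variants are not
  implemented.
* Hyperparameters are fixed per run; no tuning loop is provided, because
  in a prospective continual setting there is no validation data from
  future tasks to tune on.
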