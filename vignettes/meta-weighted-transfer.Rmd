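---
title: "Meta-learned sample weighting for transfer learning: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-learned sample weighting for transfer learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metatransfer)
```

## The problem

Activity prediction for a protein target with few labeled compounds is a
classic low-data problem. Transfer learning attacks it by pre-training a
classifier on a large multi-target source pool and fine-tuning on the target
task, but the source pool is heterogeneous: some source targets share
structure-activity relationships with the target of interest, others carry
conflicting ones. Pre-training on the wrong instances can leave the
fine-tuned model *worse* than one trained on the target alone — negative
transfer.

`metatransfer` implements a bilevel remedy: a **meta-model** `g(x, s; phi)`
maps every source instance — a compound fingerprint `x` paired with the
one-hot-encoded sequence `s` of its protein target — to a weight
`w = sigmoid(.) in (0, 1)`. The **base model** `f(x; theta)` is pre-trained
with the normalized weighted cross-entropy

```
L_train = sum_j w_j * BCE(y_j, f(x_j)) / sum_j w_j
```

and the meta-model is trained so that one accumulated gradient step of the
base model *reduces the base model's validation loss on the target training
set*, `L_val = mean BCE over the N_t target training instances`. BCE here is
the standard negative binary cross-entropy (the loss is minimized).
Differentiating `L_val` through the base update gives the second-order
meta-gradient

```
dL_val/dphi = dL_val/dtheta . dtheta/dphi = dL_val/dtheta . (-eta_theta . d2L_train/dtheta dphi)
```

with inner rate `eta_theta`; the outer update uses the combined rate
`eta'_phi = eta_phi * eta_theta`, treated as a single parameter.

## An exact, cheap form of the meta-gradient

Because `phi` enters `L_train` only through the scalar weights `w_j`, the
mixed second-order term collapses exactly. Writing `v = grad_theta L_val`
at the looked-ahead parameters, `g_j = grad_theta BCE_j`, `a_j = v . g_j`,
`W = sum w_j` and `m = sum w_j a_j / W`,

```
dL_val/dphi = -eta_theta * sum_j ((a_j - m) / W) * dw_j/dphi .
```

No Hessians appear: the implementation needs one backward pass for the
weighted source gradient, one for `v`, per-instance gradient-dot-products
`a_j` (computed layer-by-layer without materializing per-instance
gradients), and one standard backward pass through the meta-model. This is
an exact reformulation, not a first-order approximation, and
`meta_gradient()` is verified coordinate-by-coordinate against central
finite differences of `lookahead_val_loss()` (max relative error below
`1e-4`; in practice around `1e-7`).

The interpretation is transparent: an instance whose training gradient
aligns with the target's validation-descent direction better than the
weighted average (`a_j > m`) gets its weight pushed up; one that conflicts
gets pushed down.

## The training pipeline

1. **Meta-training** (`run_meta_training()`): per epoch, accumulate the
   weighted source gradient over mini-batches, take one plain lookahead step
   of size `eta_theta`, evaluate `L_val` on the target training set in a
   single batch, update `phi`, and commit the base step. Because the
   normalization makes the epoch-end gradient independent of the batch
   partition (and the network uses per-instance layer normalization, not
   batch statistics), the batch size is not a hyperparameter.
2. **Pre-training** (`pretrain_weighted()`): the base model is re-initialized;
   instances whose deterministic weight falls below the exclusion threshold
   are dropped once; each epoch draws one Monte Carlo dropout weight sample
   per surviving instance (so `epochs` samples per instance in total) and
   trains with the weighted loss.
3. **Fine-tuning** (`finetune()`): single-batch training on the low-data
   target training set, optionally with the bottleneck and normalization
   groups frozen.
4. **Evaluation** (`run_trials()`, `paired_comparison()`, `nti()`): repeated
   stratified low-data trials; rank-based ROC-AUC; trial-by-trial Wilcoxon
   signed-rank comparisons; the negative transfer index
   `NTI = mean AUC(target-only reference) - mean AUC(transfer model)`,
   positive values indicating negative transfer.

Two calculation settings bundle protocol defaults (`setting_defaults()`):
`"overlap"` (shared source/target compound spaces; bottleneck+norm frozen
during fine-tuning; 200 meta- / 150 pre-training epochs; exclusion threshold
0.05) and `"no_overlap"` (shared compounds removed from the source per the
leave-one-target-out assembly; all layers fine-tuned; 100/100 epochs). Both
fine-tune for 100 epochs.

## Architectures

* **Base model**: `d -> bottleneck -> d` (tanh), per-instance layer
  normalization with learned affine parameters, then `256 -> 64 -> 1` with a
  sigmoid output. Layer norm (not batch norm) is a deliberate choice: batch
  statistics would couple instances and break the batch-size independence of
  accumulated gradients. The bottleneck defaults to `d/16` floored at 16
  dimensions: the bottleneck is the only path from the fingerprint to the
  head, and at desk scale (`d = 64`) a 4-dimensional random projection
  destroys the gradient-alignment signal that meta-training reads; at
  fingerprint scale (`d = 4096`) the default is the usual 256.
* **Meta-model**: a fingerprint branch `d -> 128 -> 32` and a sequence branch
  `(max_len*21) -> 128 -> 32` processed independently, concatenated, fused
  through a 64-unit layer, sigmoid output. Dropout rate 0.2; by default it
  sits on the fusion layer only (see *Numerical choices*).
* Activations are tanh throughout — smooth everywhere, which keeps the
  finite-difference verification of the meta-gradient well-posed.
* Both output layers are zero-initialized: an untrained base model predicts
  exactly 0.5, and an untrained meta-model assigns weight 0.5 to every
  instance, so meta-training starts from the symmetric point where a uniform
  shift of all weights has exactly zero gradient and the first updates learn
  pure between-instance contrast.

## Optimization of the meta-model

Three stabilizers shape the outer loop; all were driven by reproducible
failure modes at desk scale and are documented here because they are the
package's own choices:

* **Null-direction projection.** The normalized training loss is invariant
  to rescaling all weights by a constant, so the meta-gradient contains a
  near-null "move all logits together" component whose accumulated drift
  saturates every weight jointly at 0 or 1 and kills the learned contrast.
  The `phi` *update direction* projects this uniform logit-shift component
  out; the exact gradient remains available as `meta_gradient()` and is what
  the finite-difference test checks.
* **Clipped, momentum-averaged SGD.** Outer updates use plain SGD with a
  global gradient-norm clip (`phi_clip_norm`, default 0.004) and heavy-ball
  momentum (0.95). Clipping bounds the per-epoch movement, so the persistent
  relevance signal integrates across epochs instead of the sigmoid
  saturating on early noise; momentum averages roughly the last twenty
  epochs of signal. Adam was evaluated for the outer loop and rejected: its
  per-coordinate normalization turns small noisy gradients into full-size
  steps and reliably locked the weights into early, sometimes wrong,
  saturation.
* **Periodic base re-initialization.** `run_meta_training()` re-initializes
  the base model every `restart_every = 20` epochs. The gradient-alignment
  signal contains a frozen noise component tied to any single random base
  initialization (its induced gradient kernel); integrating the signal
  across several initializations removes that component. This mirrors the
  protocol's re-initialization of the base model between meta-training and
  pre-training.

Default rates for desk-scale panels (`d = 64`, hundreds of instances):
`eta_theta = 0.2`, `eta'_phi = 0.3`, pre-training Adam at 0.03 and
fine-tuning Adam at 0.005. The pre-training rate was chosen so that a model
pre-trained on related sources *generalizes* to the target (reaching AUC
around 0.8 before any fine-tuning) rather than memorizing the source pool;
the gentle fine-tuning rate preserves what pre-training learned while still
letting a from-scratch control reach a fair level. At full fingerprint scale
with tens of thousands of source instances, much smaller rates (the source
protocol used Adam at `1e-5`) play the same role.

## The synthetic panel generator

`make_panel()` emulates a multi-task chemogenomic panel: one target task and
source tasks whose latent unit-norm concepts are dialled to be *related*
(cosine to the target concept at least 0.8), *irrelevant* (absolute cosine
at most 0.2) or *adversarial* (cosine at most -0.8). Fingerprints are iid
Bernoulli bit vectors; a task's labels come from thresholding the latent
score `x . beta` at the task median, so classes are balanced to within one
instance before label noise. Related tasks share at least 70% of their
synthetic sequence positions with the target, giving the meta-model's
sequence branch exploitable task-similarity signal. Generation is a pure
function of the seed.

**Adversarial labels are sign-folded, not inverted.** The obvious
construction — labeling adversarial tasks by the negated concept — turns
out to be almost harmless for a flexible classifier: its labels are a
monotone inversion of the target ranking, and fine-tuning repairs the
damage by flipping the sign of the output layer (ROC-AUC is invariant under
monotone transforms, so an anti-correlated ranking is one sign away from a
correlated one). Measured on this package's own pipeline, purely
negation-labeled source panels *helped* the target task on 8 of 8 seeds.
Adversarial tasks therefore label the *fold* of the score: instances whose
score sits far from the task median on either side are active, mid-range
instances inactive. Folded labels are non-monotone in the target score —
the synthetic analogue of activity cliffs, where structurally similar
compounds carry opposite activities — and no output-layer sign flip can
undo a representation trained on them. With this construction the
generator's transfer dial behaves as intended: standard transfer from
adversarial-only panels shows positive NTI on 9 of 10 seeds, while
related-only panels show clear positive transfer.

Generator defaults (chosen once as the package's study conditions): `d = 64`
bits at density 0.25 (a few dozen features per compound, the scaled-down
analogue of a sparse circular fingerprint), 100 instances per task, 3
related + 3 adversarial source tasks, label-flip noise 0.1, concept jitter
0.25 (related cosines around 0.97), sequences of length 60. What the
generator does *not* emulate: real chemistry (no molecular graphs or
physicochemical realism), assay-noise distributions, inter-compound
structural correlation within a task, and class imbalance. Passing the
synthetic acceptance experiments therefore demonstrates the *mechanism* —
weights separate by relevance and mitigate negative transfer — not
performance on real bioactivity data.

## Exclusion threshold

Pre-training excludes instances whose deterministic weight is below a
threshold, once, before the first epoch (re-sampling exclusions each epoch
would change the effective dataset per epoch). The source protocol fixes
0.05 and 0.20 for its two settings but derives both from the weight
distribution observed after meta-training. The package implements that rule
directly: `weight_threshold = "auto"` places the cut in the valley of the
distribution (two-means split) and only applies it when the distribution is
clearly bimodal — cluster means at least 0.25 apart and at most 10% of
weights within 0.1 of the cut. On a panel where every source task is
relevant the distribution is unimodal and nothing is excluded; on an
adversarial-dominated panel the cut lands between the two weight modes.
`"auto"` is the default for the `no_overlap` setting; the fixed numeric
values remain available and are the defaults elsewhere.

## Monte Carlo dropout

During pre-training, weights are re-sampled from the meta-model each epoch
with dropout active (one sample per surviving instance per epoch). The rate
is 0.2. Dropout is placed on the fusion hidden layer only: with dropout
after every hidden layer, the weight-sample variance on desk-scale pools
was large enough that the per-epoch reweighting noise swamped the learned
contrast and could actively degrade pre-training; the single-layer
placement keeps the sample standard deviation moderate (about 0.05) while
preserving the regularizing effect of stochastic weights. The all-layer
placement remains available (`dropout_placement = "all"`).

## Numerical choices

* Probabilities are clamped to `[1e-7, 1 - 1e-7]` inside the cross-entropy;
  meta weights to `[1e-12, 1 - 1e-12]` so they are strictly inside (0, 1).
* Layer-norm variance uses a `1e-5` stabilizer.
* Frozen layer groups are skipped entirely by the optimizer (not given zero
  gradients), so frozen parameters change by exactly zero even under Adam.
* The Wilcoxon signed-rank test drops zero differences, mid-ranks ties, and
  uses the exact convolution null for up to 25 non-zero differences (normal
  approximation with continuity and tie corrections above); identical
  methods report p = 1 rather than an error. One- vs two-sided is not
  specified by convention in this field's reports; the two-sided test is
  used as the conservative choice.
* ROC-AUC uses the rank (Mann-Whitney) formula with averaged ties rather
  than trapezoidal integration: exact tie handling in O(n log n).
* Seed fan-out: every stage and trial derives its own 31-bit seed from the
  global seed and a key path (`derive_seed()`), so runs are reproducible
  and sub-experiments are independent.

## Acceptance experiment sizes

The simulation studies behind the package's tests use: 10 fixed panel seeds
per experiment; the weight-separation experiment at the generator defaults
with 50 target training instances and 100 meta-epochs; the transfer-dial
experiment on adversarial-only panels with 5 trials per seed; the
mitigation (1 related + 5 adversarial) and no-harm (6 related) experiments
with 10 stratified fine-tuning trials per seed. Per-seed success of the
weight-separation property is around 85-90%, so a fixed 10-seed panel
typically shows 9/10; single seeds can fail without indicating a defect.

## Known limitations

* The one-step lookahead is greedy: the meta-objective scores the next
  epoch's improvement, not final fine-tuned performance.
* Relative weighting inside the normalized loss matters most while the base
  model is still fitting; near convergence only the exclusion step changes
  the outcome. Mitigation of negative transfer therefore depends on the
  training budget staying in the generalizing regime.
* The hashed featurizer is a synthetic stand-in; real applications should
  plug in actual circular fingerprints through the featurizer interface.
* Memory: instance sets store one dense sequence-encoding row per instance;
  for very long sequences and large pools a per-task encoding map would be
  preferable.
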