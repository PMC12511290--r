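# metatransfer

Meta-learned sample weighting for transfer learning on low-data bioactivity
tasks.

## The problem and who this is for

Predicting whether compounds inhibit a protein target is hard when only a
handful of labeled compounds exist for that target. Standard transfer
learning pre-trains a classifier on a large multi-target source pool
(compound fingerprints with activity labels across many related proteins)
and fine-tunes on the low-data target — but when parts of the source pool
carry conflicting structure–activity relationships, pre-training *hurts*:
negative transfer. This package is for computational chemists and machine
learning researchers who want an instance-level defence: learn how much each
source example should contribute to pre-training, so relevant examples are
kept and harmful ones suppressed, per target.

## The method

A base classifier `f(x; θ)` is pre-trained on the source pool `S^(−t)`
(all tasks except the target `t`) with a normalized weighted cross-entropy,

    L_train = Σ_j w_j · BCE(y_j, f(x_j; θ)) / Σ_j w_j ,

where each weight `w_j = g(x_j, s_j; φ) ∈ (0,1)` is produced by a
meta-model from the compound fingerprint and the one-hot-encoded sequence
of its protein. The meta-objective is generalization to the target: the
mean cross-entropy `L_val` of the base model on the `N_t` target training
instances, minimized with respect to `φ` *through* the base model's update,

    ∂L_val/∂φ = ∂L_val/∂θ · ∂θ/∂φ = ∂L_val/∂θ · (−η_θ · ∂²L_train/∂θ∂φ) ,

with the combined outer rate `η′_φ = η_φ·η_θ` treated as one parameter.
Because `φ` enters `L_train` only through scalar weights, the second-order
term collapses exactly to first-order quantities (see the methods
vignette), and the implementation computes it analytically — verified
against central finite differences to ~1e−9 relative error. Gradients are
accumulated over mini-batches and models updated once per epoch, making
batch size a non-hyperparameter; pre-training samples a fresh Monte Carlo
dropout weight per surviving instance each epoch, after excluding instances
whose deterministic weight falls below a threshold.

Evaluation follows the low-data protocol: repeated stratified 50-compound
fine-tuning trials, rank-based ROC-AUC, trial-by-trial Wilcoxon signed-rank
comparisons, and the negative transfer index
`NTI = mean AUC(target-only) − mean AUC(transfer model)` (positive ⇒
negative transfer).

The package also ships the curation rules for raw Ki tables (geometric-mean
aggregation under a max/min ≤ 10 consistency rule, 1000 nM potency
threshold, < 1000 Da mass filter, leave-one-target-out source assembly with
optional shared-compound removal) and a synthetic multi-task panel
generator whose source tasks are dialled to be related, irrelevant or
adversarial to the target — so every stage is testable without downloads.

## Worked example

An adversarial-dominated synthetic panel (1 related + 5 adversarial source
tasks, 64-bit fingerprints, 100 instances per task), three methods, ten
stratified 50-compound trials each:

```r
library(metatransfer)

cfg <- experiment_config(
  mode = "synthetic", setting = "no_overlap",
  methods = c("meta", "standard", "target_only"),
  panel = synthetic_panel_config(n_related = 1, n_adversarial = 5),
  n_trials = 10, n_train = 50, seed = 42)
report <- run_experiment(cfg)
print(report)
#> <evaluation_report>
#>   mean AUC meta         0.6454
#>   mean AUC standard     0.4966
#>   mean AUC target_only  0.6632
#>   meta vs standard: median dAUC +0.1584, p = 0.001953 (**)
#>   meta vs target_only: median dAUC -0.0096, p = 0.6074 (ns)
#>   NTI (target_only - meta): +0.0178
#>   NTI (target_only - standard): +0.1666
```

Reading the numbers: standard transfer learning is destroyed by the
adversarial sources (mean AUC 0.50 — no better than random — and a large
positive NTI of +0.17 against the target-only control). The meta-weighted
pipeline suppresses those sources and recovers to the target-only level
(NTI +0.02), beating standard transfer on every trial (median per-trial
AUC gain +0.16, Wilcoxon p = 0.002). On panels of purely related sources
the two pipelines perform alike, so the weighting does no harm when
transfer is positive.

The learned weights themselves are inspectable:

```r
p  <- make_panel(synthetic_panel_config(seed = 1))       # 3 related + 3 adversarial
sp <- stratified_split(p$target, 50, seed = 1)
fit <- run_meta_training(base_model(64), meta_model(64, ncol(p$source$S)),
                         p$source, sp$train, epochs = 100)
wt <- export_weights(fit$meta, p$source)
tapply(wt$weight, p$source$task_id, mean)   # related tasks high, adversarial low
```

A thin command-line wrapper with subcommands `simulate`, `curate`,
`meta-train`, `run-trials`, `evaluate` and `run-experiment` is installed at
`inst/cli/metatransfer.R`.

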