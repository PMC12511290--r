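#' Pre-training configuration
#'
#' @param epochs number of pre-training epochs (also the number of Monte
#'   Carlo weight samples drawn per surviving source instance).
#' @param weight_threshold instances whose deterministic weight falls below
#'   this value are excluded once, before the first epoch; a number in
#'   `[0, 1)`, or `"auto"` to place the cut in the valley of the observed
#'   weight distribution (two-means split, applied only when the
#'   distribution is clearly bimodal: cluster means at least 0.25 apart;
#'   otherwise nothing is excluded). The automatic rule mirrors choosing the
#'   threshold from the weight distribution observed after meta-training.
#' @param mc_dropout sample a fresh stochastic weight per surviving instance
#'   each epoch (Monte Carlo dropout); otherwise the deterministic weights
#'   are reused every epoch.
#' @param freeze_groups layer groups to freeze later, during fine-tuning
#'   (carried in the config so a calculation setting is one object).
#' @param lr learning rate of the committed updates.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param batch_size optional source mini-batch size.
#' @param seed seed for the per-epoch Monte Carlo draws.
#' @return an object of class `pretrain_config`.
#' @export
pretrain_config <- function(epochs = 150L, weight_threshold = 0.05,
                            mc_dropout = TRUE, freeze_groups = character(0),
                            lr = 0.03, optimizer = "adam",
                            batch_size = NULL, seed = 1L) {
  if (epochs < 1L) config_stop("epochs", "must be >= 1")
  if (is.character(weight_threshold)) {
    if (!identical(weight_threshold, "auto"))
      config_stop("weight_threshold", "must be numeric in [0, 1) or \"auto\"")
  } else if (weight_threshold < 0 || weight_threshold >= 1) {
    config_stop("weight_threshold", "must lie in [0, 1)")
  }
  structure(list(epochs = as.integer(epochs),
                 weight_threshold = weight_threshold,
                 mc_dropout = isTRUE(mc_dropout),
                 freeze_groups = freeze_groups, lr = lr,
                 optimizer = optimizer, batch_size = batch_size,
                 seed = as.integer(seed)),
            class = "pretrain_config")
}

# shared training loop: epoch-end accumulated updates with per-epoch weights
# supplied by weight_fn(epoch) (length n, or a scalar 1 for unweighted)
fit_epochs <- function(base, X, y, weight_fn, epochs, lr, optimizer,
                       batch_size = NULL, keep_history = FALSE) {
  opt <- make_optimizer(optimizer, lr = lr)
  frozen <- frozen_param_names(base)
  losses <- numeric(epochs)
  whist <- if (keep_history) matrix(NA_real_, epochs, length(y)) else NULL
  for (e in seq_len(epochs)) {
    w <- weight_fn(e)
    if (length(w) == 1L) w <- rep(w, length(y))
    if (keep_history) whist[e, ] <- w
    tr <- weighted_epoch_grads(base, X, y, w, batch_size)
    if (!is.finite(tr$loss)) stop(sprintf("non-finite loss at epoch %d", e),
                                  call. = FALSE)
    st <- optimizer_step(opt, base$params, tr$grad, frozen = frozen)
    base$params <- st$params
    opt <- st$opt
    losses[e] <- tr$loss
  }
  attr(base, "loss_history") <- losses
  if (keep_history) attr(base, "weight_history") <- whist
  base
}

#' Pre-train the base model with meta-learned weights (Monte Carlo dropout)
#'
#' Implements weighted pre-training: source instances whose deterministic
#' (dropout-off) meta-model weight falls below `cfg$weight_threshold` are
#' excluded once before the first epoch; in every epoch a fresh stochastic
#' weight is sampled per surviving instance through Monte Carlo dropout
#' (`cfg$mc_dropout = TRUE`; `epochs` samples per instance in total) and used
#' in the normalized weighted cross-entropy; gradients are accumulated over
#' mini-batches and the model is updated once per epoch.
#'
#' @param base a freshly (re-)initialized [base_model()].
#' @param meta a trained [meta_model()].
#' @param S source [instance_set].
#' @param cfg a [pretrain_config()].
#' @param keep_weight_history also return the epochs-by-instances matrix of
#'   sampled weights (as attribute `weight_history`).
#' @return the pre-trained base model, with attribute `loss_history`.
#' @export
pretrain_weighted <- function(base, meta, S, cfg,
                              keep_weight_history = FALSE) {
  stopifnot(inherits(cfg, "pretrain_config"))
  if (length(S) == 0L) stop("empty source dataset", call. = FALSE)
  w0 <- meta_forward(meta, S$X, S$S, stochastic = FALSE)
  thr <- if (identical(cfg$weight_threshold, "auto"))
    auto_weight_threshold(w0) else cfg$weight_threshold
  keep <- w0 >= thr
  if (!any(keep)) stop("threshold removed entire source set", call. = FALSE)
  Sk <- S[keep]
  weight_fn <- function(e) {
    if (cfg$mc_dropout) {
      with_local_seed(derive_seed(cfg$seed, "mc", e),
                      meta_forward(meta, Sk$X, Sk$S, stochastic = TRUE))
    } else {
      w0[keep]
    }
  }
  out <- fit_epochs(base, Sk$X, Sk$y, weight_fn, cfg$epochs, cfg$lr,
                    cfg$optimizer, cfg$batch_size,
                    keep_history = keep_weight_history)
  attr(out, "n_excluded") <- sum(!keep)
  attr(out, "weight_threshold") <- thr
  out
}

#' Distribution-based exclusion threshold
#'
#' Places the low-weight exclusion cut in the valley of a bimodal weight
#' distribution: a two-means (1-d k-means) split of the deterministic
#' weights; the threshold is the midpoint between the cluster means. The cut
#' is only applied when the distribution is genuinely bimodal: the cluster
#' means must be at least `min_gap` apart and the valley must be sparsely
#' populated (at most `max_valley` of the weights within 0.1 of the cut).
#' Broad unimodal distributions - e.g. when every source task is relevant -
#' yield threshold 0, excluding nothing.
#'
#' @param w deterministic meta-model weights of all source instances.
#' @param min_gap minimal distance between cluster means for the cut to be
#'   applied.
#' @param max_valley maximal fraction of weights within `cut +/- 0.1` for
#'   the distribution to count as bimodal.
#' @return a scalar threshold in `[0, 1)`.
#' @export
auto_weight_threshold <- function(w, min_gap = 0.25, max_valley = 0.10) {
  if (length(unique(w)) < 2L) return(0)
  km <- stats::kmeans(w, centers = range(w))
  lo <- min(km$centers); hi <- max(km$centers)
  if (hi - lo < min_gap) return(0)
  cut <- (lo + hi) / 2
  if (mean(abs(w - cut) < 0.1) > max_valley) return(0)
  cut
}

#' Standard (unweighted) pre-training
#'
#' The conventional transfer-learning baseline: identical loop to
#' [pretrain_weighted()] with all weights equal to one and no exclusion, so
#' any performance difference is attributable to the learned weights.
#'
#' @param base a freshly initialized [base_model()].
#' @param S source [instance_set].
#' @param epochs number of epochs.
#' @param lr learning rate.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param batch_size optional mini-batch size.
#' @param seed unused (kept for interface symmetry; the loop is
#'   deterministic).
#' @return the pre-trained base model, with attribute `loss_history`.
#' @export
pretrain_standard <- function(base, S, epochs = 150L, lr = 0.03,
                              optimizer = "adam", batch_size = NULL,
                              seed = 1L) {
  if (length(S) == 0L) stop("empty source dataset", call. = FALSE)
  fit_epochs(base, S$X, S$y, function(e) 1, epochs, lr, optimizer, batch_size)
}

#' Fine-tune on the low-data target task
#'
#' Trains the base model on the target training instances in a single batch
#' with plain BCE, leaving the requested layer groups frozen (exactly zero
#' parameter change). Freezing the bottleneck and normalization groups
#' retains the pre-trained feature representation; passing no groups
#' fine-tunes all layers.
#'
#' @param base a pre-trained (or fresh, for the target-only control)
#'   [base_model()].
#' @param target a [target_split()]; training uses `target$train`.
#' @param epochs fine-tuning epochs; default 100.
#' @param freeze_groups layer groups to freeze, e.g.
#'   `c("bottleneck_down", "bottleneck_up", "norm")`.
#' @param lr learning rate.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param seed unused (deterministic loop; kept for interface symmetry).
#' @return the fine-tuned base model.
#' @export
finetune <- function(base, target, epochs = 100L,
                     freeze_groups = character(0), lr = 0.005,
                     optimizer = "adam", seed = 1L) {
  train <- if (inherits(target, "target_split")) target$train else target
  if (length(train) == 0L) stop("empty fine-tuning training set", call. = FALSE)
  base <- freeze(base, freeze_groups)
  if (epochs == 0L) return(base)
  fit_epochs(base, train$X, train$y, function(e) 1, epochs, lr, optimizer)
}

#' Trial protocol defaults for a calculation setting
#'
#' The first calculation setting (shared source/target compound spaces)
#' freezes the bottleneck and normalization groups during fine-tuning and
#' uses 200 meta- / 150 pre-training epochs with exclusion threshold 0.05;
#' the second setting (non-overlapping compound sets) fine-tunes all layers
#' and uses 100/100 epochs with threshold 0.20. Both fine-tune for 100
#' epochs. Learning rates are desk-scale defaults for the built-in synthetic
#' panels; override them for other data.
#'
#' @param setting `"overlap"` (first setting) or `"no_overlap"` (second).
#' @return a list of protocol parameters consumed by [run_trials()].
#' @export
setting_defaults <- function(setting = c("overlap", "no_overlap")) {
  setting <- match.arg(setting)
  common <- list(finetune_epochs = 100L, mc_dropout = TRUE,
                 eta_theta = 0.2, eta_phi_comb = 0.3,
                 meta_optimizer = "sgd", phi_clip_norm = 0.004,
                 phi_momentum = 0.95, restart_every = 20L,
                 lr_pretrain = 0.03, lr_finetune = 0.005,
                 optimizer = "adam", batch_size = NULL)
  if (setting == "overlap") {
    c(list(meta_epochs = 200L, pretrain_epochs = 150L,
           weight_threshold = 0.05,
           freeze_groups = c("bottleneck_down", "bottleneck_up", "norm")),
      common)
  } else {
    c(list(meta_epochs = 100L, pretrain_epochs = 100L,
           weight_threshold = "auto", freeze_groups = character(0)),
      common)
  }
}

#' Run repeated fine-tuning trials for one method
#'
#' Pre-training (and, for the meta method, meta-training) is performed once;
#' each trial then draws a fresh stratified low-data split of the target
#' task, fine-tunes a copy of the pre-trained model (or trains the control
#' from scratch), and evaluates ROC-AUC on that trial's held-out instances.
#' The `rf_control` method trains a random forest (100 trees, sqrt(d)
#' features per split) on the target training instances only.
#'
#' @param panel a `synthetic_panel` from [make_panel()], or any list with
#'   `source` and `target` [instance_set]s.
#' @param method one of `"meta"`, `"standard"`, `"target_only"`,
#'   `"rf_control"`.
#' @param n_trials number of independent fine-tuning trials.
#' @param n_train training instances per trial (stratified).
#' @param seed global seed; per-trial seeds are derived from it.
#' @param control protocol parameters, see [setting_defaults()].
#' @return data frame with `method`, `trial`, `auc`, `n_test`.
#' @export
run_trials <- function(panel, method = c("meta", "standard", "target_only",
                                         "rf_control"),
                       n_trials = 50L, n_train = 50L, seed = 1L,
                       control = setting_defaults("no_overlap")) {
  method <- match.arg(method)
  S <- panel$source
  target <- panel$target
  if (n_train >= length(target))
    stop("n_train must be smaller than the target task", call. = FALSE)
  d <- ncol(target$X)

  pre <- NULL
  if (method %in% c("meta", "standard")) {
    base0 <- base_model(d, seed = derive_seed(seed, "base_pre"))
    if (method == "meta") {
      split0 <- stratified_split(target, n_train, derive_seed(seed, "metasplit"))
      meta0 <- meta_model(d, ncol(target$S), seed = derive_seed(seed, "meta"))
      fit <- run_meta_training(
        base_model(d, seed = derive_seed(seed, "base_meta")), meta0, S,
        split0$train, epochs = control$meta_epochs,
        eta_theta = control$eta_theta, eta_phi_comb = control$eta_phi_comb,
        optimizer = control$meta_optimizer,
        phi_clip_norm = control$phi_clip_norm,
        phi_momentum = control$phi_momentum,
        batch_size = control$batch_size,
        restart_every = control$restart_every,
        seed = derive_seed(seed, "meta_restart"))
      cfg <- pretrain_config(epochs = control$pretrain_epochs,
                             weight_threshold = control$weight_threshold,
                             mc_dropout = control$mc_dropout,
                             freeze_groups = control$freeze_groups,
                             lr = control$lr_pretrain,
                             optimizer = control$optimizer,
                             batch_size = control$batch_size,
                             seed = derive_seed(seed, "mc"))
      pre <- pretrain_weighted(base0, fit$meta, S, cfg)
    } else {
      pre <- pretrain_standard(base0, S, epochs = control$pretrain_epochs,
                               lr = control$lr_pretrain,
                               optimizer = control$optimizer,
                               batch_size = control$batch_size)
    }
  }

  res <- lapply(seq_len(n_trials), function(i) {
    sp <- stratified_split(target, n_train, derive_seed(seed, "trial", i))
    scores <- switch(method,
      meta = ,
      standard = base_forward(
        finetune(pre, sp, epochs = control$finetune_epochs,
                 freeze_groups = control$freeze_groups,
                 lr = control$lr_finetune, optimizer = control$optimizer),
        sp$test$X),
      target_only = base_forward(
        finetune(base_model(d, seed = derive_seed(seed, "tonly", i)), sp,
                 epochs = control$finetune_epochs,
                 lr = control$lr_finetune, optimizer = control$optimizer),
        sp$test$X),
      rf_control = rf_scores(sp, seed = derive_seed(seed, "rf", i)))
    data.frame(method = method, trial = i,
               auc = roc_auc(scores, sp$test$y),
               n_test = length(sp$test), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# random-forest control scores: trained on the trial's target training set
rf_scores <- function(sp, seed) {
  with_local_seed(seed, {
    fit <- randomForest::randomForest(
      x = sp$train$X, y = factor(sp$train$y, levels = c(0, 1)),
      ntree = 100L, mtry = max(1L, floor(sqrt(ncol(sp$train$X)))))
    stats::predict(fit, sp$test$X, type = "prob")[, "1"]
  })
}
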