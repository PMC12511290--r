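test_that("pretrain configuration is validated", {
  expect_error(pretrain_config(epochs = 0), "epochs")
  expect_error(pretrain_config(weight_threshold = 1), "weight_threshold")
  expect_error(pretrain_config(weight_threshold = "magic"), "weight_threshold")
  expect_s3_class(pretrain_config(weight_threshold = "auto"), "pretrain_config")
})

test_that("low-weight exclusion counts follow the threshold rule", {
  w <- c(0.05, 0.15, 0.25, 0.9)
  expect_equal(sum(w >= 0.20), 2)      # two instances survive a 0.20 cut
  expect_equal(sum(w >= 0), 4)         # threshold 0 keeps everything
  # raising the threshold never increases the surviving count
  survivors <- vapply(seq(0, 0.95, by = 0.05), function(t) sum(w >= t), 0)
  expect_true(all(diff(survivors) <= 0))
})

test_that("the automatic threshold cuts bimodal but not unimodal distributions", {
  set.seed(3)
  bimodal <- c(rnorm(100, 0.15, 0.03), rnorm(100, 0.8, 0.05))
  thr <- auto_weight_threshold(bimodal)
  expect_gt(thr, 0.3); expect_lt(thr, 0.65)
  unimodal <- rnorm(200, 0.5, 0.12)
  expect_equal(auto_weight_threshold(unimodal), 0)
  expect_equal(auto_weight_threshold(rep(0.5, 10)), 0)
})

test_that("constant-half weights with threshold 0 and MC off reduce to standard pre-training", {
  panel <- tiny_panel(seed = 21, n = 15)
  meta0 <- zero_meta(tiny_meta(8, ncol(panel$source$S)))
  base <- tiny_base(seed = 6)
  cfg <- pretrain_config(epochs = 8, weight_threshold = 0,
                         mc_dropout = FALSE, lr = 0.05, seed = 1)
  mw <- pretrain_weighted(base, meta0, panel$source, cfg)
  std <- pretrain_standard(base, panel$source, epochs = 8, lr = 0.05)
  for (nm in names(base$params))
    expect_lt(max(abs(get_params(mw)[[nm]] - get_params(std)[[nm]])), 1e-6)
  expect_equal(attr(mw, "n_excluded"), 0L)
})

test_that("MC dropout draws exactly one fresh weight sample per instance per epoch", {
  panel <- tiny_panel(seed = 22, n = 15)
  fit <- run_meta_training(tiny_base(), tiny_meta(8, ncol(panel$source$S)),
                           panel$source, panel$target[1:8], epochs = 5)
  cfg <- pretrain_config(epochs = 6, weight_threshold = 0, mc_dropout = TRUE,
                         lr = 0.05, seed = 9)
  out <- pretrain_weighted(tiny_base(), fit$meta, panel$source, cfg,
                           keep_weight_history = TRUE)
  wh <- attr(out, "weight_history")
  expect_equal(dim(wh), c(6L, length(panel$source)))
  expect_true(all(is.finite(wh)))
  # samples differ between epochs (stochastic), reruns are seed-reproducible
  expect_gt(max(apply(wh, 2, sd)), 0)
  out2 <- pretrain_weighted(tiny_base(), fit$meta, panel$source, cfg,
                            keep_weight_history = TRUE)
  expect_identical(wh, attr(out2, "weight_history"))
  # excluding everything is an error
  expect_error(pretrain_weighted(tiny_base(), zero_meta(fit$meta),
                                 panel$source,
                                 pretrain_config(epochs = 2,
                                                 weight_threshold = 0.9)),
               "entire source set")
})

test_that("full-batch gradient descent decreases the loss on a separable panel", {
  panel <- make_panel(synthetic_panel_config(d = 16, n_per_task = 20,
                                             n_related = 2, n_adversarial = 0,
                                             label_noise = 0, seq_len = 4,
                                             seed = 5))
  out <- pretrain_standard(base_model(16, bottleneck = 8,
                                      hidden = c(16L, 8L), seed = 2),
                           panel$source, epochs = 40, lr = 0.3,
                           optimizer = "sgd")
  losses <- attr(out, "loss_history")
  expect_true(all(diff(losses) < 1e-3))
  expect_lt(losses[40], losses[1])
})

test_that("fine-tuning respects its contracts and improves the training fit", {
  panel <- tiny_panel(seed = 23, n = 30, noise = 0)
  sp <- stratified_split(panel$target, 20, seed = 2)
  base <- tiny_base(seed = 3)
  expect_identical(get_params(finetune(base, sp, epochs = 0)),
                   get_params(base))
  before <- roc_auc(base_forward(base, sp$train$X), sp$train$y)
  after_model <- finetune(base, sp, epochs = 150, lr = 0.05)
  after <- roc_auc(base_forward(after_model, sp$train$X), sp$train$y)
  expect_gt(after, before)
  expect_error(finetune(base, sp$train[0], epochs = 5), "empty")
})

test_that("run_trials returns one AUC per trial, deterministically", {
  panel <- make_panel(synthetic_panel_config(d = 16, n_per_task = 30,
                                             n_related = 1, n_adversarial = 1,
                                             seq_len = 4, seed = 31))
  ctl <- setting_defaults("no_overlap")
  ctl$finetune_epochs <- 20L
  r1 <- run_trials(panel, "target_only", n_trials = 1, n_train = 15,
                   seed = 2, control = ctl)
  expect_equal(nrow(r1), 1)
  expect_true(r1$auc >= 0 && r1$auc <= 1)
  r2 <- run_trials(panel, "rf_control", n_trials = 3, n_train = 15,
                   seed = 2, control = ctl)
  r3 <- run_trials(panel, "rf_control", n_trials = 3, n_train = 15,
                   seed = 2, control = ctl)
  expect_identical(r2$auc, r3$auc)
  expect_error(run_trials(panel, "standard", n_trials = 1, n_train = 30,
                          seed = 1, control = ctl), "smaller")
})

test_that("a target-only learner masters a noise-free task given generous data", {
  panel <- make_panel(synthetic_panel_config(d = 32, bit_density = 0.25,
                                             label_noise = 0,
                                             n_per_task = 200, seed = 3))
  ctl <- setting_defaults("no_overlap")
  ctl$finetune_epochs <- 300L
  ctl$lr_finetune <- 0.02
  r <- run_trials(panel, "target_only", n_trials = 3, n_train = 160,
                  seed = 3, control = ctl)
  expect_gt(mean(r$auc), 0.9)
})
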