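test_that("normalized weighted cross-entropy matches hand arithmetic", {
  # two instances with per-instance BCEs 1.0 and 3.0 and weights 0.8 / 0.2
  y <- c(1, 1)
  p <- c(exp(-1), exp(-3))
  l <- bce_loss(y, p)
  expect_equal(l, c(1, 3), tolerance = 1e-9)
  w <- c(0.8, 0.2)
  expect_equal(sum(w * l) / sum(w), 1.4, tolerance = 1e-9)
})

test_that("constant meta-weights cancel in the normalized loss", {
  panel <- tiny_panel(seed = 6, n = 12)
  base <- tiny_base()
  meta0 <- zero_meta(tiny_meta(8, ncol(panel$source$S)))  # w = 0.5 everywhere
  unweighted <- mean(bce_loss(panel$source$y,
                              base_forward(base, panel$source$X)))
  expect_equal(weighted_train_loss(base, meta0, panel$source), unweighted,
               tolerance = 1e-12)
  expect_error(weighted_train_loss(base, meta0, panel$source[0]), "empty")
})

test_that("validation loss has its closed-form values", {
  panel <- tiny_panel(seed = 6, n = 12)
  base <- tiny_base()   # predicts exactly 0.5 -> loss log(2)
  expect_equal(validation_loss(base, panel$target), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(1, 0.25), -log(0.25), tolerance = 1e-12)
  expect_error(validation_loss(base, panel$target[0]), "empty")
})

test_that("meta_step is the identity at eta_theta = 0 and for a zeroed meta-model", {
  panel <- tiny_panel(seed = 11)
  Ttr <- panel$target[1:5]
  base <- tiny_base()
  meta <- tiny_meta(8, ncol(panel$source$S))
  st0 <- meta_train_state(base, meta, eta_theta = 0, eta_phi_comb = 1)
  st0 <- meta_step(st0, panel$source, Ttr)
  expect_identical(st0$base$params, base$params)
  expect_identical(st0$meta$params, meta$params)
  expect_equal(nrow(st0$history), 1)
  # all-zero meta parameters: weights constant 0.5, phi gradient exactly zero,
  # but theta still takes its lookahead step
  mz <- zero_meta(meta)
  st1 <- meta_train_state(base, mz, eta_theta = 0.5, eta_phi_comb = 1,
                          phi_clip_norm = Inf, phi_momentum = 0)
  st1 <- meta_step(st1, panel$source, Ttr)
  expect_equal(st1$meta$params, mz$params, tolerance = 1e-12)
  expect_gt(max(abs(st1$base$params$W_out - base$params$W_out)), 0)
})

test_that("the analytic meta-gradient matches central finite differences", {
  panel <- tiny_panel(seed = 11)     # d = 8, 2 source tasks x 10 instances
  Ttr <- panel$target[1:5]
  base <- tiny_base()
  meta <- tiny_meta(8, ncol(panel$source$S))
  eta <- 0.5
  g <- unlist(meta_gradient(base, meta, panel$source, Ttr, eta))
  phi <- get_params(meta)
  fv <- metatransfer:::flatten_params(phi)
  h <- 1e-4
  fd <- vapply(seq_along(fv), function(i) {
    up <- fv; up[i] <- up[i] + h
    dn <- fv; dn[i] <- dn[i] - h
    (lookahead_val_loss(base, set_params(meta,
       metatransfer:::unflatten_params(up, phi)), panel$source, Ttr, eta) -
     lookahead_val_loss(base, set_params(meta,
       metatransfer:::unflatten_params(dn, phi)), panel$source, Ttr, eta)) / (2 * h)
  }, 0)
  rel <- abs(g - fd) / pmax(abs(fd), 1e-8)
  expect_lt(max(rel), 1e-4)
})

test_that("mini-batch accumulation reproduces the full-batch epoch gradient", {
  panel <- tiny_panel(seed = 8, n = 10)
  base <- tiny_base()
  meta <- tiny_meta(8, ncol(panel$source$S))
  w <- meta_forward(meta, panel$source$X, panel$source$S)
  full <- metatransfer:::weighted_epoch_grads(base, panel$source$X,
                                              panel$source$y, w, NULL)
  for (B in c(2, 5)) {
    bs <- ceiling(length(panel$source) / B)
    batched <- metatransfer:::weighted_epoch_grads(base, panel$source$X,
                                                   panel$source$y, w, bs)
    for (nm in names(full$grad)) {
      denom <- pmax(abs(full$grad[[nm]]), 1e-12)
      expect_lt(max(abs(batched$grad[[nm]] - full$grad[[nm]]) / denom), 1e-6)
    }
  }
})

test_that("constant-half weights reproduce unweighted training bit-for-bit", {
  panel <- tiny_panel(seed = 9, n = 15)
  base <- tiny_base()
  meta0 <- zero_meta(tiny_meta(8, ncol(panel$source$S)))
  # committed theta trajectory of meta-training with w = 1/2 equals plain
  # full-batch gradient descent with the same step size
  st <- meta_train_state(base, meta0, eta_theta = 0.1, eta_phi_comb = 1,
                         optimizer = "sgd")
  for (e in 1:5) st <- meta_step(st, panel$source, panel$target[1:8])
  ref <- pretrain_standard(base, panel$source, epochs = 5, lr = 0.1,
                           optimizer = "sgd")
  for (nm in names(base$params))
    expect_lt(max(abs(st$base$params[[nm]] - get_params(ref)[[nm]])), 1e-6)
})

test_that("the phi update direction is set by the combined rate alone", {
  panel <- tiny_panel(seed = 12)
  Ttr <- panel$target[1:5]
  base <- tiny_base()
  meta <- tiny_meta(8, ncol(panel$source$S))
  step_of <- function(ephi) {
    st <- meta_train_state(base, meta, eta_theta = 0.3, eta_phi_comb = ephi,
                           optimizer = "sgd", phi_clip_norm = Inf,
                           phi_momentum = 0)
    st <- meta_step(st, panel$source, Ttr)
    metatransfer:::flatten_params(st$meta$params) -
      metatransfer:::flatten_params(meta$params)
  }
  d1 <- step_of(0.5)
  d2 <- step_of(1.0)
  expect_equal(d2, 2 * d1, tolerance = 1e-9)   # magnitude linear, direction equal
})

test_that("run_meta_training is deterministic and the zero-epoch identity", {
  panel <- tiny_panel(seed = 13)
  base <- tiny_base()
  meta <- tiny_meta(8, ncol(panel$source$S))
  f0 <- run_meta_training(base, meta, panel$source, panel$target[1:5],
                          epochs = 0)
  expect_identical(f0$meta$params, meta$params)
  f1 <- run_meta_training(base, meta, panel$source, panel$target[1:5],
                          epochs = 4)
  f2 <- run_meta_training(base, meta, panel$source, panel$target[1:5],
                          epochs = 4)
  expect_identical(f1$meta$params, f2$meta$params)
  expect_equal(nrow(f1$history), 4)
  expect_true(all(is.finite(f1$history$L_val)))
})

test_that("weight export covers every source instance once, deterministically", {
  panel <- tiny_panel(seed = 14)
  meta0 <- zero_meta(tiny_meta(8, ncol(panel$source$S)))
  wt <- export_weights(meta0, panel$source)
  expect_equal(nrow(wt), length(panel$source))
  expect_equal(wt$weight, rep(0.5, length(panel$source)))
  expect_identical(export_weights(meta0, panel$source),
                   export_weights(meta0, panel$source))
  expect_setequal(paste(wt$task_id, wt$compound_key),
                  paste(panel$source$task_id, panel$source$compound_key))
})
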