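#' Weighted source training loss
#'
#' The weighted binary cross-entropy used for pre-training: per-instance BCE
#' losses of the base model on the source pool, weighted by the meta-model's
#' deterministic weights and normalized by the weight sum,
#' `sum_j w_j * BCE_j / sum_j w_j`. Because of the normalization, any
#' constant weight reproduces the unweighted mean BCE.
#'
#' @param base a [base_model()].
#' @param meta a [meta_model()].
#' @param S source [instance_set].
#' @return non-negative scalar loss.
#' @export
weighted_train_loss <- function(base, meta, S) {
  if (length(S) == 0L) stop("empty source dataset", call. = FALSE)
  w <- meta_forward(meta, S$X, S$S, stochastic = FALSE)
  p <- base_forward(base, S$X)
  val <- sum(w * bce_loss(S$y, p)) / sum(w)
  if (!is.finite(val)) stop("non-finite weighted training loss", call. = FALSE)
  val
}

#' Validation loss on the target training set
#'
#' Mean (unweighted) binary cross-entropy of the base model over the target
#' training instances; the meta-objective minimized with respect to the
#' meta-model's parameters through the base model's update.
#'
#' @param base a [base_model()].
#' @param T_train target training [instance_set].
#' @return non-negative scalar loss.
#' @export
validation_loss <- function(base, T_train) {
  if (length(T_train) == 0L) stop("empty target training set", call. = FALSE)
  mean(bce_loss(T_train$y, base_forward(base, T_train$X)))
}

# accumulate sum_j w_j grad_theta l_j over mini-batches, then normalize once
# by sum(w): the epoch-end gradient is independent of the batch partition
weighted_epoch_grads <- function(base, X, y, w, batch_size = NULL) {
  gnum <- NULL
  loss_num <- 0
  for (idx in batch_indices(length(y), batch_size)) {
    ca <- base_forward_cache(base, X[idx, , drop = FALSE])
    bp <- base_backward(base, ca, ca$prob - y[idx])
    g <- base_grads(bp, w[idx])
    gnum <- if (is.null(gnum)) g else Map(`+`, gnum, g)
    loss_num <- loss_num + sum(w[idx] * bce_loss(y[idx], ca$prob))
  }
  W <- sum(w)
  list(grad = lapply(gnum, function(g) g / W), loss = loss_num / W)
}

# per-instance directional derivatives a_j = v^T grad_theta l_j(theta)
epoch_grad_dots <- function(base, X, y, v, batch_size = NULL) {
  a <- numeric(length(y))
  for (idx in batch_indices(length(y), batch_size)) {
    ca <- base_forward_cache(base, X[idx, , drop = FALSE])
    bp <- base_backward(base, ca, ca$prob - y[idx])
    a[idx] <- base_grad_dot(bp, v)
  }
  a
}

# one full meta-epoch computation (no state mutation):
# (i) accumulate the weighted source gradient, (ii) lookahead theta',
# (iii) validation loss and its theta-gradient v, (iv) exact meta-gradient.
#
# Because phi enters L_train only through the scalar weights w_j, the
# second-order term collapses exactly:
#   dL_val/dphi = -eta_theta * sum_j ((a_j - m)/W) dw_j/dphi,
# with a_j = v^T grad_theta l_j, m = sum_j w_j a_j / W, W = sum_j w_j.
meta_epoch_core <- function(base, meta, S, T_train, eta_theta,
                            batch_size = NULL) {
  wcache <- meta_forward_cache(meta, S$X, S$S, stochastic = FALSE)
  w <- wcache$w
  tr <- weighted_epoch_grads(base, S$X, S$y, w, batch_size)
  theta_prime <- params_axpy(-eta_theta, tr$grad, base$params)
  base_prime <- set_params(base, theta_prime)
  ca_val <- base_forward_cache(base_prime, T_train$X)
  n_t <- length(T_train$y)
  L_val <- mean(bce_loss(T_train$y, ca_val$prob))
  bp_val <- base_backward(base_prime, ca_val, ca_val$prob - T_train$y)
  v <- base_grads(bp_val, rep(1 / n_t, n_t))
  a <- epoch_grad_dots(base, S$X, S$y, v, batch_size)
  W <- sum(w)
  m <- sum(w * a) / W
  dval_dw <- -eta_theta * (a - m) / W
  g_phi <- meta_grads(meta, wcache, dval_dw)
  g_phi_centered <- meta_grads(meta, wcache, dval_dw, center_u = TRUE)
  list(w = w, L_train = tr$loss, grad_theta = tr$grad,
       theta_prime = theta_prime, L_val = L_val, g_phi = g_phi,
       g_phi_centered = g_phi_centered, a = a, m = m, dval_dw = dval_dw)
}

#' Exact meta-gradient of the validation loss
#'
#' Computes the analytic gradient of the one-step-lookahead validation loss
#' with respect to every meta-model parameter: the source pass is
#' accumulated, the base parameters take one plain gradient step of size
#' `eta_theta`, the validation loss is evaluated on the target training set,
#' and the chain rule is applied through the base update. The returned
#' gradient includes the `-eta_theta` factor of the lookahead and can be
#' checked coordinate-by-coordinate against central finite differences of
#' [lookahead_val_loss()].
#'
#' @param base a [base_model()] (parameters at the pre-update point).
#' @param meta a [meta_model()].
#' @param S source [instance_set].
#' @param T_train target training [instance_set].
#' @param eta_theta inner (lookahead) learning rate.
#' @param batch_size optional source mini-batch size; the result is
#'   batch-partition independent.
#' @return named list of gradient arrays matching `get_params(meta)`.
#' @export
meta_gradient <- function(base, meta, S, T_train, eta_theta,
                          batch_size = NULL) {
  meta_epoch_core(base, meta, S, T_train, eta_theta, batch_size)$g_phi
}

#' Validation loss after a one-step lookahead
#'
#' The scalar pipeline underlying the meta-gradient: weights from the
#' meta-model, one accumulated weighted gradient step on the base model,
#' validation loss of the stepped model on the target training set. Useful
#' as the function to difference when verifying [meta_gradient()].
#'
#' @inheritParams meta_gradient
#' @return scalar validation loss at the lookahead parameters.
#' @export
lookahead_val_loss <- function(base, meta, S, T_train, eta_theta,
                               batch_size = NULL) {
  w <- meta_forward(meta, S$X, S$S, stochastic = FALSE)
  tr <- weighted_epoch_grads(base, S$X, S$y, w, batch_size)
  base_prime <- set_params(base, params_axpy(-eta_theta, tr$grad, base$params))
  validation_loss(base_prime, T_train)
}

#' Initialize meta-training state
#'
#' @param base freshly initialized [base_model()].
#' @param meta freshly initialized [meta_model()].
#' @param eta_theta inner learning rate (lookahead step; also the committed
#'   base-update step / Adam learning rate).
#' @param eta_phi_comb combined meta learning rate (the product of the inner
#'   and outer rates, treated as one independent parameter).
#' @param optimizer `"sgd"` for plain gradient commits exactly matching the
#'   derivation, or `"adam"`.
#' @param phi_weight_decay decoupled L2 decay on the meta-model parameters;
#'   keeps the weight logits out of early sigmoid saturation so that only
#'   consistently re-established contrast between source instances survives.
#' @param phi_clip_norm global norm bound on the (rescaled) meta-gradient;
#'   bounds the meta-model's per-epoch movement so the persistent relevance
#'   signal integrates over epochs instead of saturating on early noise.
#' @param phi_momentum heavy-ball momentum on the clipped meta-gradient
#'   (outer SGD updates only).
#' @param batch_size optional source mini-batch size.
#' @return an object of class `meta_train_state`.
#' @export
meta_train_state <- function(base, meta, eta_theta = 0.2, eta_phi_comb = 0.3,
                             optimizer = c("sgd", "adam"),
                             phi_weight_decay = 0, phi_clip_norm = Inf,
                             phi_momentum = 0, batch_size = NULL) {
  optimizer <- match.arg(optimizer)
  structure(list(
    base = base, meta = meta, eta_theta = eta_theta,
    eta_phi_comb = eta_phi_comb, optimizer = optimizer,
    batch_size = batch_size, epoch = 0L,
    opt_theta = make_optimizer(optimizer, lr = eta_theta),
    opt_phi = make_optimizer(optimizer, lr = eta_phi_comb,
                             momentum = phi_momentum,
                             weight_decay = phi_weight_decay,
                             clip_norm = phi_clip_norm),
    history = data.frame(epoch = integer(0), L_train = numeric(0),
                         L_val = numeric(0))),
    class = "meta_train_state")
}

#' One meta-training epoch
#'
#' Performs one epoch of the bilevel procedure: accumulated weighted source
#' gradient, one-step lookahead of the base parameters, single-batch
#' validation loss on the target training set, exact second-order
#' meta-gradient, outer update of the meta-model, and commit of the base
#' update. With `eta_theta = 0` both parameter sets are provably unchanged
#' (the meta-gradient carries the factor `eta_theta`).
#'
#' @param state a [meta_train_state()].
#' @param S source [instance_set].
#' @param T_train target training [instance_set].
#' @return the updated state, with losses appended to its history.
#' @export
meta_step <- function(state, S, T_train) {
  stopifnot(inherits(state, "meta_train_state"))
  if (length(S) == 0L) stop("empty source dataset", call. = FALSE)
  eh <- meta_epoch_core(state$base, state$meta, S, T_train,
                        state$eta_theta, state$batch_size)
  if (!all(vapply(eh$g_phi, function(g) all(is.finite(g)), TRUE)) ||
      !is.finite(eh$L_val) || !is.finite(eh$L_train))
    stop(sprintf("non-finite meta-gradient or loss at epoch %d",
                 state$epoch + 1L), call. = FALSE)
  if (state$eta_theta != 0) {
    # outer update: the combined rate eta'_phi absorbs the eta_theta factor
    # of the meta-gradient, so the phi step uses g_phi / eta_theta at rate
    # eta'_phi (identical to lr eta'_phi/eta_theta on the raw gradient).
    # The update direction has the uniform logit-shift component projected
    # out (see meta_grads): the exact gradient is available as
    # meta_gradient(); the step direction removes its null-drift component.
    g_phi_scaled <- lapply(eh$g_phi_centered, function(g) g / state$eta_theta)
    st_phi <- optimizer_step(state$opt_phi, state$meta$params, g_phi_scaled)
    state$meta$params <- st_phi$params
    state$opt_phi <- st_phi$opt
    if (state$optimizer == "sgd") {
      # commit the same lookahead step that the meta-gradient differentiated
      state$base$params <- eh$theta_prime
    } else {
      st_theta <- optimizer_step(state$opt_theta, state$base$params,
                                 eh$grad_theta,
                                 frozen = frozen_param_names(state$base))
      state$base$params <- st_theta$params
      state$opt_theta <- st_theta$opt
    }
  }
  state$epoch <- state$epoch + 1L
  state$history <- rbind(state$history,
                         data.frame(epoch = state$epoch,
                                    L_train = eh$L_train, L_val = eh$L_val))
  state
}

#' Run meta-training
#'
#' Repeats [meta_step()] for a fixed number of epochs. Deterministic given
#' the initialization seeds: the procedure involves no sampling (dropout
#' stays off during meta-training; Monte Carlo weight sampling belongs to
#' the subsequent pre-training phase).
#'
#' Every `restart_every` epochs the base model is re-initialized with a
#' fresh seed. The gradient-alignment signal that drives the meta-model has
#' a frozen noise component tied to any single random base initialization
#' (its induced gradient kernel); integrating the signal across several
#' initializations removes that component, and mirrors the re-initialization
#' of the base model between meta-training and pre-training.
#'
#' @inheritParams meta_train_state
#' @param S source [instance_set].
#' @param T_train target training [instance_set].
#' @param epochs number of meta-epochs (0 returns the models unchanged).
#' @param restart_every re-initialize the base model after this many epochs
#'   (`Inf` to train one base model throughout).
#' @param seed seed stream for the base re-initializations; defaults to the
#'   base model's own initialization seed.
#' @return a list of class `meta_fit` with elements `meta`, `base`,
#'   `history` (per-epoch `L_train`, `L_val`).
#' @export
run_meta_training <- function(base, meta, S, T_train, epochs = 100L,
                              eta_theta = 0.2, eta_phi_comb = 0.3,
                              optimizer = c("sgd", "adam"),
                              phi_weight_decay = 0, phi_clip_norm = 0.004,
                              phi_momentum = 0.95, batch_size = NULL,
                              restart_every = 20L, seed = NULL) {
  optimizer <- match.arg(optimizer)
  if (is.null(seed)) seed <- base$seed
  state <- meta_train_state(base, meta, eta_theta, eta_phi_comb,
                            optimizer, phi_weight_decay,
                            phi_clip_norm, phi_momentum, batch_size)
  for (e in seq_len(epochs)) {
    if (e > 1 && is.finite(restart_every) && (e - 1) %% restart_every == 0) {
      fresh <- base_model(base$d, bottleneck = base$bottleneck,
                          hidden = base$hidden,
                          seed = derive_seed(seed, "restart", e))
      fresh$frozen <- state$base$frozen
      state$base <- fresh
      state$opt_theta <- make_optimizer(optimizer, lr = eta_theta)
    }
    state <- meta_step(state, S, T_train)
  }
  structure(list(meta = state$meta, base = state$base,
                 history = state$history), class = "meta_fit")
}

#' @export
print.meta_fit <- function(x, ...) {
  n <- nrow(x$history)
  cat(sprintf("<meta_fit> %d meta-epochs", n))
  if (n > 0)
    cat(sprintf("; L_train %.4f -> %.4f, L_val %.4f -> %.4f",
                x$history$L_train[1], x$history$L_train[n],
                x$history$L_val[1], x$history$L_val[n]))
  cat("\n")
  invisible(x)
}

#' Export per-instance source weights
#'
#' Evaluates the meta-model on every source instance. Deterministic mode
#' uses the dropout-off forward pass; stochastic mode draws one Monte Carlo
#' dropout sample (seeded).
#'
#' @param meta a trained [meta_model()].
#' @param S source [instance_set].
#' @param stochastic draw a Monte Carlo dropout sample instead of the
#'   deterministic weights.
#' @param seed RNG seed used when `stochastic = TRUE`.
#' @return data frame with `task_id`, `compound_key`, `weight`, and a
#'   `stochastic` flag; one row per source instance.
#' @export
export_weights <- function(meta, S, stochastic = FALSE, seed = 1L) {
  w <- if (stochastic) {
    with_local_seed(seed, meta_forward(meta, S$X, S$S, stochastic = TRUE))
  } else {
    meta_forward(meta, S$X, S$S, stochastic = FALSE)
  }
  data.frame(task_id = S$task_id, compound_key = S$compound_key,
             weight = w, stochastic = stochastic, stringsAsFactors = FALSE)
}
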