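LN_EPS <- 1e-5

init_weight <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = 1 / sqrt(nin)), nin, nout)
}

#' Construct the base classifier
#'
#' A feed-forward classifier over binary fingerprints. The first two layers
#' form a bottleneck (projection to `bottleneck` dimensions and back to `d`),
#' followed by a per-instance layer normalization with learned affine
#' parameters, a small head, and a single sigmoid output giving the activity
#' probability. Hidden activations are tanh. Parameters are grouped into
#' `bottleneck_down`, `bottleneck_up`, `norm` and `head` so groups can be
#' frozen during fine-tuning.
#'
#' Layer normalization (rather than batch statistics) is deliberate: it keeps
#' every forward pass a per-instance function, so accumulated gradients are
#' independent of mini-batch partitioning.
#'
#' @param d input (fingerprint) dimension.
#' @param bottleneck bottleneck width; default `d %/% 16`, floored at 16
#'   (capped below `d`): the bottleneck is the only path from the fingerprint
#'   to the head, and very narrow random projections destroy the gradient
#'   signal that meta-training relies on at small `d`.
#' @param hidden widths of the two head hidden layers.
#' @param seed seed for the fan-in-scaled Gaussian initialization. The output
#'   layer starts at zero, so an untrained model predicts exactly 0.5 for
#'   every instance (no spurious initialization bias in early gradients).
#' @return an object of class `base_model`.
#' @export
base_model <- function(d, bottleneck = max(1L, min(d - 1L, max(16L, d %/% 16L))),
                       hidden = c(256L, 64L), seed = 1L) {
  stopifnot(d >= 1L, bottleneck >= 1L, bottleneck < d, length(hidden) == 2L)
  params <- with_local_seed(seed, list(
    W_down = init_weight(d, bottleneck), b_down = numeric(bottleneck),
    W_up   = init_weight(bottleneck, d), b_up   = numeric(d),
    gamma  = rep(1, d),                  beta   = numeric(d),
    W_h1   = init_weight(d, hidden[1]),  b_h1   = numeric(hidden[1]),
    W_h2   = init_weight(hidden[1], hidden[2]), b_h2 = numeric(hidden[2]),
    W_out  = matrix(0, hidden[2], 1L), b_out  = numeric(1)
  ))
  structure(list(
    d = as.integer(d), bottleneck = as.integer(bottleneck),
    hidden = as.integer(hidden), params = params,
    groups = list(
      bottleneck_down = c("W_down", "b_down"),
      bottleneck_up   = c("W_up", "b_up"),
      norm            = c("gamma", "beta"),
      head            = c("W_h1", "b_h1", "W_h2", "b_h2", "W_out", "b_out")),
    frozen = character(0), seed = as.integer(seed)),
    class = "base_model")
}

# full forward pass; returns probabilities and (optionally) the cache needed
# for backpropagation
base_forward_cache <- function(model, X) {
  p <- model$params
  Z1 <- addb(X %*% p$W_down, p$b_down); A1 <- tanh(Z1)
  Z2 <- addb(A1 %*% p$W_up, p$b_up);   A2 <- tanh(Z2)
  mu <- rowMeans(A2)
  sdv <- sqrt(rowMeans(A2^2) - mu^2 + LN_EPS)
  Xhat <- (A2 - mu) / sdv
  A3 <- addb(Xhat * matrix(p$gamma, nrow(X), model$d, byrow = TRUE), p$beta)
  Z4 <- addb(A3 %*% p$W_h1, p$b_h1);   A4 <- tanh(Z4)
  Z5 <- addb(A4 %*% p$W_h2, p$b_h2);   A5 <- tanh(Z5)
  logit <- as.numeric(addb(A5 %*% p$W_out, p$b_out))
  list(X = X, A1 = A1, A2 = A2, sdv = sdv, Xhat = Xhat, A3 = A3,
       A4 = A4, A5 = A5, logit = logit, prob = sigmoid(logit))
}

#' Base-model forward pass
#'
#' @param model a [base_model()].
#' @param X matrix of fingerprints, one instance per row (width `d`).
#' @return vector of predicted activity probabilities in (0, 1).
#' @export
base_forward <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$d)
    stop(sprintf("input width %d does not match model dimension %d",
                 ncol(X), model$d), call. = FALSE)
  base_forward_cache(model, X)$prob
}

# backpropagate per-instance logit gradients through the base model.
# Returns per-instance pre-activation deltas; grads and gradient-vector dot
# products are then linear functionals of these (base_grads / base_grad_dot).
base_backward <- function(model, cache, dlogit) {
  p <- model$params
  n <- length(dlogit)
  Dout <- matrix(dlogit, n, 1)
  dA5 <- Dout %*% t(p$W_out); D5 <- dA5 * (1 - cache$A5^2)
  dA4 <- D5 %*% t(p$W_h2);   D4 <- dA4 * (1 - cache$A4^2)
  dA3 <- D4 %*% t(p$W_h1)
  Dgamma <- dA3 * cache$Xhat           # per-instance grads of gamma
  Dbeta <- dA3                         # per-instance grads of beta
  dXhat <- dA3 * matrix(p$gamma, n, model$d, byrow = TRUE)
  dA2 <- (dXhat - rowMeans(dXhat) -
            cache$Xhat * rowMeans(dXhat * cache$Xhat)) / cache$sdv
  D2 <- dA2 * (1 - cache$A2^2)
  dA1 <- D2 %*% t(p$W_up);   D1 <- dA1 * (1 - cache$A1^2)
  list(cache = cache, Dout = Dout, D5 = D5, D4 = D4,
       Dgamma = Dgamma, Dbeta = Dbeta, D2 = D2, D1 = D1)
}

# gradient of sum_j c_j * loss_j w.r.t. all base parameters
base_grads <- function(bp, coef) {
  ca <- bp$cache
  wmul <- function(D) D * coef
  list(
    W_down = t(ca$X) %*% wmul(bp$D1), b_down = colSums(wmul(bp$D1)),
    W_up   = t(ca$A1) %*% wmul(bp$D2), b_up  = colSums(wmul(bp$D2)),
    gamma  = colSums(wmul(bp$Dgamma)), beta  = colSums(wmul(bp$Dbeta)),
    W_h1   = t(ca$A3) %*% wmul(bp$D4), b_h1  = colSums(wmul(bp$D4)),
    W_h2   = t(ca$A4) %*% wmul(bp$D5), b_h2  = colSums(wmul(bp$D5)),
    W_out  = t(ca$A5) %*% wmul(bp$Dout), b_out = colSums(wmul(bp$Dout)))
}

# per-instance dot products a_j = v^T grad_theta loss_j for a parameter-shaped
# direction v; the workhorse of the exact second-order meta-gradient
base_grad_dot <- function(bp, v) {
  ca <- bp$cache
  as.numeric(
    rowSums((ca$X %*% v$W_down) * bp$D1) + bp$D1 %*% v$b_down +
    rowSums((ca$A1 %*% v$W_up) * bp$D2) + bp$D2 %*% v$b_up +
    bp$Dgamma %*% v$gamma + bp$Dbeta %*% v$beta +
    rowSums((ca$A3 %*% v$W_h1) * bp$D4) + bp$D4 %*% v$b_h1 +
    rowSums((ca$A4 %*% v$W_h2) * bp$D5) + bp$D5 %*% v$b_h2 +
    rowSums((ca$A5 %*% v$W_out) * bp$Dout) + bp$Dout %*% v$b_out)
}

#' Construct the meta weight-network
#'
#' A modular network mapping a (fingerprint, sequence encoding) pair to a
#' sample weight in (0, 1). The fingerprint and sequence branches process
#' their inputs independently; their latent representations are concatenated
#' and fused, and a sigmoid bounds the output. Dropout (default rate 0.2)
#' sits after every hidden layer and is only active in stochastic
#' (Monte Carlo) mode.
#'
#' @param d fingerprint dimension.
#' @param seq_dim sequence-encoding dimension (`max_len * 21`).
#' @param branch_hidden widths of the two layers of each branch.
#' @param fusion_hidden width of the fusion layer.
#' @param dropout dropout rate in `[0, 1)`; default 0.2.
#' @param dropout_placement `"fusion"` (default) applies dropout to the
#'   fusion hidden layer only; `"all"` after every hidden layer. The fusion
#'   placement keeps the Monte Carlo weight-sample variance moderate, so the
#'   per-epoch reweighting noise does not swamp the learned weight contrast
#'   on small source pools.
#' @param seed initialization seed. The output layer starts at zero, so an
#'   untrained meta-model assigns weight 0.5 to every instance; meta-training
#'   begins at the symmetric point where uniform-shift gradients vanish and
#'   the first updates learn pure between-instance contrast.
#' @return an object of class `meta_model`.
#' @export
meta_model <- function(d, seq_dim, branch_hidden = c(128L, 32L),
                       fusion_hidden = 64L, dropout = 0.2,
                       dropout_placement = c("fusion", "all"), seed = 1L) {
  dropout_placement <- match.arg(dropout_placement)
  stopifnot(d >= 1L, seq_dim >= 1L, length(branch_hidden) == 2L,
            fusion_hidden >= 1L, dropout >= 0, dropout < 1)
  h1 <- branch_hidden[1]; h2 <- branch_hidden[2]
  params <- with_local_seed(seed, list(
    Wf1 = init_weight(d, h1),       bf1 = numeric(h1),
    Wf2 = init_weight(h1, h2),      bf2 = numeric(h2),
    Ws1 = init_weight(seq_dim, h1), bs1 = numeric(h1),
    Ws2 = init_weight(h1, h2),      bs2 = numeric(h2),
    Wc1 = init_weight(2L * h2, fusion_hidden), bc1 = numeric(fusion_hidden),
    Wc2 = matrix(0, fusion_hidden, 1L),        bc2 = numeric(1)
  ))
  structure(list(d = as.integer(d), seq_dim = as.integer(seq_dim),
                 branch_hidden = as.integer(branch_hidden),
                 fusion_hidden = as.integer(fusion_hidden),
                 dropout = dropout, dropout_placement = dropout_placement,
                 params = params, seed = as.integer(seed)),
            class = "meta_model")
}

drop_mask <- function(n, m, rate) {
  matrix(stats::rbinom(n * m, 1L, 1 - rate) / (1 - rate), n, m)
}

meta_forward_cache <- function(model, X, S, stochastic = FALSE) {
  p <- model$params
  n <- nrow(X)
  all_layers <- identical(model$dropout_placement, "all")
  msk <- function(m, fusion = FALSE) {
    on <- stochastic && model$dropout > 0 && (fusion || all_layers)
    if (on) drop_mask(n, m, model$dropout) else 1
  }
  Af1 <- tanh(addb(X %*% p$Wf1, p$bf1)) * msk(ncol(p$Wf1))
  Af2 <- tanh(addb(Af1 %*% p$Wf2, p$bf2)) * msk(ncol(p$Wf2))
  As1 <- tanh(addb(S %*% p$Ws1, p$bs1)) * msk(ncol(p$Ws1))
  As2 <- tanh(addb(As1 %*% p$Ws2, p$bs2)) * msk(ncol(p$Ws2))
  H <- cbind(Af2, As2)
  Ac1 <- tanh(addb(H %*% p$Wc1, p$bc1)) * msk(ncol(p$Wc1), fusion = TRUE)
  u <- as.numeric(addb(Ac1 %*% p$Wc2, p$bc2))
  w <- clamp_prob(sigmoid(u), 1e-12)
  list(X = X, S = S, Af1 = Af1, Af2 = Af2, As1 = As1, As2 = As2,
       H = H, Ac1 = Ac1, u = u, w = w)
}

#' Meta-model forward pass: sample weights for compound-target pairs
#'
#' @param model a [meta_model()].
#' @param X fingerprints (matrix, width `d`).
#' @param S sequence encodings (matrix, width `seq_dim`).
#' @param stochastic keep dropout active (Monte Carlo sampling). With
#'   `stochastic = FALSE` the pass is deterministic.
#' @return vector of weights strictly inside (0, 1).
#' @export
meta_forward <- function(model, X, S, stochastic = FALSE) {
  X <- as.matrix(X); S <- as.matrix(S)
  if (ncol(X) != model$d || ncol(S) != model$seq_dim)
    stop(sprintf("input widths (%d, %d) do not match meta-model dims (%d, %d)",
                 ncol(X), ncol(S), model$d, model$seq_dim), call. = FALSE)
  if (nrow(X) != nrow(S))
    stop("fingerprint and sequence batches differ in length", call. = FALSE)
  meta_forward_cache(model, X, S, stochastic)$w
}

# gradient of sum_j dout_j * w_j w.r.t. phi (deterministic forward only).
# center_u projects the uniform component out of the logit-space gradient:
# the normalized training loss is invariant to rescaling all weights, so the
# all-logits-shift direction is a near-null direction whose accumulated
# drift only saturates the sigmoid; removing it leaves pure between-instance
# contrast.
meta_grads <- function(model, cache, dout, center_u = FALSE) {
  p <- model$params
  n <- length(dout)
  Du <- matrix(dout * cache$w * (1 - cache$w), n, 1)  # sigmoid'
  if (center_u) Du <- Du - mean(Du)
  dAc1 <- Du %*% t(p$Wc2); Dc1 <- dAc1 * (1 - cache$Ac1^2)
  dH <- Dc1 %*% t(p$Wc1)
  h2 <- model$branch_hidden[2]
  dAf2 <- dH[, seq_len(h2), drop = FALSE]
  dAs2 <- dH[, h2 + seq_len(h2), drop = FALSE]
  Df2 <- dAf2 * (1 - cache$Af2^2)
  dAf1 <- Df2 %*% t(p$Wf2); Df1 <- dAf1 * (1 - cache$Af1^2)
  Ds2 <- dAs2 * (1 - cache$As2^2)
  dAs1 <- Ds2 %*% t(p$Ws2); Ds1 <- dAs1 * (1 - cache$As1^2)
  list(
    Wf1 = t(cache$X) %*% Df1,   bf1 = colSums(Df1),
    Wf2 = t(cache$Af1) %*% Df2, bf2 = colSums(Df2),
    Ws1 = t(cache$S) %*% Ds1,   bs1 = colSums(Ds1),
    Ws2 = t(cache$As1) %*% Ds2, bs2 = colSums(Ds2),
    Wc1 = t(cache$H) %*% Dc1,   bc1 = colSums(Dc1),
    Wc2 = t(cache$Ac1) %*% Du,  bc2 = colSums(Du))
}

#' Freeze parameter groups of the base model
#'
#' Frozen groups receive exactly zero update under any subsequent optimizer
#' step (they are skipped entirely, not merely given zero gradients).
#' Calling with `groups = character(0)` unfreezes everything.
#'
#' @param model a [base_model()].
#' @param groups character vector of group names among
#'   `bottleneck_down`, `bottleneck_up`, `norm`, `head`.
#' @return the model with its frozen set replaced.
#' @export
freeze <- function(model, groups) {
  stopifnot(inherits(model, "base_model"))
  bad <- setdiff(groups, names(model$groups))
  if (length(bad) > 0L)
    stop(sprintf("unknown layer group(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  model$frozen <- unique(groups)
  model
}

# parameter names currently frozen
frozen_param_names <- function(model) {
  if (is.null(model$frozen) || length(model$frozen) == 0L) return(character(0))
  unlist(model$groups[model$frozen], use.names = FALSE)
}

#' Get / set model parameters
#'
#' Access the full parameter list of a base or meta model, e.g. to zero a
#' layer, perturb single coordinates for finite-difference checks, or
#' serialize a checkpoint.
#'
#' @param model a [base_model()] or [meta_model()].
#' @return `get_params`: the named list of parameter arrays.
#' @export
get_params <- function(model) model$params

#' @rdname get_params
#' @param value named list matching the model's parameter shapes.
#' @export
set_params <- function(model, value) {
  stopifnot(identical(names(model$params), names(value)))
  model$params <- value
  model
}

# elementwise linear combination over parameter lists
params_axpy <- function(a, x, y) {
  stats::setNames(lapply(names(y), function(nm) a * x[[nm]] + y[[nm]]), names(y))
}

params_zero_like <- function(x) lapply(x, function(p) p * 0)

flatten_params <- function(params) unlist(params, use.names = FALSE)

unflatten_params <- function(vec, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    k <- length(template[[nm]])
    out[[nm]][] <- vec[pos + seq_len(k)]
    pos <- pos + k
  }
  out
}

#' Save / load a model checkpoint
#'
#' Checkpoints store the architecture configuration, the parameters and the
#' initialization seed in a single RDS container.
#'
#' @param model a base or meta model.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) saveRDS(model, path)

#' @rdname save_checkpoint
#' @return `load_checkpoint`: the restored model.
#' @export
load_checkpoint <- function(path) readRDS(path)
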