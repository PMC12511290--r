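#' Create an optimizer
#'
#' Plain gradient descent (`"sgd"`) or Adam. The bilevel derivation assumes
#' plain gradient steps for the lookahead; Adam is available for the realized
#' (committed) updates, matching common training practice.
#'
#' @param kind `"sgd"` or `"adam"`.
#' @param lr learning rate.
#' @param momentum heavy-ball momentum for `"sgd"` (0 = plain gradient
#'   descent). Averages the per-epoch gradient signal so persistent
#'   directions compound while epoch-to-epoch noise cancels.
#' @param beta1,beta2,eps Adam moment decays and stabilizer.
#' @param weight_decay decoupled L2 decay rate (parameters shrink by
#'   `lr * weight_decay` per step before the gradient update); 0 disables.
#' @param clip_norm global gradient-norm clip: gradients are rescaled so
#'   their overall Euclidean norm does not exceed this value (`Inf`
#'   disables). Bounds the per-epoch parameter movement, the standard
#'   stabilizer for noisy meta-gradients.
#' @return an optimizer state object.
#' @export
make_optimizer <- function(kind = c("sgd", "adam"), lr, momentum = 0,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                           weight_decay = 0, clip_norm = Inf) {
  kind <- match.arg(kind)
  structure(list(kind = kind, lr = lr, momentum = momentum,
                 beta1 = beta1, beta2 = beta2,
                 eps = eps, weight_decay = weight_decay,
                 clip_norm = clip_norm, t = 0L, m = NULL, v = NULL),
            class = "mt_optimizer")
}

# one optimizer step; frozen parameter names are skipped entirely so frozen
# groups see exactly zero update (including Adam momentum carry-over)
optimizer_step <- function(opt, params, grads, frozen = character(0)) {
  live <- setdiff(names(params), frozen)
  if (is.finite(opt$clip_norm)) {
    gn <- sqrt(sum(vapply(grads[live], function(g) sum(g^2), 0)))
    if (gn > opt$clip_norm)
      grads[live] <- lapply(grads[live], function(g) g * (opt$clip_norm / gn))
  }
  if (opt$weight_decay > 0)
    for (nm in live)
      params[[nm]] <- params[[nm]] * (1 - opt$lr * opt$weight_decay)
  if (opt$kind == "sgd") {
    if (opt$momentum > 0) {
      if (is.null(opt$m)) opt$m <- params_zero_like(params)
      for (nm in live) {
        opt$m[[nm]] <- opt$momentum * opt$m[[nm]] + grads[[nm]]
        params[[nm]] <- params[[nm]] - opt$lr * opt$m[[nm]]
      }
    } else {
      for (nm in live) params[[nm]] <- params[[nm]] - opt$lr * grads[[nm]]
    }
    return(list(params = params, opt = opt))
  }
  if (is.null(opt$m)) {
    opt$m <- params_zero_like(params)
    opt$v <- params_zero_like(params)
  }
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (nm in live) {
    g <- grads[[nm]]
    opt$m[[nm]] <- opt$beta1 * opt$m[[nm]] + (1 - opt$beta1) * g
    opt$v[[nm]] <- opt$beta2 * opt$v[[nm]] + (1 - opt$beta2) * g^2
    params[[nm]] <- params[[nm]] -
      opt$lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + opt$eps)
  }
  list(params = params, opt = opt)
}

# split 1..n into contiguous batches of size <= batch_size (NULL = one batch)
batch_indices <- function(n, batch_size = NULL) {
  if (is.null(batch_size) || batch_size >= n) return(list(seq_len(n)))
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}
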