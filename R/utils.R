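#' Logistic sigmoid
#' @param x numeric vector or matrix.
#' @return values in (0, 1).
#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

# clamp probabilities away from 0/1 so log() stays finite
clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Binary cross-entropy per instance
#'
#' Standard negative binary cross-entropy, `-(y log p + (1-y) log(1-p))`,
#' with probabilities clamped to `[1e-7, 1 - 1e-7]` for numerical safety.
#'
#' @param y binary labels (0/1).
#' @param p predicted probabilities.
#' @return non-negative per-instance losses.
#' @export
bce_loss <- function(y, p) {
  p <- clamp_prob(p)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Derive a child seed from a parent seed and a key path
#'
#' Counter-/key-based seed fan-out: a parent seed plus any number of string or
#' integer keys deterministically yields a 31-bit child seed. Used so that
#' stages and trials get independent, reproducible RNG streams.
#'
#' @param seed integer parent seed.
#' @param ... keys (coerced to character) identifying the consumer.
#' @return an integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# evaluate expr with a local RNG state; the caller's stream is untouched
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# add a row-constant bias vector to a matrix
addb <- function(Z, b) Z + matrix(b, nrow(Z), length(b), byrow = TRUE)

# stop with a configuration error naming the offending field
config_stop <- function(field, msg) {
  stop(sprintf("invalid configuration: field `%s` %s", field, msg), call. = FALSE)
}
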