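#' Configuration for a synthetic multi-task panel
#'
#' Describes a chemogenomic-style panel: one target task plus source tasks
#' whose latent concepts are dialled to be related (cosine >= 0.8 to the
#' target concept), irrelevant (|cosine| <= 0.2) or adversarial
#' (cosine <= -0.8, i.e. systematically conflicting structure-activity
#' relationships). Instances are sparse binary "fingerprints"; labels come
#' from thresholding the latent score at the per-task median, then flipping
#' with probability `label_noise`.
#'
#' @param d fingerprint length.
#' @param bit_density Bernoulli rate of each fingerprint bit, in (0,1).
#' @param n_per_task instances per task (target included).
#' @param n_related,n_irrelevant,n_adversarial source task counts by relation.
#' @param label_noise label flip probability in `[0, 0.5)`.
#' @param concept_jitter sd of the Gaussian perturbation applied to related /
#'   adversarial concepts before re-normalization.
#' @param seq_len length of the synthetic per-task "protein sequences".
#' @param seed integer seed; generation is a pure function of it.
#' @return an object of class `synthetic_panel_config`.
#' @export
synthetic_panel_config <- function(d = 64L, bit_density = 0.25,
                                   n_per_task = 100L, n_related = 3L,
                                   n_irrelevant = 0L, n_adversarial = 3L,
                                   label_noise = 0.1, concept_jitter = 0.25,
                                   seq_len = 60L, seed = 1L) {
  cfg <- list(d = as.integer(d), bit_density = bit_density,
              n_per_task = as.integer(n_per_task),
              n_related = as.integer(n_related),
              n_irrelevant = as.integer(n_irrelevant),
              n_adversarial = as.integer(n_adversarial),
              label_noise = label_noise, concept_jitter = concept_jitter,
              seq_len = as.integer(seq_len), seed = as.integer(seed))
  if (cfg$d < 1L) config_stop("d", "must be a positive integer")
  if (cfg$bit_density <= 0 || cfg$bit_density >= 1)
    config_stop("bit_density", "must lie in (0, 1)")
  if (cfg$n_per_task < 4L) config_stop("n_per_task", "must be at least 4")
  for (f in c("n_related", "n_irrelevant", "n_adversarial"))
    if (cfg[[f]] < 0L) config_stop(f, "must be non-negative")
  if (cfg$n_related + cfg$n_irrelevant + cfg$n_adversarial < 1L)
    config_stop("n_related", "no source tasks: n_related + n_irrelevant + n_adversarial must be >= 1")
  if (cfg$label_noise < 0 || cfg$label_noise >= 0.5)
    config_stop("label_noise", "must lie in [0, 0.5)")
  if (cfg$concept_jitter < 0) config_stop("concept_jitter", "must be >= 0")
  if (cfg$seq_len < 1L) config_stop("seq_len", "must be positive")
  structure(cfg, class = "synthetic_panel_config")
}

# draw a unit-norm concept near `anchor` (or random if NULL) satisfying a
# cosine constraint against `target`; rejection-sampled, capped attempts.
# `jitter` is the Euclidean norm of the perturbation added to the unit-norm
# anchor (a random direction scaled to length `jitter`), so the expected
# cosine ~ 1/sqrt(1 + jitter^2) is dimension-independent.
draw_concept <- function(target, anchor, jitter, accept, what, max_attempts = 1000L) {
  d <- length(target)
  for (i in seq_len(max_attempts)) {
    b <- if (is.null(anchor)) {
      stats::rnorm(d)
    } else {
      u <- stats::rnorm(d)
      anchor + jitter * u / sqrt(sum(u^2))
    }
    b <- b / sqrt(sum(b^2))
    if (accept(sum(b * target))) return(b)
  }
  stop(sprintf("could not sample a %s concept satisfying its cosine constraint after %d attempts; reduce concept_jitter",
               what, max_attempts), call. = FALSE)
}

random_sequence <- function(len) {
  paste(sample(AA_ALPHABET[1:20], len, replace = TRUE), collapse = "")
}

# mutate exactly floor(frac * len) positions to a different residue,
# guaranteeing >= (1 - frac) sequence identity with the input
mutated_sequence <- function(seq, frac = 0.2) {
  chars <- strsplit(seq, "")[[1]]
  k <- floor(frac * length(chars))
  if (k > 0) {
    pos <- sample(length(chars), k)
    chars[pos] <- vapply(chars[pos], function(a)
      sample(setdiff(AA_ALPHABET[1:20], a), 1), "")
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic multi-task panel
#'
#' Builds the target task and its source tasks from latent per-task concepts
#' (unit vectors `beta`). Fingerprint bits are iid Bernoulli(`bit_density`);
#' an instance is active iff its latent score `x . beta` exceeds the task
#' median score (so classes are balanced to within one instance before
#' noise), then labels flip independently with probability `label_noise`.
#' Related concepts are jittered copies of the target concept, adversarial
#' concepts jittered negations; related tasks share at least 70 percent of
#' sequence positions with the target, other tasks get independent random
#' sequences.
#'
#' @param cfg a [synthetic_panel_config()].
#' @return an object of class `synthetic_panel`: a list with `source` (an
#'   [instance_set] over all source tasks), `target` (an [instance_set] of
#'   the full target task; split it with [stratified_split()]), `concepts`
#'   (per-task metadata incl. latent vectors and relations), and `config`.
#' @export
make_panel <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_panel_config"))
  with_local_seed(cfg$seed, {
    beta_t <- stats::rnorm(cfg$d)
    beta_t <- beta_t / sqrt(sum(beta_t^2))
    seq_t <- random_sequence(cfg$seq_len)

    relations <- c("target",
                   rep("related", cfg$n_related),
                   rep("irrelevant", cfg$n_irrelevant),
                   rep("adversarial", cfg$n_adversarial))
    task_ids <- c("target",
                  unlist(lapply(c("related", "irrelevant", "adversarial"),
                                function(r) {
                                  k <- sum(relations == r)
                                  if (k > 0) sprintf("%s_%d", r, seq_len(k))
                                })))

    concepts <- lapply(seq_along(relations), function(i) {
      rel <- relations[i]
      beta <- switch(rel,
        target = beta_t,
        related = draw_concept(beta_t, beta_t, cfg$concept_jitter,
                               function(cs) cs >= 0.8, "related"),
        adversarial = draw_concept(beta_t, -beta_t, cfg$concept_jitter,
                                   function(cs) cs <= -0.8, "adversarial"),
        irrelevant = draw_concept(beta_t, NULL, 0,
                                  function(cs) abs(cs) <= 0.2, "irrelevant"))
      sequence <- switch(rel,
        target = seq_t,
        related = mutated_sequence(seq_t, frac = 0.2),
        random_sequence(cfg$seq_len))
      list(task_id = task_ids[i], beta = beta, relation = rel,
           sequence = sequence, cosine = sum(beta * beta_t))
    })
    names(concepts) <- task_ids

    sets <- lapply(concepts, function(cc) {
      n <- cfg$n_per_task
      X <- matrix(stats::rbinom(n * cfg$d, 1L, cfg$bit_density), n, cfg$d)
      score <- as.numeric(X %*% cc$beta)
      y <- if (cc$relation == "adversarial") {
        # sign-folded labels: extreme latent scores in either direction are
        # active, mid-range inactive. A monotone inversion of the target
        # ranking would be repaired by flipping the classifier's output
        # sign, so it cannot cause genuine negative transfer; folded labels
        # are non-monotone in the target score (the analogue of activity
        # cliffs) and actively poison the sign readout.
        dev <- abs(score - stats::median(score))
        as.numeric(dev > stats::median(dev))
      } else {
        as.numeric(score > stats::median(score))
      }
      if (cfg$label_noise > 0) {
        flip <- stats::runif(n) < cfg$label_noise
        y[flip] <- 1 - y[flip]
      }
      s_enc <- encode_sequence(cc$sequence, max_len = cfg$seq_len)
      instance_set(X, y, rep(cc$task_id, n),
                   sprintf("cmpd_%s_%04d", cc$task_id, seq_len(n)),
                   matrix(s_enc, n, length(s_enc), byrow = TRUE))
    })

    structure(list(
      source = bind_instances(sets[names(sets) != "target"]),
      target = sets[["target"]],
      concepts = concepts,
      config = cfg), class = "synthetic_panel")
  })
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat(sprintf("<synthetic_panel> d = %d, %d source instances (%d tasks), %d target instances\n",
              x$config$d, length(x$source),
              length(unique(x$source$task_id)), length(x$target)))
  print(relatedness_report(x$concepts))
  invisible(x)
}

#' Tabulate source-task relatedness to the target
#'
#' @param concepts the per-task concept list of a [make_panel()] result.
#' @return data frame with `task_id`, `cosine` (to the target concept) and
#'   `relation`, one row per source task (empty if there are none).
#' @export
relatedness_report <- function(concepts) {
  rel <- vapply(concepts, `[[`, "", "relation")
  if (!any(rel == "target"))
    stop("no target concept present", call. = FALSE)
  beta_t <- concepts[[which(rel == "target")[1]]]$beta
  src <- concepts[rel != "target"]
  data.frame(
    task_id = vapply(src, `[[`, "", "task_id"),
    cosine = vapply(src, function(cc) sum(cc$beta * beta_t), 0),
    relation = vapply(src, `[[`, "", "relation"),
    row.names = NULL, stringsAsFactors = FALSE)
}
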