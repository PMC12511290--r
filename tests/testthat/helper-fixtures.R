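# small fixtures shared across test files; everything is generated in code

tiny_panel <- function(seed = 11, d = 8L, n = 10L, seq_len = 3L,
                       noise = 0) {
  make_panel(synthetic_panel_config(
    d = d, n_per_task = n, n_related = 1L, n_adversarial = 1L,
    label_noise = noise, seq_len = seq_len, seed = seed))
}

tiny_base <- function(d = 8L, seed = 4) {
  base_model(d, bottleneck = 2L, hidden = c(8L, 4L), seed = seed)
}

tiny_meta <- function(d = 8L, seq_dim, seed = 5) {
  meta_model(d, seq_dim, branch_hidden = c(6L, 4L), fusion_hidden = 5L,
             seed = seed)
}

# a meta-model with every parameter zero: outputs exactly 0.5 everywhere
zero_meta <- function(meta) {
  set_params(meta, lapply(get_params(meta), function(p) p * 0))
}

# brute-force pairwise AUC oracle (independent of the rank implementation)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# brute-force exact two-sided signed-rank p-value: enumerate all 2^n sign
# assignments over the observed mid-ranks
wilcoxon_bruteforce <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  lower <- mean(w_all <= w_obs + 1e-9)
  upper <- mean(w_all >= w_obs - 1e-9)
  min(1, 2 * min(lower, upper))
}

# toy curated instance table: tasks A (target) and B with one shared compound
toy_records <- function() {
  featurize <- hashed_featurizer(d = 16L, n_bits = 4L)
  compounds <- c("c1", "c2", "c3", "c2")
  tasks <- c("B", "B", "B", "A")
  X <- t(vapply(compounds, featurize, numeric(16)))
  S <- do.call(rbind, lapply(tasks, function(t)
    encode_sequence(if (t == "A") "ACD" else "WYK", max_len = 3)))
  instance_set(X, c(1, 0, 1, 1), tasks, compounds, S)
}
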