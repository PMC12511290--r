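#' ROC-AUC by the rank (Mann-Whitney) formula
#'
#' Equals the probability that a random positive scores above a random
#' negative, with ties counted half:
#' `AUC = (sum of positive ranks - n1 (n1 + 1) / 2) / (n1 n0)`.
#' Exact tie handling, invariant under strictly monotone score transforms.
#'
#' @param scores numeric score vector (higher = more likely active).
#' @param labels binary labels (0/1), both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  r <- rank(scores)  # ties averaged
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# exact null distribution of the signed-rank statistic W+ for given
# (possibly mid-) ranks: convolution over independent sign flips on a grid
# of doubled ranks (mid-ranks are half-integers)
signed_rank_null <- function(ranks2) {
  probs <- 1
  for (r in ranks2) {
    padded <- c(probs, rep(0, r))
    shifted <- c(rep(0, r), probs)
    probs <- (padded + shifted) / 2
  }
  probs  # probs[i] = P(2*W+ = i - 1)
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (Wilcoxon's original rule); ties among the
#' absolute differences receive mid-ranks. The null distribution is exact
#' (full sign-flip enumeration via convolution) for up to 25 non-zero
#' differences and a normal approximation with continuity and tie correction
#' above. The all-zero case is reported as p = 1 rather than an error, so
#' pipelines comparing identical models do not crash.
#'
#' @param d numeric vector of paired differences.
#' @return list with `statistic` (W+, sum of positive ranks), `p_value`
#'   (two-sided), and `n_used` (non-zero differences).
#' @export
wilcoxon_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(list(statistic = NA_real_, p_value = 1, n_used = 0L))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25L) {
    ranks2 <- as.integer(round(2 * r))
    probs <- signed_rank_null(ranks2)
    w2 <- as.integer(round(2 * w))
    lower <- sum(probs[seq_len(w2 + 1L)])          # P(W+ <= w)
    upper <- sum(probs[(w2 + 1L):length(probs)])   # P(W+ >= w)
    p <- min(1, 2 * min(lower, upper))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = w, p_value = p, n_used = n)
}

#' Significance stars for a p-value
#'
#' Bands: `ns` for p > 0.05, `*` for 0.01 < p <= 0.05, `**` for
#' 0.001 < p <= 0.01, `***` for p <= 0.001.
#'
#' @param p p-value.
#' @return character scalar.
#' @export
significance_stars <- function(p) {
  if (p <= 0.001) "***" else if (p <= 0.01) "**" else if (p <= 0.05) "*" else "ns"
}

#' Trial-by-trial paired comparison of two methods
#'
#' Computes per-trial AUC differences `a - b` and tests them with the
#' two-sided Wilcoxon signed-rank test ([wilcoxon_signed_rank()]).
#'
#' @param a,b paired per-trial AUC vectors of equal length (>= 5).
#' @param name_a,name_b method labels for printing.
#' @return an object of class `comparison_report`: `dauc`, `statistic`,
#'   `p_value`, `stars`, `median_dauc`.
#' @export
paired_comparison <- function(a, b, name_a = "a", name_b = "b") {
  if (length(a) != length(b))
    stop("paired AUC vectors differ in length", call. = FALSE)
  if (length(a) < 5L)
    stop("need at least 5 paired trials", call. = FALSE)
  dauc <- a - b
  ts <- wilcoxon_signed_rank(dauc)
  structure(list(name_a = name_a, name_b = name_b, dauc = dauc,
                 statistic = ts$statistic, p_value = ts$p_value,
                 stars = significance_stars(ts$p_value),
                 median_dauc = stats::median(dauc), n_used = ts$n_used),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %s vs %s: median dAUC %+0.4f, W+ = %s, p = %.4g (%s)\n",
              x$name_a, x$name_b, x$median_dauc,
              format(x$statistic), x$p_value, x$stars))
  invisible(x)
}

#' Negative transfer index
#'
#' Mean AUC of a reference model trained only on the target domain minus the
#' mean AUC of a transfer model over matched trials. Positive values indicate
#' negative transfer (pre-training hurt the target task).
#'
#' @param auc_reference per-trial AUCs of the target-only reference model.
#' @param auc_transfer per-trial AUCs of the transfer model.
#' @return scalar NTI; antisymmetric in its arguments.
#' @export
nti <- function(auc_reference, auc_transfer) {
  if (length(auc_reference) != length(auc_transfer))
    stop("AUC vectors differ in length", call. = FALSE)
  mean(auc_reference) - mean(auc_transfer)
}

#' Box plot of per-trial AUC distributions
#'
#' @param trials data frame with `method` and `auc` columns (rows from
#'   [run_trials()]).
#' @return a ggplot object.
#' @export
plot_auc_boxplot <- function(trials) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ggplot2::ggplot(trials, ggplot2::aes(x = method, y = auc)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "AUC") +
    ggplot2::theme_bw()
}

#' Box plot of per-trial AUC differences
#'
#' @param comparison a [paired_comparison()] result.
#' @return a ggplot object.
#' @export
plot_dauc_boxplot <- function(comparison) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- data.frame(pair = sprintf("%s - %s", comparison$name_a,
                                  comparison$name_b),
                   dauc = comparison$dauc)
  ggplot2::ggplot(df, ggplot2::aes(x = pair, y = dauc)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "dAUC",
                  subtitle = sprintf("p = %.3g (%s)", comparison$p_value,
                                     comparison$stars)) +
    ggplot2::theme_bw()
}
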