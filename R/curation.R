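AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Aggregate repeated Ki measurements for one compound-target pair
#'
#' Multiple Ki values for the same compound and target are condensed to their
#' geometric mean, provided the measurements are mutually consistent: the
#' ratio of the largest to the smallest value must not exceed 10. Inconsistent
#' measurement sets are discarded (returned as `NA_real_`).
#'
#' @param values numeric vector of positive Ki values (nM).
#' @param max_ratio largest tolerated `max(values)/min(values)`; default 10.
#' @return the geometric mean (nM), or `NA_real_` if the set is discarded.
#' @examples
#' aggregate_ki(c(100, 400))  # 200
#' aggregate_ki(c(50, 600))   # NA: ratio 12 > 10
#' @export
aggregate_ki <- function(values, max_ratio = 10) {
  if (length(values) == 0L) stop("empty Ki value set", call. = FALSE)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("Ki values must be positive and finite", call. = FALSE)
  if (max(values) / min(values) > max_ratio) return(NA_real_)
  exp(mean(log(values)))
}

#' Binarize a Ki value into an activity label
#'
#' Compounds with Ki strictly below the potency threshold are labeled active
#' (1); a Ki at or above the threshold is inactive (0). The 1000 nM default
#' reflects the practical medicinal-chemistry convention that micromolar
#' inhibitors are not development candidates.
#'
#' @param ki_nM positive Ki (nM); vectorized.
#' @param threshold_nM potency threshold (nM), default 1000.
#' @return integer 0/1 labels.
#' @export
binarize <- function(ki_nM, threshold_nM = 1000) {
  if (any(!is.finite(ki_nM)) || any(ki_nM <= 0) || threshold_nM <= 0)
    stop("Ki and threshold must be positive", call. = FALSE)
  as.integer(ki_nM < threshold_nM)
}

#' One-hot encode a protein sequence
#'
#' Flattened one-hot matrix over the 20 amino acids plus `X` (unknown), 21
#' channels per position, row-major by position. Sequences longer than
#' `max_len` are tail-truncated; shorter ones are right-padded with zeros, so
#' the output length is constant (`max_len * 21`) across a dataset.
#'
#' @param sequence character scalar over `ACDEFGHIKLMNPQRSTVWYX`.
#' @param max_len maximum number of positions encoded; default 512.
#' @return numeric vector of length `max_len * 21`.
#' @export
encode_sequence <- function(sequence, max_len = 512L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, max_len >= 1L)
  out <- numeric(max_len * 21L)
  if (nchar(sequence) == 0L) return(out)
  chars <- strsplit(sequence, "")[[1]]
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx)) {
    pos <- which(is.na(idx))[1]
    stop(sprintf("illegal sequence character '%s' at position %d",
                 chars[pos], pos), call. = FALSE)
  }
  keep <- seq_len(min(length(chars), max_len))
  out[(keep - 1L) * 21L + idx[keep]] <- 1
  out
}

#' Assemble the leave-one-target-out source dataset
#'
#' Builds the multi-task source pool for a given target: all instances of all
#' tasks except the target. With `remove_overlap = TRUE` the compound spaces
#' are additionally made disjoint: any source instance whose compound also
#' occurs in the target task is dropped, so no structure is seen in both
#' domains.
#'
#' @param records an [instance_set] spanning all tasks (target included).
#' @param target_id the task to hold out.
#' @param remove_overlap drop source instances whose compound key occurs in
#'   the target task.
#' @return an [instance_set] containing no target-task instances.
#' @export
assemble_source <- function(records, target_id, remove_overlap = FALSE) {
  stopifnot(inherits(records, "instance_set"))
  if (!target_id %in% records$task_id)
    stop(sprintf("unknown target task '%s'", target_id), call. = FALSE)
  is_target <- records$task_id == target_id
  keep <- !is_target
  if (remove_overlap) {
    target_compounds <- unique(records$compound_key[is_target])
    keep <- keep & !(records$compound_key %in% target_compounds)
  }
  if (!any(keep)) stop("source dataset is empty after filtering", call. = FALSE)
  records[keep]
}

#' Stratified low-data train/test split of a single task
#'
#' Draws a training set of exactly `n_train` instances whose class proportions
#' match the full task (largest-remainder rounding, so per-class counts differ
#' from exact proportionality by at most one and sum exactly to `n_train`).
#' The remaining instances form the test set. A pure function of `seed`.
#'
#' @param task_instances an [instance_set] of a single task with both classes
#'   present.
#' @param n_train training-set size (must be smaller than the task).
#' @param seed integer seed controlling the draw.
#' @return a [target_split].
#' @export
stratified_split <- function(task_instances, n_train, seed) {
  stopifnot(inherits(task_instances, "instance_set"))
  n <- length(task_instances)
  if (length(unique(task_instances$task_id)) != 1L)
    stop("stratified_split expects a single task", call. = FALSE)
  if (n_train >= n)
    stop("n_train must be smaller than the task size", call. = FALSE)
  y <- task_instances$y
  classes <- sort(unique(y))
  if (length(classes) < 2L)
    stop("both classes must be present for a stratified split", call. = FALSE)
  # largest-remainder apportionment of n_train across classes
  exact <- n_train * vapply(classes, function(cl) mean(y == cl), 0)
  base <- floor(exact)
  rem <- n_train - sum(base)
  if (rem > 0) {
    order_frac <- order(exact - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1L
  }
  counts <- stats::setNames(as.integer(base), classes)
  idx_train <- with_local_seed(seed, {
    unlist(lapply(seq_along(classes), function(k) {
      pool <- which(y == classes[k])
      if (counts[k] > length(pool))
        stop("class too small for requested stratified count", call. = FALSE)
      sample(pool, counts[k])
    }))
  })
  idx_train <- sort(idx_train)
  target_split(task_instances[idx_train],
               task_instances[setdiff(seq_len(n), idx_train)])
}

#' Curate a raw bioactivity table into labeled records
#'
#' Applies the package's curation rules to a long-format activity table with
#' one row per measurement: optional molecular-mass filter (< 1000 Da when a
#' `mass_da` column is present), per (compound, target) geometric-mean Ki
#' aggregation with the max/min <= 10 consistency rule (inconsistent sets
#' discarded), and potency thresholding into binary labels.
#'
#' @param activities data frame with columns `compound_key`, `target_id`,
#'   `ki_nM` and optionally `mass_da`.
#' @param threshold_nM potency threshold for [binarize()].
#' @param max_ratio consistency bound for [aggregate_ki()].
#' @return data frame with columns `compound_key`, `target_id`, `ki_nM`
#'   (aggregated) and `y`; discarded measurements are absent.
#' @export
curate_activities <- function(activities, threshold_nM = 1000, max_ratio = 10) {
  req <- c("compound_key", "target_id", "ki_nM")
  if (!all(req %in% names(activities)))
    stop("activity table needs columns compound_key, target_id, ki_nM",
         call. = FALSE)
  if ("mass_da" %in% names(activities))
    activities <- activities[is.na(activities$mass_da) |
                               activities$mass_da < 1000, , drop = FALSE]
  if (nrow(activities) == 0L) stop("no activity records after filtering", call. = FALSE)
  key <- interaction(activities$compound_key, activities$target_id, drop = TRUE)
  agg <- vapply(split(activities$ki_nM, key), aggregate_ki, 0,
                max_ratio = max_ratio)
  first <- !duplicated(key)
  out <- data.frame(compound_key = activities$compound_key[first],
                    target_id = activities$target_id[first],
                    ki_nM = agg[match(key[first], names(agg))],
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$ki_nM), , drop = FALSE]
  rownames(out) <- NULL
  out$y <- binarize(out$ki_nM, threshold_nM)
  out
}

#' Hashed binary featurizer (synthetic fingerprint stand-in)
#'
#' Deterministically maps a compound key to a fixed-length sparse binary
#' vector by hashing. This is a synthetic stand-in that gives the pipeline a
#' chemistry-free fingerprint of the right shape and sparsity; real
#' applications should supply an ECFP4 featurizer (e.g. 4096-bit fingerprints
#' computed with a cheminformatics toolkit) through the same interface: a
#' function `compound_key -> 0/1 vector of length d`.
#'
#' @param d fingerprint length; default 4096.
#' @param n_bits number of bits set per compound; default 32.
#' @return a featurizer function.
#' @export
hashed_featurizer <- function(d = 4096L, n_bits = 32L) {
  force(d); force(n_bits)
  function(compound_key) {
    x <- numeric(d)
    x[(vapply(seq_len(n_bits), function(i)
      derive_seed(0L, compound_key, i), 0L) %% d) + 1L] <- 1
    x
  }
}

#' Build a labeled instance set from curated records
#'
#' Joins curated activity records with target sequences and a featurizer into
#' the [instance_set] consumed by training: fingerprints from the featurizer,
#' per-task sequence encodings from [encode_sequence()].
#'
#' @param curated data frame from [curate_activities()].
#' @param sequences named character vector (or list), target_id -> sequence.
#' @param featurizer function `compound_key -> 0/1 vector`; default
#'   [hashed_featurizer()].
#' @param max_len sequence-encoding length for [encode_sequence()].
#' @return an [instance_set].
#' @export
build_instances <- function(curated, sequences,
                            featurizer = hashed_featurizer(),
                            max_len = 512L) {
  missing_seq <- setdiff(unique(curated$target_id), names(sequences))
  if (length(missing_seq) > 0L)
    stop(sprintf("no sequence for target(s): %s",
                 paste(missing_seq, collapse = ", ")), call. = FALSE)
  X <- t(vapply(curated$compound_key, featurizer,
                numeric(length(featurizer(curated$compound_key[1])))))
  enc <- lapply(sequences[unique(curated$target_id)], encode_sequence,
                max_len = max_len)
  S <- do.call(rbind, enc[curated$target_id])
  instance_set(X, curated$y, curated$target_id, curated$compound_key, S)
}

#' Report per-task active fractions
#'
#' Reporting utility for the 25-50 percent active-fraction regime in which
#' low-data classification tasks are usually selected; not applied as an
#' automatic filter.
#'
#' @param records an [instance_set] or a curated data frame with `target_id`
#'   (or `task_id`) and `y` columns.
#' @return data frame with `task_id`, `n`, `n_active`, `active_fraction`.
#' @export
active_fraction_report <- function(records) {
  if (inherits(records, "instance_set")) {
    task <- records$task_id; y <- records$y
  } else {
    task <- if ("task_id" %in% names(records)) records$task_id else records$target_id
    y <- records$y
  }
  out <- do.call(rbind, lapply(split(y, task), function(v)
    data.frame(n = length(v), n_active = sum(v),
               active_fraction = mean(v))))
  data.frame(task_id = rownames(out), out, row.names = NULL)
}
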