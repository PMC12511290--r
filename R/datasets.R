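#' Labeled instance set
#'
#' The package's basic data container: a set of labeled (fingerprint, label,
#' task) triples. Each instance carries a binary fingerprint `x` (one row of
#' `X`), a binary activity label `y` (1 = active), the task it belongs to
#' (a protein target), the compound key, and the encoded sequence
#' representation `s` of its task (one row of `S`).
#'
#' @param X numeric matrix, `n x d`, binary fingerprints.
#' @param y numeric/integer vector of 0/1 labels, length `n`.
#' @param task_id character vector, length `n`.
#' @param compound_key character vector, length `n`.
#' @param S numeric matrix, `n x L`, per-instance encoded task sequences
#'   (rows repeat within a task).
#' @return an object of class `instance_set`.
#' @export
instance_set <- function(X, y, task_id, compound_key, S) {
  X <- as.matrix(X)
  S <- as.matrix(S)
  n <- nrow(X)
  y <- as.numeric(y)
  stopifnot(length(y) == n, length(task_id) == n,
            length(compound_key) == n, nrow(S) == n)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  structure(list(X = X, y = y, task_id = as.character(task_id),
                 compound_key = as.character(compound_key), S = S),
            class = "instance_set")
}

#' @export
length.instance_set <- function(x) nrow(x$X)

#' Subset an instance set
#' @param x an `instance_set`.
#' @param i row index (logical or integer).
#' @param ... unused.
#' @return an `instance_set` with the selected instances.
#' @export
`[.instance_set` <- function(x, i, ...) {
  instance_set(x$X[i, , drop = FALSE], x$y[i], x$task_id[i],
               x$compound_key[i], x$S[i, , drop = FALSE])
}

#' @export
print.instance_set <- function(x, ...) {
  cat(sprintf("<instance_set> %d instances, %d tasks, d = %d, seq dim = %d\n",
              length(x), length(unique(x$task_id)), ncol(x$X), ncol(x$S)))
  tab <- table(x$task_id)
  cat("  per task:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

# rbind-like combination of instance sets
bind_instances <- function(sets) {
  instance_set(do.call(rbind, lapply(sets, `[[`, "X")),
               unlist(lapply(sets, `[[`, "y")),
               unlist(lapply(sets, `[[`, "task_id")),
               unlist(lapply(sets, `[[`, "compound_key")),
               do.call(rbind, lapply(sets, `[[`, "S")))
}

#' Target train/test split
#'
#' Container for a low-data target task: `train` holds the few labeled
#' instances available for fine-tuning (and meta-supervision), `test` the
#' held-out remainder used for evaluation. Both are [instance_set]s of a
#' single task with disjoint compound keys.
#'
#' @param train,test `instance_set`s of the same single task.
#' @return an object of class `target_split`.
#' @export
target_split <- function(train, test) {
  stopifnot(inherits(train, "instance_set"), inherits(test, "instance_set"))
  tasks <- unique(c(train$task_id, test$task_id))
  if (length(tasks) != 1L)
    stop("target split must cover exactly one task", call. = FALSE)
  if (length(intersect(train$compound_key, test$compound_key)) > 0L)
    stop("train and test share compound keys", call. = FALSE)
  structure(list(train = train, test = test), class = "target_split")
}

#' @export
print.target_split <- function(x, ...) {
  cat(sprintf("<target_split> task %s: %d train (%d active) / %d test (%d active)\n",
              x$train$task_id[1], length(x$train), sum(x$train$y),
              length(x$test), sum(x$test$y)))
  invisible(x)
}
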