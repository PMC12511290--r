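#' Write a synthetic panel to disk
#'
#' Writes `instances.tsv` (task_id, instance_id, label, fingerprint as a 0/1
#' string), `sequences.fasta` (one record per task) and `concepts.json`
#' (per-task metadata: relation, cosine to target, latent concept).
#'
#' @param panel a `synthetic_panel` from [make_panel()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  all_inst <- bind_instances(list(panel$source, panel$target))
  df <- data.frame(task_id = all_inst$task_id,
                   instance_id = all_inst$compound_key,
                   label = all_inst$y,
                   fingerprint = apply(all_inst$X, 1, paste, collapse = ""),
                   stringsAsFactors = FALSE)
  utils::write.table(df, file.path(dir, "instances.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  seqs <- Biostrings::AAStringSet(vapply(panel$concepts, `[[`, "", "sequence"))
  names(seqs) <- names(panel$concepts)
  Biostrings::writeXStringSet(seqs, file.path(dir, "sequences.fasta"))
  meta <- lapply(panel$concepts, function(cc)
    list(task_id = cc$task_id, relation = cc$relation,
         cosine = cc$cosine, beta = cc$beta))
  jsonlite::write_json(list(config = unclass(panel$config), concepts = meta),
                       file.path(dir, "concepts.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a panel written by [write_panel()]
#'
#' @param dir directory containing `instances.tsv`, `sequences.fasta` and
#'   `concepts.json`.
#' @return a `synthetic_panel` list (source, target, concepts, config).
#' @export
read_panel <- function(dir) {
  df <- utils::read.delim(file.path(dir, "instances.tsv"),
                          colClasses = c("character", "character",
                                         "numeric", "character"))
  js <- jsonlite::read_json(file.path(dir, "concepts.json"),
                            simplifyVector = FALSE)
  cfg <- do.call(synthetic_panel_config, lapply(js$config, unlist))
  seqs <- read_sequences(file.path(dir, "sequences.fasta"))
  X <- do.call(rbind, lapply(strsplit(df$fingerprint, ""), as.numeric))
  enc <- lapply(seqs, encode_sequence, max_len = cfg$seq_len)
  S <- do.call(rbind, enc[df$task_id])
  all_inst <- instance_set(X, df$label, df$task_id, df$instance_id, S)
  concepts <- lapply(js$concepts, function(cc)
    list(task_id = cc$task_id, relation = cc$relation,
         cosine = cc$cosine, beta = unlist(cc$beta),
         sequence = seqs[[cc$task_id]]))
  names(concepts) <- vapply(concepts, `[[`, "", "task_id")
  structure(list(source = all_inst[all_inst$task_id != "target"],
                 target = all_inst[all_inst$task_id == "target"],
                 concepts = concepts, config = cfg),
            class = "synthetic_panel")
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_sequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), names(ss))
}

#' Read a bioactivity table
#'
#' CSV or TSV (by extension) with header columns `compound_key`, `target_id`,
#' `ki_nM` and optionally `mass_da`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_activities <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE)
}
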