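#' Configuration of an end-to-end experiment
#'
#' Bundles a data mode, a calculation setting, the methods to compare, and a
#' global seed into one object. The setting drives the protocol defaults
#' (freezing, epochs, exclusion threshold) via [setting_defaults()];
#' individual entries can be overridden through `control`.
#'
#' @param mode `"synthetic"` (built-in panel generator) or `"real"` (caller
#'   supplies a panel built from curated data).
#' @param setting `"overlap"` or `"no_overlap"`.
#' @param methods methods to run, a subset of
#'   `c("meta", "standard", "target_only", "rf_control")`.
#' @param panel a [synthetic_panel_config()] (synthetic mode) or a list with
#'   `source` and `target` instance sets (real mode).
#' @param n_trials fine-tuning trials per method.
#' @param n_train stratified training instances per trial.
#' @param seed global seed; all stage and trial seeds derive from it.
#' @param out_dir optional output directory for result files.
#' @param control named list overriding entries of [setting_defaults()].
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(mode = c("synthetic", "real"),
                              setting = c("no_overlap", "overlap"),
                              methods = c("meta", "standard", "target_only"),
                              panel = synthetic_panel_config(),
                              n_trials = 10L, n_train = 50L, seed = 1L,
                              out_dir = NULL, control = list()) {
  mode <- match.arg(mode)
  if (length(setting) > 1L) setting <- setting[1]
  if (!setting %in% c("overlap", "no_overlap"))
    config_stop("setting", "must be 'overlap' or 'no_overlap'")
  bad <- setdiff(methods, c("meta", "standard", "target_only", "rf_control"))
  if (length(bad) > 0L)
    config_stop("methods", paste("unknown method:", paste(bad, collapse = ", ")))
  ctl <- setting_defaults(setting)
  ctl[names(control)] <- control
  structure(list(mode = mode, setting = setting, methods = methods,
                 panel = panel, n_trials = as.integer(n_trials),
                 n_train = as.integer(n_train), seed = as.integer(seed),
                 out_dir = out_dir, control = ctl),
            class = "experiment_config")
}

#' Run an end-to-end experiment
#'
#' Generates (or accepts) a multi-task panel, runs the requested methods
#' through pre-training / fine-tuning trials, and compiles an evaluation
#' report: per-trial AUCs, trial-by-trial paired comparisons against the
#' `meta` method, and negative transfer indices against the `target_only`
#' reference. If `cfg$out_dir` is set, per-trial AUCs (`trials.csv`), the
#' report (`report.json`) and a manifest with file checksums
#' (`manifest.json`) are written there; re-running with the same
#' configuration reproduces the files.
#'
#' @param cfg an [experiment_config()].
#' @return an object of class `evaluation_report`: `trials` (data frame),
#'   `comparisons` (list of [paired_comparison()] results), `nti` (data
#'   frame), `panel_relatedness`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  panel <- if (cfg$mode == "synthetic") {
    pc <- cfg$panel
    pc$seed <- derive_seed(cfg$seed, "panel")
    make_panel(do.call(synthetic_panel_config, unclass(pc)[
      setdiff(names(unclass(pc)), character(0))]))
  } else {
    cfg$panel
  }
  if (cfg$setting == "no_overlap" && cfg$mode == "real") {
    target_compounds <- unique(panel$target$compound_key)
    keep <- !(panel$source$compound_key %in% target_compounds)
    panel$source <- panel$source[keep]
  }

  trials <- do.call(rbind, lapply(cfg$methods, function(mm)
    run_trials(panel, mm, n_trials = cfg$n_trials, n_train = cfg$n_train,
               seed = cfg$seed, control = cfg$control)))

  auc_of <- function(mm) trials$auc[trials$method == mm]
  comparisons <- list()
  if ("meta" %in% cfg$methods) {
    for (other in setdiff(cfg$methods, "meta")) {
      comparisons[[paste0("meta_vs_", other)]] <-
        paired_comparison(auc_of("meta"), auc_of(other), "meta", other)
    }
  }
  nti_tab <- NULL
  if ("target_only" %in% cfg$methods) {
    transfer_methods <- intersect(cfg$methods, c("meta", "standard"))
    if (length(transfer_methods) > 0L)
      nti_tab <- data.frame(
        method = transfer_methods,
        nti = vapply(transfer_methods, function(mm)
          nti(auc_of("target_only"), auc_of(mm)), 0),
        row.names = NULL)
  }
  report <- structure(list(
    trials = trials, comparisons = comparisons, nti = nti_tab,
    panel_relatedness = if (!is.null(panel$concepts))
      relatedness_report(panel$concepts) else NULL,
    config = cfg), class = "evaluation_report")

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

# serialize a report plus a manifest with checksums of every written file
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$trials, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  js <- list(
    setting = report$config$setting,
    seed = report$config$seed,
    n_trials = report$config$n_trials,
    n_train = report$config$n_train,
    mean_auc = lapply(split(report$trials$auc, report$trials$method), mean),
    comparisons = lapply(report$comparisons, function(cc)
      list(p_value = cc$p_value, stars = cc$stars,
           median_dauc = cc$median_dauc, statistic = cc$statistic)),
    nti = report$nti)
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c("trials.csv", "report.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("metatransfer")),
    r_version = R.version.string,
    seed = report$config$seed,
    files = lapply(stats::setNames(files, files), function(f)
      unname(tools::md5sum(file.path(dir, f)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  means <- vapply(split(x$trials$auc, x$trials$method), mean, 0)
  for (mm in names(means))
    cat(sprintf("  mean AUC %-12s %.4f\n", mm, means[mm]))
  for (cc in x$comparisons)
    cat(sprintf("  %s vs %s: median dAUC %+0.4f, p = %.4g (%s)\n",
                cc$name_a, cc$name_b, cc$median_dauc, cc$p_value, cc$stars))
  if (!is.null(x$nti))
    for (i in seq_len(nrow(x$nti)))
      cat(sprintf("  NTI (target_only - %s): %+0.4f\n",
                  x$nti$method[i], x$nti$nti[i]))
  invisible(x)
}
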