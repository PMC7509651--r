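# End-to-end orchestration: simulate or load a cohort, QC, prepare, run the
# univariate marker screen, the importance screen, the stabilised tree
# build and the evaluation, writing every intermediate artifact with the
# seed and configuration echoed.

#' Assemble a pipeline run configuration
#'
#' @param generator A [generator_config()] (used when `cohort_csv` is NULL).
#' @param cohort_csv Optional path to an input cohort CSV instead of
#'   simulation.
#' @param scheme `"crc"` or `"breast"`, or an [age_scheme()].
#' @param markers Tree candidate markers.
#' @param qc List with `min_ref_a67`, `max_dii`.
#' @param marker_resamples Bootstrap resamples for the marker table.
#' @param tree List with `alpha`, `n_trees`, `n_thresh` and [split_control()]
#'   fields.
#' @param importance_resamples Resamples for the importance screen.
#' @param eval_resamples Bootstrap resamples for performance CIs.
#' @param early_stages Stage labels counted as early for the subgroup row.
#' @param seed Mandatory RNG seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(generator = default_crc_config(),
                       cohort_csv = NULL, scheme = "crc",
                       markers = tree_markers(),
                       qc = list(min_ref_a67 = 450, max_dii = 0.4),
                       marker_resamples = 2000,
                       tree = list(alpha = 0.05, n_trees = 500,
                                   n_thresh = 2000),
                       importance_resamples = 500,
                       eval_resamples = 2000,
                       early_stages = c("0", "I", "II"),
                       seed) {
  if (missing(seed) || is.null(seed)) stop_invalid("run_config: seed is mandatory")
  if (!is.null(cohort_csv) && !file.exists(cohort_csv)) {
    stop_invalid("run_config: cohort_csv does not exist: ", cohort_csv)
  }
  structure(list(generator = generator, cohort_csv = cohort_csv,
                 scheme = scheme, markers = markers, qc = qc,
                 marker_resamples = marker_resamples, tree = tree,
                 importance_resamples = importance_resamples,
                 eval_resamples = eval_resamples,
                 early_stages = early_stages, seed = seed),
            class = "run_config")
}

resolve_scheme <- function(scheme) {
  if (inherits(scheme, "age_scheme")) return(scheme)
  switch(as.character(scheme),
         crc = crc_age_scheme(),
         breast = breast_age_scheme(),
         stop_invalid("unknown age scheme: ", scheme))
}

config_fingerprint <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %%
            4294967291)
}

write_csv_with_provenance <- function(df, path, version, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cfscreen %s config=%s seed=%s", version, hash, seed),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full screening analysis pipeline
#'
#' Executes simulate/load, QC, missing-value removal, the per-marker ROC
#' report (age-matched), the resampled importance screen, the matched
#' train/test split, the stabilised global-tree build and the evaluation
#' (training, held-out, early-stage sets), writing `cohort.csv`,
#' `qc_report.json`, `marker_table.csv`, `importance.csv`, `tree.json`,
#' `tree.txt`, `performance.csv` and `manifest.json` into `out_dir`. Every
#' artifact embeds the package version, a configuration fingerprint and the
#' seed. Deterministic given the configuration and seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `qc_report`, `marker_table`, `importance`, `tree`, `performance`) and
#'   the output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  version <- as.character(utils::packageVersion("cfscreen"))
  hash <- config_fingerprint(config)
  scheme <- resolve_scheme(config$scheme)
  path <- function(f) file.path(out_dir, f)

  cohort <- if (!is.null(config$cohort_csv)) {
    read_cohort_csv(config$cohort_csv)
  } else {
    generate_cohort(config$generator, seed = derive_seed(seed, "simulate"))
  }
  attr(cohort, "provenance") <- c(attr(cohort, "provenance"),
                                  list(config = hash, version = version))
  write_cohort_csv(cohort, path("cohort.csv"))

  qc <- apply_qc_filters(cohort, min_ref_a67 = config$qc$min_ref_a67,
                         max_dii = config$qc$max_dii)
  write_qc_report(qc$report, path("qc_report.json"))

  prepared <- remove_missing(qc$cohort, config$markers)$cohort
  if (!any(is_cancer_label(prepared$group)) ||
      !any(!is_cancer_label(prepared$group))) {
    stop_invalid("run_pipeline: prepared cohort is single-class; cannot ",
                 "build a tree")
  }

  mt <- marker_table(prepared, markers = config$markers, age_matched = TRUE,
                     scheme = scheme,
                     n_resamples = config$marker_resamples,
                     seed = derive_seed(seed, "markers"))
  write_csv_with_provenance(mt, path("marker_table.csv"), version, hash, seed)

  imp <- importance_over_resamples(prepared, variables = config$markers,
                                   scheme = scheme,
                                   n_resamples = config$importance_resamples,
                                   seed = derive_seed(seed, "importance"))
  imp_summary <- data.frame(variable = colnames(imp),
                            median_importance = apply(imp, 2, stats::median),
                            mean_importance = colMeans(imp),
                            stringsAsFactors = FALSE)
  write_csv_with_provenance(imp_summary, path("importance.csv"), version,
                            hash, seed)

  split <- split_train_test(prepared, scheme,
                            seed = derive_seed(seed, "split"))
  tree <- build_global_tree(split$train, candidates = config$markers,
                            scheme = scheme, alpha = config$tree$alpha,
                            n_trees = config$tree$n_trees,
                            n_thresh = config$tree$n_thresh,
                            seed = derive_seed(seed, "tree"))
  write_tree_json(tree, path("tree.json"))
  writeLines(format(tree), path("tree.txt"))

  perf <- list(
    performance(tree, split$train, n_resamples = config$eval_resamples,
                seed = derive_seed(seed, "perf_train"),
                set_name = "training"),
    if (nrow(split$test) > 0 &&
        length(unique(is_cancer_label(split$test$group))) == 2) {
      performance(tree, split$test, n_resamples = config$eval_resamples,
                  seed = derive_seed(seed, "perf_test"),
                  set_name = "testing")
    }
  )
  early <- intersect(config$early_stages, prepared$stage)
  if (length(early)) {
    perf[[length(perf) + 1L]] <- subgroup_performance(
      tree, prepared, filter = early, set_name = "early-stage",
      n_resamples = config$eval_resamples,
      seed = derive_seed(seed, "perf_early")
    )
  }
  perf <- Filter(Negate(is.null), perf)
  perf_df <- do.call(rbind, lapply(perf, as.data.frame))
  write_csv_with_provenance(perf_df, path("performance.csv"), version, hash,
                            seed)

  jsonlite::write_json(
    list(version = version, config_fingerprint = hash, seed = seed,
         n_input = qc$report$n_input,
         n_after_qc = nrow(qc$cohort), n_prepared = nrow(prepared),
         n_train = nrow(split$train), n_test = nrow(split$test),
         files = c("cohort.csv", "qc_report.json", "marker_table.csv",
                   "importance.csv", "tree.json", "tree.txt",
                   "performance.csv")),
    path("manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(list(cohort = cohort, qc_report = qc$report, marker_table = mt,
                 importance = imp_summary, tree = tree,
                 performance = perf_df, split = split, out_dir = out_dir))
}
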