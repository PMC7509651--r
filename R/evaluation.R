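# Tree evaluation: confusion-matrix performance with empirical bootstrap
# confidence intervals on training, held-out, subgroup and cross-cohort
# sets, plus the stability comparison between the stabilised builder and
# conventional single-fit trees.

se_sp_from_predictions <- function(pred, cancer) {
  ok <- !is.na(pred)
  tp <- sum(ok & cancer & pred == "cancer")
  fn <- sum(ok & cancer & pred == "healthy")
  tn <- sum(ok & !cancer & pred == "healthy")
  fp <- sum(ok & !cancer & pred == "cancer")
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       se = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       sp = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       n_unclassified = sum(!ok))
}

#' Tree performance with bootstrap confidence intervals
#'
#' Point sensitivity and specificity from the confusion matrix of the
#' (frozen) tree on the evaluation set, with empirical (basic) bootstrap
#' confidence intervals over resamples of the evaluation set only -- the
#' tree is never refitted. CIs are clipped to `[0, 1]` (the basic method can
#' overshoot); replicates that lose a class contribute `NA` and are dropped
#' from the quantiles. A single-class evaluation set reports the undefined
#' metric as `NA` and still computes the other.
#'
#' @param tree A `cfs_tree`.
#' @param cohort Evaluation cohort.
#' @param n_resamples Bootstrap resamples (default 2000).
#' @param level Confidence level.
#' @param seed RNG seed.
#' @param set_name Label stored in the report.
#' @return Object of class `performance_report` with confusion counts,
#'   `se`, `sp` and their CI bounds.
#' @export
performance <- function(tree, cohort, n_resamples = 2000, level = 0.95,
                        seed = NULL, set_name = "evaluation") {
  cancer <- is_cancer_label(cohort$group)
  pred <- predict(tree, cohort)
  pt <- se_sp_from_predictions(pred, cancer)
  n <- nrow(cohort)
  reps <- with_seed(seed, {
    out <- matrix(NA_real_, n_resamples, 2)
    for (b in seq_len(n_resamples)) {
      i <- sample.int(n, n, replace = TRUE)
      r <- se_sp_from_predictions(pred[i], cancer[i])
      out[b, ] <- c(r$se, r$sp)
    }
    out
  })
  clip01 <- function(x) pmin(1, pmax(0, x))
  ci <- function(point, v) {
    if (is.na(point)) return(c(NA_real_, NA_real_))
    v <- v[is.finite(v)]
    if (length(v) == 0) return(c(NA_real_, NA_real_))
    qs <- stats::quantile(v - point, c((1 - level) / 2, (1 + level) / 2),
                          names = FALSE, type = 7)
    clip01(point + qs)
  }
  se_ci <- ci(pt$se, reps[, 1])
  sp_ci <- ci(pt$sp, reps[, 2])
  structure(
    list(set_name = set_name, n = n, tp = pt$tp, fp = pt$fp, tn = pt$tn,
         fn = pt$fn, se = pt$se, se_lo = se_ci[1], se_hi = se_ci[2],
         sp = pt$sp, sp_lo = sp_ci[1], sp_hi = sp_ci[2],
         n_unclassified = pt$n_unclassified, n_resamples = n_resamples,
         level = level),
    class = "performance_report"
  )
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("%s (n = %d): Se = %.3f [%.3f, %.3f], Sp = %.3f [%.3f, %.3f]\n",
              x$set_name, x$n, x$se, x$se_lo, x$se_hi,
              x$sp, x$sp_lo, x$sp_hi))
  if (x$n_unclassified > 0) {
    cat(sprintf("  %d subject(s) unclassifiable (missing path value)\n",
                x$n_unclassified))
  }
  invisible(x)
}

#' @export
as.data.frame.performance_report <- function(x, ...) {
  data.frame(set = x$set_name, n = x$n, tp = x$tp, fp = x$fp, tn = x$tn,
             fn = x$fn, se = x$se, se_lo = x$se_lo, se_hi = x$se_hi,
             sp = x$sp, sp_lo = x$sp_lo, sp_hi = x$sp_hi,
             stringsAsFactors = FALSE)
}

#' Split a cohort into a matched training set and a held-out test set
#'
#' The training set is the age-matched subcohort (equal cancer/healthy
#' counts per age category, drawn without replacement); the test set is
#' every remaining subject. The two are disjoint and their union is the
#' cohort.
#'
#' @param cohort Prepared cohort (QC'd, complete-case).
#' @param scheme [age_scheme()].
#' @param seed RNG seed.
#' @return List with `train` and `test` data frames.
#' @export
split_train_test <- function(cohort, scheme = crc_age_scheme(),
                             seed = NULL) {
  ms <- age_matched_resample(cohort, scheme, replace = FALSE, seed = seed)
  test_idx <- setdiff(seq_len(nrow(cohort)), ms$index)
  if (length(test_idx) == 0) {
    warning("split_train_test: matching kept every subject; test set empty")
  }
  list(train = cohort[ms$index, , drop = FALSE],
       test = cohort[test_idx, , drop = FALSE])
}

#' Performance on a cancer subgroup
#'
#' Applies [performance()] to the cancer subjects selected by a predicate
#' (e.g. early stages), pooled with all healthy subjects of the cohort.
#'
#' @param tree A `cfs_tree`.
#' @param cohort Evaluation cohort.
#' @param filter Predicate: either a function of the cohort rows returning
#'   a logical, or a character vector of stages to keep.
#' @param ... Passed to [performance()].
#' @param set_name Label for the report.
#' @return A `performance_report`.
#' @export
subgroup_performance <- function(tree, cohort, filter,
                                 set_name = "subgroup", ...) {
  cancer <- is_cancer_label(cohort$group)
  keep_cancer <- if (is.function(filter)) {
    filter(cohort)
  } else {
    !is.na(cohort$stage) & cohort$stage %in% filter
  }
  keep_cancer <- cancer & keep_cancer
  if (!any(keep_cancer)) {
    stop_invalid("subgroup_performance: no cancer subject matches the ",
                 "predicate (", set_name, ")")
  }
  performance(tree, cohort[keep_cancer | !cancer, , drop = FALSE],
              set_name = set_name, ...)
}

#' Apply a tree across cohorts
#'
#' Evaluates a tree built on one cohort against another (e.g. the CRC tree
#' on the breast cohort); the report is flagged as cross-cohort.
#'
#' @param tree A `cfs_tree` built on cohort A.
#' @param cohort_b Cohort to predict; must carry every variable the tree
#'   uses.
#' @param ... Passed to [performance()].
#' @param set_name Label for the report.
#' @return A `performance_report` with `cross_cohort = TRUE`.
#' @export
cross_cohort_apply <- function(tree, cohort_b, set_name = "cross-cohort",
                               ...) {
  missing_vars <- setdiff(tree_variables_used(tree), names(cohort_b))
  if (length(missing_vars)) {
    stop_invalid("cross_cohort_apply: cohort lacks variable(s): ",
                 paste(missing_vars, collapse = ", "))
  }
  rep <- performance(tree, cohort_b, set_name = set_name, ...)
  rep$cross_cohort <- TRUE
  rep
}

#' Stability comparison: stabilised builder versus conventional trees
#'
#' Over `n_splits` random 2/3-1/3 partitions (stratified by class) of the
#' cohort, fits (a) a conventional greedy tree on the learning 2/3 and (b)
#' the stabilised global tree with the matched procedure on the same 2/3,
#' evaluating both on the held-out 1/3. Reports per-split test sensitivity
#' and specificity and per-method means, standard deviations and mean
#' bootstrap CI widths.
#'
#' @param cohort Prepared cohort.
#' @param n_splits Number of partitions (default 20).
#' @param scheme [age_scheme()].
#' @param candidates Tree candidate variables.
#' @param control [split_control()].
#' @param alpha,n_trees,n_thresh Stabilised-builder settings (scaled-down
#'   resampling defaults keep the comparison affordable).
#' @param ci_resamples Bootstrap resamples for the per-split CI widths.
#' @param seed RNG seed.
#' @return List with `results` (one row per split and method) and
#'   `summary` (per-method mean/SD of test Se and Sp and mean CI widths).
#' @export
compare_stability <- function(cohort, n_splits = 20,
                              scheme = crc_age_scheme(),
                              candidates = tree_markers(),
                              control = split_control(), alpha = 0.05,
                              n_trees = 100, n_thresh = 200,
                              ci_resamples = 500, seed = NULL) {
  cohort <- remove_missing(cohort, candidates)$cohort
  cancer_idx <- which(is_cancer_label(cohort$group))
  healthy_idx <- which(!is_cancer_label(cohort$group))
  rows <- list()
  for (s in seq_len(n_splits)) {
    split_seed <- derive_seed(seed, paste0("split", s))
    train_idx <- with_seed(split_seed, {
      c(sample(cancer_idx, round(2 / 3 * length(cancer_idx))),
        sample(healthy_idx, round(2 / 3 * length(healthy_idx))))
    })
    train <- cohort[sort(train_idx), , drop = FALSE]
    test <- cohort[setdiff(seq_len(nrow(cohort)), train_idx), , drop = FALSE]
    conv <- grow_tree(train, candidates, control)
    glob <- build_global_tree(train, candidates, scheme = scheme,
                              control = control, alpha = alpha,
                              n_trees = n_trees, n_thresh = n_thresh,
                              seed = derive_seed(split_seed, "global"))
    for (m in c("conventional", "iterative")) {
      tree <- if (m == "conventional") conv else glob
      rep <- performance(tree, test, n_resamples = ci_resamples,
                         seed = derive_seed(split_seed, paste0("ci_", m)),
                         set_name = m)
      rows[[length(rows) + 1L]] <- data.frame(
        split = s, method = m, se = rep$se, sp = rep$sp,
        se_ci_width = rep$se_hi - rep$se_lo,
        sp_ci_width = rep$sp_hi - rep$sp_lo,
        stringsAsFactors = FALSE
      )
    }
  }
  results <- do.call(rbind, rows)
  summarise <- function(m) {
    r <- results[results$method == m, , drop = FALSE]
    sd_or_na <- function(x) if (length(x) > 1) stats::sd(x) else NA_real_
    data.frame(method = m, n_splits = nrow(r),
               mean_se = mean(r$se), sd_se = sd_or_na(r$se),
               mean_sp = mean(r$sp), sd_sp = sd_or_na(r$sp),
               mean_se_ci_width = mean(r$se_ci_width),
               mean_sp_ci_width = mean(r$sp_ci_width),
               stringsAsFactors = FALSE)
  }
  list(results = results,
       summary = rbind(summarise("conventional"), summarise("iterative")))
}
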