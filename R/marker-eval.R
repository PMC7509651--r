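# Per-marker univariate screening: ROC point estimates with empirical
# bootstrap confidence intervals, unadjusted or under age-matched
# resampling.

marker_orientation <- function(marker) {
  # nuclear concentrations rise in cancer; mitochondrial load and MNR fall
  if (marker %in% c("mnr", "ref_m67")) "lower" else "higher"
}

roc_point_stats <- function(values, cancer, orientation) {
  roc <- roc_curve(values, cancer, orientation = orientation)
  c(threshold = roc$optimal_threshold, sp = roc$sp_at_opt,
    se = roc$se_at_opt, auc = roc$auc)
}

#' Univariate marker evaluation with bootstrap confidence intervals
#'
#' Estimates, for one marker, the closest-corner optimal threshold and the
#' sensitivity, specificity and AUC at it, each with an empirical (basic)
#' bootstrap confidence interval over `n_resamples` resamples. The threshold
#' is re-estimated inside every bootstrap replicate. With
#' `age_matched = TRUE` the point estimates come from one age-matched
#' subcohort (equal cancer/healthy counts per age category, drawn without
#' replacement) and every replicate re-draws a matched bootstrap sample;
#' otherwise replicates are plain resamples of the complete-case rows.
#'
#' @param cohort Cohort data frame.
#' @param marker Marker column name (e.g. `"ref_a67"`, `"mnr"`).
#' @param age_matched Use age-matched resampling.
#' @param scheme [age_scheme()] used when `age_matched = TRUE`.
#' @param n_resamples Bootstrap resamples (default 2000).
#' @param level Confidence level.
#' @param seed RNG seed.
#' @param orientation ROC orientation; defaults to the marker's documented
#'   direction (`"lower"` for `mnr` and `ref_m67`, `"higher"` otherwise).
#' @return One-row data frame with the marker name, group sizes, and
#'   `threshold`, `sp`, `se`, `auc` columns each accompanied by `_lo`/`_hi`
#'   bounds.
#' @export
evaluate_marker <- function(cohort, marker, age_matched = FALSE,
                            scheme = crc_age_scheme(), n_resamples = 2000,
                            level = 0.95, seed = NULL,
                            orientation = marker_orientation(marker)) {
  if (!marker %in% names(cohort)) stop_invalid("unknown marker: ", marker)
  cohort <- cohort[!is.na(cohort[[marker]]), , drop = FALSE]
  cancer <- is_cancer_label(cohort$group)
  if (!any(cancer) || !any(!cancer)) {
    stop_invalid("evaluate_marker: both classes required")
  }
  values <- cohort[[marker]]

  if (age_matched) {
    cat <- assign_age_categories(cohort, scheme)
    pools <- matched_pools(cat, cancer)
    point_idx <- with_seed(derive_seed(seed, "point"),
                           matched_draw(pools, replace = FALSE))
    point <- roc_point_stats(values[point_idx], cancer[point_idx],
                             orientation)
    reps <- with_seed(derive_seed(seed, "boot"), {
      t(vapply(seq_len(n_resamples), function(b) {
        i <- matched_draw(pools, replace = TRUE)
        roc_point_stats(values[i], cancer[i], orientation)
      }, numeric(4)))
    })
    n_cancer <- sum(cancer[point_idx])
    n_healthy <- sum(!cancer[point_idx])
  } else {
    point <- roc_point_stats(values, cancer, orientation)
    n <- length(values)
    reps <- with_seed(derive_seed(seed, "boot"), {
      out <- matrix(NA_real_, n_resamples, 4)
      for (b in seq_len(n_resamples)) {
        for (r in 1:100) {
          i <- sample.int(n, n, replace = TRUE)
          if (any(cancer[i]) && any(!cancer[i])) break
        }
        out[b, ] <- roc_point_stats(values[i], cancer[i], orientation)
      }
      out
    })
    n_cancer <- sum(cancer)
    n_healthy <- sum(!cancer)
  }

  stat_names <- c("threshold", "sp", "se", "auc")
  row <- list(marker = marker, n_cancer = n_cancer, n_healthy = n_healthy,
              orientation = orientation)
  for (j in seq_along(stat_names)) {
    ci <- basic_ci_from_replicates(unname(point[j]), reps[, j],
                                   level = level)
    row[[stat_names[j]]] <- ci$point
    row[[paste0(stat_names[j], "_lo")]] <- ci$lower
    row[[paste0(stat_names[j], "_hi")]] <- ci$upper
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Marker panel report
#'
#' Runs [evaluate_marker()] for each marker and stacks the rows into the
#' familiar screening-table shape (threshold, specificity, sensitivity and
#' AUC, each with confidence bounds).
#'
#' @param cohort Cohort data frame.
#' @param markers Marker names (default: the five panel markers used for
#'   tree building).
#' @param ... Passed to [evaluate_marker()].
#' @param seed RNG seed; each marker gets a derived sub-seed.
#' @return Data frame, one row per marker.
#' @export
marker_table <- function(cohort, markers = tree_markers(), seed = NULL,
                         ...) {
  rows <- lapply(markers, function(m) {
    evaluate_marker(cohort, m, seed = derive_seed(seed, m), ...)
  })
  do.call(rbind, rows)
}
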