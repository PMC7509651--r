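# ROC analysis: curve construction over midpoint thresholds, rank-based AUC
# with ties counted one half, and the closest-to-ideal-corner optimal
# cut-point.

coerce_cancer_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  is_cancer_label(labels)
}

#' ROC curve for a single marker
#'
#' Builds the ROC curve of a numeric marker against a binary cancer/healthy
#' label. Candidate thresholds are the midpoints between consecutive distinct
#' pooled values, with `-Inf`/`+Inf` sentinels. Under the
#' `"higher-in-cancer"` orientation a subject is called cancer when its value
#' is strictly greater than the threshold; under `"lower-in-cancer"`, when
#' strictly lower. `orientation = "auto"` picks `"lower-in-cancer"` when the
#' raw AUC is below 0.5 and records the flip.
#'
#' @param values Numeric marker values (no missing values; remove upstream).
#' @param labels Logical cancer indicator, or group labels where anything
#'   other than `"healthy"` counts as cancer.
#' @param orientation `"auto"`, `"higher"` (higher-in-cancer) or `"lower"`.
#' @return An object of class `cfs_roc`: `thresholds` (original scale),
#'   `sensitivity`, `specificity`, `auc`, `orientation`, group sizes, and
#'   the optimal threshold with its Se/Sp (see [optimal_threshold()]).
#' @export
roc_curve <- function(values, labels, orientation = c("auto", "higher",
                                                      "lower")) {
  orientation <- match.arg(orientation)
  cancer <- coerce_cancer_labels(labels)
  if (anyNA(values) || anyNA(cancer)) {
    stop_invalid("roc_curve: missing values must be removed upstream")
  }
  n1 <- sum(cancer)
  n2 <- sum(!cancer)
  if (n1 == 0 || n2 == 0) {
    stop_invalid("roc_curve: both classes must be present")
  }
  # rank-based AUC, ties counted 0.5: P(cancer > healthy) + 0.5 P(tie)
  r <- rank(values)
  auc_raw <- (sum(r[cancer]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  if (orientation == "auto") {
    orientation <- if (auc_raw < 0.5) "lower" else "higher"
  }
  flip <- orientation == "lower"
  w <- if (flip) -values else values
  sv <- sort(unique(w))
  mids <- if (length(sv) > 1) (sv[-1] + sv[-length(sv)]) / 2 else numeric(0)
  tw <- c(-Inf, mids, Inf)
  sc <- sort(w[cancer])
  sh <- sort(w[!cancer])
  se <- (n1 - findInterval(tw, sc)) / n1  # cancer called when w > t
  sp <- findInterval(tw, sh) / n2         # healthy called when w <= t
  thresholds <- if (flip) -tw else tw
  res <- structure(
    list(marker = NULL, orientation = orientation,
         thresholds = thresholds, sensitivity = se, specificity = sp,
         auc = if (flip) 1 - auc_raw else auc_raw,
         n_cancer = n1, n_healthy = n2),
    class = "cfs_roc"
  )
  opt <- optimal_threshold(res, details = TRUE)
  res$optimal_threshold <- opt$threshold
  res$se_at_opt <- opt$sensitivity
  res$sp_at_opt <- opt$specificity
  res
}

#' Area under the ROC curve
#'
#' Equals the Mann-Whitney U statistic divided by `n1 * n2`, with ties
#' counted one half; identical to trapezoidal integration of the curve.
#'
#' @param roc A `cfs_roc` from [roc_curve()].
#' @return AUC in `[0, 1]` (at least 0.5 when the orientation was chosen
#'   automatically).
#' @export
roc_auc <- function(roc) {
  stopifnot(inherits(roc, "cfs_roc"))
  roc$auc
}

#' Optimal ROC threshold (closest-to-ideal-corner rule)
#'
#' Returns the candidate threshold minimising the Euclidean distance between
#' the ROC curve and the ideal point (Se = 1, 1 - Sp = 0), i.e.
#' `sqrt((1 - Se)^2 + (1 - Sp)^2)`. Ties are broken toward the smaller
#' threshold value.
#'
#' @param roc A `cfs_roc`.
#' @param details Return Se/Sp at the optimum as well.
#' @return The threshold, or a list `(threshold, sensitivity, specificity,
#'   distance)` when `details = TRUE`.
#' @export
optimal_threshold <- function(roc, details = FALSE) {
  stopifnot(inherits(roc, "cfs_roc"))
  d <- sqrt((1 - roc$sensitivity)^2 + (1 - roc$specificity)^2)
  best <- which(d == min(d))
  if (length(best) > 1) best <- best[which.min(roc$thresholds[best])]
  if (!details) return(roc$thresholds[best])
  list(threshold = roc$thresholds[best],
       sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best],
       distance = d[best])
}

#' @export
print.cfs_roc <- function(x, ...) {
  cat(sprintf("ROC (%s-in-cancer): AUC = %.3f, n = %d cancer / %d healthy\n",
              x$orientation, x$auc, x$n_cancer, x$n_healthy))
  cat(sprintf("  optimal threshold %.6g (Se = %.3f, Sp = %.3f)\n",
              x$optimal_threshold, x$se_at_opt, x$sp_at_opt))
  invisible(x)
}
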