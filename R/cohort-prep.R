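# Cohort preparation: missing-value removal, age categorisation,
# age-matched case-control resampling, and the descriptive two-group tests
# used before modelling.

#' Age-category scheme
#'
#' Defines the ordered age categories used for case-control matching, via
#' `cut()` break points, plus an optional admissible age window outside of
#' which subjects are dropped from matching.
#'
#' @param breaks Strictly increasing numeric break points passed to
#'   [base::cut()] (right-closed intervals).
#' @param labels Category labels, length `length(breaks) - 1`.
#' @param window Optional `c(min, max)` admissible age window (inclusive).
#' @return An object of class `age_scheme`.
#' @export
age_scheme <- function(breaks, labels = NULL, window = NULL) {
  stopifnot(all(diff(breaks) > 0))
  if (is.null(labels)) {
    labels <- paste(head(breaks, -1), breaks[-1], sep = "-")
  }
  stopifnot(length(labels) == length(breaks) - 1)
  structure(list(breaks = breaks, labels = labels, window = window),
            class = "age_scheme")
}

#' Colorectal-cancer age scheme
#'
#' Five categories: `<45`, `45-50`, `51-55`, `56-60`, `>60`. With integer
#' ages, age 45 falls in the `45-50` category by default; setting
#' `age45_in_lower = TRUE` moves it into `<45` (the bounds in the source
#' material admit either reading, so the alternative is one flag away).
#'
#' @param age45_in_lower Assign age 45 to the lowest category.
#' @return An `age_scheme`.
#' @export
crc_age_scheme <- function(age45_in_lower = FALSE) {
  lo <- if (age45_in_lower) 45 else 44
  age_scheme(breaks = c(-Inf, lo, 50, 55, 60, Inf),
             labels = c("<45", "45-50", "51-55", "56-60", ">60"))
}

#' Breast-cancer age scheme
#'
#' Ages restricted to the 25-65 window, matched in 5-year bands within it.
#'
#' @return An `age_scheme` with `window = c(25, 65)`.
#' @export
breast_age_scheme <- function() {
  age_scheme(breaks = c(24, 30, 35, 40, 45, 50, 55, 60, 65),
             labels = c("25-30", "31-35", "36-40", "41-45",
                        "46-50", "51-55", "56-60", "61-65"),
             window = c(25, 65))
}

#' Assign age categories
#'
#' Maps each subject to exactly one category of the scheme. Subjects with
#' missing ages, or ages outside the scheme's window, get `NA` and are
#' excluded from age-matched analyses (they remain available for unadjusted
#' ones).
#'
#' @param cohort Cohort data frame with an `age` column (or an age vector).
#' @param scheme An [age_scheme()].
#' @return Factor of categories, `NA` for unmatchable subjects.
#' @export
assign_age_categories <- function(cohort, scheme) {
  stopifnot(inherits(scheme, "age_scheme"))
  age <- if (is.data.frame(cohort)) cohort$age else cohort
  cat <- cut(age, breaks = scheme$breaks, labels = scheme$labels,
             right = TRUE)
  if (!is.null(scheme$window)) {
    cat[!is.na(age) & (age < scheme$window[1] | age > scheme$window[2])] <- NA
  }
  cat
}

#' Remove subjects with missing values on analysis variables
#'
#' @param cohort Cohort data frame.
#' @param variables Marker/panel variable names that must be present.
#' @return List with `cohort` (complete cases) and `n_removed`, a named
#'   count per group.
#' @export
remove_missing <- function(cohort, variables) {
  unknown <- setdiff(variables, names(cohort))
  if (length(unknown)) {
    stop_invalid("unknown variable(s): ", paste(unknown, collapse = ", "))
  }
  keep <- rep(TRUE, nrow(cohort))
  for (v in variables) keep <- keep & !is.na(cohort[[v]])
  removed <- cohort$group[!keep]
  n_removed <- c(cancer = sum(is_cancer_label(removed)),
                 healthy = sum(!is_cancer_label(removed)))
  list(cohort = cohort[keep, , drop = FALSE], n_removed = n_removed)
}

#' Age-matched case-control resampling
#'
#' Within each age category, draws `min(n_cancer, n_healthy)` subjects from
#' each group -- without replacement for a matched subcohort, or with
#' replacement for a matched bootstrap replicate. The pooled draw is
#' age-balanced by construction. Categories empty in either group are
#' skipped and recorded.
#'
#' @param cohort Cohort data frame.
#' @param scheme An [age_scheme()].
#' @param replace Draw with replacement (matched bootstrap)?
#' @param seed RNG seed.
#' @return An object of class `matched_sample`: integer row `index` into
#'   `cohort`, subject `ids`, the per-category `category_table`
#'   (cancer/healthy counts drawn), `skipped` categories, `replace`, `seed`.
#' @export
age_matched_resample <- function(cohort, scheme, replace = FALSE,
                                 seed = NULL) {
  cat <- assign_age_categories(cohort, scheme)
  cancer <- is_cancer_label(cohort$group)
  pools <- matched_pools(cat, cancer)
  idx <- with_seed(seed, matched_draw(pools, replace))
  drawn_cat <- table(factor(cat[idx], levels = levels(cat)),
                     ifelse(cancer[idx], "cancer", "healthy"))
  structure(
    list(index = idx,
         ids = if ("subject_id" %in% names(cohort)) {
           cohort$subject_id[idx]
         } else {
           as.character(idx)
         },
         category_table = drawn_cat,
         skipped = pools$skipped, replace = replace, seed = seed),
    class = "matched_sample"
  )
}

# Precompute per-category cancer/healthy index pools (internal; reused by
# resampling-heavy callers so repeated draws avoid re-categorising).
matched_pools <- function(cat, cancer) {
  keep <- !is.na(cat)
  lv <- levels(cat)
  pools <- list()
  skipped <- character(0)
  for (l in lv) {
    ic <- which(keep & cat == l & cancer)
    ih <- which(keep & cat == l & !cancer)
    if (length(ic) == 0 || length(ih) == 0) {
      if (length(ic) + length(ih) > 0) skipped <- c(skipped, l)
      next
    }
    pools[[l]] <- list(cancer = ic, healthy = ih)
  }
  list(pools = pools, skipped = skipped)
}

matched_draw <- function(pools, replace) {
  idx <- integer(0)
  for (p in pools$pools) {
    m <- min(length(p$cancer), length(p$healthy))
    draw <- function(x) {
      if (replace) {
        x[sample.int(length(x), m, replace = TRUE)]
      } else if (length(x) == m) {
        x
      } else {
        x[sample.int(length(x), m)]
      }
    }
    idx <- c(idx, draw(p$cancer), draw(p$healthy))
  }
  sort(idx)
}

#' Serialise a matched sample as JSON
#'
#' @param ms A `matched_sample`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matched_sample <- function(ms, path) {
  out <- list(ids = ms$ids,
              category_table = as.data.frame.matrix(ms$category_table),
              skipped = ms$skipped, replace = ms$replace, seed = ms$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' One-sided Mann-Whitney test with normal approximation
#'
#' Rank-sum comparison of two samples with tie-corrected variance and
#' continuity correction, reported as a z statistic and one-sided p-value.
#' `alternative = "greater"` tests whether `x` is stochastically greater
#' than `y`. When every value across both samples is tied the statistic is
#' degenerate and `(z = 0, p = 0.5)` is returned.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"greater"` or `"less"`.
#' @return List with `z` and `p`.
#' @export
mann_whitney_one_sided <- function(x, y,
                                   alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) > 0, length(y) > 0)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(list(z = 0, p = 0.5))
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = FALSE,
                       correct = TRUE)
  )
  p <- unname(ht$p.value)
  list(z = stats::qnorm(p, lower.tail = FALSE), p = p)
}

#' Two-sample proportion test with continuity correction
#'
#' @param k1,n1 Successes and trials in the first sample.
#' @param k2,n2 Successes and trials in the second sample.
#' @param continuity Apply the Yates continuity correction.
#' @return Two-sided p-value.
#' @export
proportion_test <- function(k1, n1, k2, n2, continuity = TRUE) {
  if (n1 <= 0 || n2 <= 0) stop_invalid("proportion_test: n1, n2 must be > 0")
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  ht <- suppressWarnings(
    stats::prop.test(c(k1, k2), c(n1, n2), correct = continuity)
  )
  unname(ht$p.value)
}
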