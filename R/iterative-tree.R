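# Iterative node-stabilised tree construction: at each node, many trees are
# fitted to age-matched bootstrap resamples of the subjects reaching the
# node; the most frequently selected variable is frozen after a chi-squared
# homogeneity check plus a proportion test confirming it beats the
# runner-up, and its threshold is estimated as the bootstrap median with an
# empirical confidence interval. Only then does construction
# descend.

# Route subjects down a frozen path: list of steps
# (variable, threshold, direction) with direction "left" (<=) or "right".
route_path <- function(cohort, path) {
  keep <- rep(TRUE, nrow(cohort))
  for (step in path) {
    v <- cohort[[step$variable]]
    keep <- keep & !is.na(v) &
      if (step$direction == "left") v <= step$threshold else v > step$threshold
  }
  keep
}

#' Resampled variable selection at one node
#'
#' For each of `n_trees` age-matched bootstrap resamples of the subjects
#' reaching the node, finds the best admissible split (subject to the
#' minimum-leaf rule evaluated against the full learning-set size) and
#' records the selected variable; resamples where no admissible split
#' exists count as "no split". A chi-squared homogeneity test is applied to
#' the frequency table over the candidate set; the modal variable is chosen
#' when the test rejects homogeneity at `alpha`. A continuity-corrected
#' proportion test between the two most frequent variables is computed and
#' by default both tests must reject at `alpha` for the modal variable to
#' be frozen (see `require_top_two`).
#'
#' @param cohort Learning cohort (complete cases on the candidates).
#' @param frozen_path Frozen root path (possibly empty list).
#' @param candidates Candidate variable names.
#' @param scheme [age_scheme()] for matched resampling.
#' @param n_trees Resamples per node (default 500).
#' @param alpha Significance level for the chi-squared test.
#' @param control [split_control()].
#' @param seed RNG seed.
#' @param require_top_two Require the top-two proportion test to reject as
#'   well (the default): bootstrap resamples of one cohort are strongly
#'   correlated, so the goodness-of-fit test alone rejects too readily on
#'   noise; demanding that the modal variable also beat the runner-up
#'   restores the intended "no parameter selected" stopping behaviour.
#'   Set to FALSE to make the runner-up comparison advisory only.
#' @return Object of class `node_selection`: `variable` (or `NA`),
#'   `frequencies` over candidates, `n_no_split`, `chi_square_p`,
#'   `top_two_p`, `n_trees`.
#' @export
select_node_variable <- function(cohort, frozen_path = list(), candidates,
                                 scheme = crc_age_scheme(), n_trees = 500,
                                 alpha = 0.05, control = split_control(),
                                 seed = NULL, require_top_two = TRUE) {
  at_node <- route_path(cohort, frozen_path)
  node <- cohort[at_node, , drop = FALSE]
  cancer <- is_cancer_label(node$group)
  if (!any(cancer) || !any(!cancer)) {
    stop_invalid("select_node_variable: node must contain both classes")
  }
  x <- as.matrix(node[, candidates, drop = FALSE])
  y <- as.numeric(cancer)
  n_learning <- nrow(cohort)
  root_ss <- node_ss(as.numeric(is_cancer_label(cohort$group)))
  cat <- assign_age_categories(node, scheme)
  pools <- matched_pools(cat, cancer)

  picks <- with_seed(seed, {
    vapply(seq_len(n_trees), function(b) {
      idx <- matched_draw(pools, replace = TRUE)
      if (length(idx) == 0) return(NA_character_)
      sp <- best_split(x[idx, , drop = FALSE], y[idx], control,
                       allowed = candidates, n_learning = n_learning,
                       root_ss = root_ss)
      if (is.null(sp)) NA_character_ else sp$variable
    }, character(1))
  })
  freq <- table(factor(picks, levels = candidates))
  n_no_split <- sum(is.na(picks))

  chosen <- NA_character_
  chi_p <- NA_real_
  top_two_p <- NA_real_
  if (sum(freq) > 0) {
    chi_p <- if (length(candidates) > 1) {
      suppressWarnings(stats::chisq.test(
        as.vector(freq), p = rep(1 / length(candidates), length(candidates))
      ))$p.value
    } else {
      0  # a single candidate is trivially the modal choice
    }
    ord <- order(freq, decreasing = TRUE)
    if (length(candidates) > 1 && freq[ord[1]] > 0) {
      top_two_p <- proportion_test(freq[ord[1]], n_trees,
                                   freq[ord[2]], n_trees)
    }
    passes <- chi_p < alpha &&
      (!require_top_two || length(candidates) == 1 ||
         (is.finite(top_two_p) && top_two_p < alpha))
    if (passes) chosen <- candidates[ord[1]]
  }
  structure(
    list(variable = chosen, frequencies = freq, n_no_split = n_no_split,
         chi_square_p = chi_p, top_two_p = top_two_p, n_trees = n_trees,
         frozen_path = frozen_path),
    class = "node_selection"
  )
}

#' @export
print.node_selection <- function(x, ...) {
  cat(sprintf("node selection over %d resampled trees (depth %d)\n",
              x$n_trees, length(x$frozen_path)))
  print(x$frequencies)
  cat(sprintf("  no split: %d | chi^2 p = %.3g | top-two p = %.3g | chosen: %s\n",
              x$n_no_split, x$chi_square_p, x$top_two_p,
              ifelse(is.na(x$variable), "<none>", x$variable)))
  invisible(x)
}

#' Bootstrap-median threshold for a frozen node variable
#'
#' For each of `n_resamples` age-matched bootstrap resamples of the
#' subjects reaching the node, computes the best single-split threshold on
#' the chosen variable; the node threshold is the median of the resampled
#' thresholds and its confidence interval comes from the distribution of
#' the differences from the resample mean, added back to the median
#' (empirical bootstrap). Errors if the variable is degenerate at the node
#' (the caller then closes the node as a leaf).
#'
#' @param cohort Learning cohort.
#' @param frozen_path Frozen path to the node.
#' @param variable Chosen split variable.
#' @param scheme [age_scheme()].
#' @param n_resamples Threshold resamples (default 2000).
#' @param level Confidence level.
#' @param control [split_control()].
#' @param seed RNG seed.
#' @return A `bootstrap_ci` whose `point` is the bootstrap-median threshold.
#' @export
estimate_node_threshold <- function(cohort, frozen_path = list(), variable,
                                    scheme = crc_age_scheme(),
                                    n_resamples = 2000, level = 0.95,
                                    control = split_control(), seed = NULL) {
  at_node <- route_path(cohort, frozen_path)
  node <- cohort[at_node, , drop = FALSE]
  v <- node[[variable]]
  if (length(unique(v)) < 2) {
    stop_invalid("estimate_node_threshold: '", variable,
                 "' is degenerate at this node")
  }
  cancer <- is_cancer_label(node$group)
  y <- as.numeric(cancer)
  x <- matrix(v, ncol = 1, dimnames = list(NULL, variable))
  n_learning <- nrow(cohort)
  root_ss <- node_ss(as.numeric(is_cancer_label(cohort$group)))
  cat <- assign_age_categories(node, scheme)
  pools <- matched_pools(cat, cancer)

  thresholds <- with_seed(seed, {
    vapply(seq_len(n_resamples), function(b) {
      idx <- matched_draw(pools, replace = TRUE)
      if (length(idx) == 0) return(NA_real_)
      sp <- best_split(x[idx, , drop = FALSE], y[idx], control,
                       allowed = variable, n_learning = n_learning,
                       root_ss = root_ss)
      if (is.null(sp)) NA_real_ else sp$threshold
    }, numeric(1))
  })
  thresholds <- thresholds[is.finite(thresholds)]
  if (length(thresholds) < max(10, n_resamples / 20)) {
    stop_invalid("estimate_node_threshold: too few resamples admitted a ",
                 "split on '", variable, "'")
  }
  point <- stats::median(thresholds)
  d <- thresholds - mean(thresholds)
  qs <- stats::quantile(d, c((1 - level) / 2, (1 + level) / 2),
                        names = FALSE, type = 7)
  structure(
    list(point = point,
         lower = min(point + qs[1], point),
         upper = max(point + qs[2], point),
         n_resamples = length(thresholds), level = level,
         method = "basic", n_failed = n_resamples - length(thresholds)),
    class = "bootstrap_ci"
  )
}

#' Build the stabilised global decision tree
#'
#' Recursively applies [select_node_variable()] and
#' [estimate_node_threshold()] from the root down: at each node, the modal
#' variable over `n_trees` matched resampled trees is frozen (when the
#' chi-squared homogeneity test rejects at `alpha`), its threshold is set to
#' the bootstrap median over `n_thresh` resamples, and subjects are routed
#' (`value <= threshold` goes left) before recursing on the children.
#' Branch expansion stops when (i) no resample can split the node further,
#' (ii) a further split would leave fewer than the minimum leaf fraction of
#' the learning set, or (iii) the chi-squared test does not select any
#' variable -- plus the engine's depth and node-size guards. Leaves are
#' labelled by majority class (ties healthy) with class proportions and the
#' fraction of the learning set they cover.
#'
#' @param cohort Learning cohort (complete cases on the candidates).
#' @param candidates Candidate variables (default [tree_markers()]).
#' @param scheme [age_scheme()].
#' @param control [split_control()].
#' @param alpha Chi-squared significance level.
#' @param n_trees Resampled trees per node selection.
#' @param n_thresh Resamples for the threshold estimate.
#' @param seed RNG seed; every node draws from a sub-seed derived from it,
#'   so the whole tree is reproducible from (cohort, config, seed).
#' @param require_top_two Also require the top-two proportion test (the
#'   default; see [select_node_variable()]).
#' @return Object of class `cfs_global_tree` (also a `cfs_tree`):
#'   `root`, `variables`, `control`, `n_learning`, plus `build_log`, a list
#'   of per-node `node_selection` records, and `seed`.
#' @export
build_global_tree <- function(cohort, candidates = tree_markers(),
                              scheme = crc_age_scheme(),
                              control = split_control(), alpha = 0.05,
                              n_trees = 500, n_thresh = 2000, seed = NULL,
                              require_top_two = TRUE) {
  if (length(candidates) == 0) {
    y <- as.numeric(is_cancer_label(cohort$group))
    return(structure(list(root = make_leaf(y, length(y)),
                          variables = character(0), control = control,
                          n_learning = length(y), build_log = list(),
                          seed = seed),
                     class = c("cfs_global_tree", "cfs_tree")))
  }
  cc <- remove_missing(cohort, candidates)$cohort
  y_all <- as.numeric(is_cancer_label(cc$group))
  if (!any(y_all == 1) || !any(y_all == 0)) {
    stop_invalid("build_global_tree: both classes required")
  }
  n_learning <- nrow(cc)
  build_log <- list()
  node_counter <- 0L

  build <- function(path, depth) {
    at_node <- route_path(cc, path)
    y <- y_all[at_node]
    node_counter <<- node_counter + 1L
    node_seed <- derive_seed(seed, paste0("node", node_counter))
    if (depth >= control$max_depth || length(y) < control$minsplit ||
        node_ss(y) <= 0) {
      return(make_leaf(y, n_learning))
    }
    sel <- select_node_variable(cc, path, candidates, scheme = scheme,
                                n_trees = n_trees, alpha = alpha,
                                control = control,
                                seed = derive_seed(node_seed, "select"),
                                require_top_two = require_top_two)
    build_log[[length(build_log) + 1L]] <<- sel
    if (is.na(sel$variable)) return(make_leaf(y, n_learning))
    ci <- tryCatch(
      estimate_node_threshold(cc, path, sel$variable, scheme = scheme,
                              n_resamples = n_thresh,
                              control = control,
                              seed = derive_seed(node_seed, "thresh")),
      error = function(e) NULL
    )
    if (is.null(ci)) return(make_leaf(y, n_learning))
    v <- cc[[sel$variable]][at_node]
    left <- v <= ci$point
    if (!any(left) || all(left)) return(make_leaf(y, n_learning))
    node <- list(is_leaf = FALSE, variable = sel$variable,
                 threshold = ci$point,
                 threshold_ci = c(ci$lower, ci$upper),
                 gain = node_ss(y) - node_ss(y[left]) - node_ss(y[!left]),
                 n = length(y), n_cancer = sum(y), prop_cancer = mean(y))
    node$left <- build(c(path, list(list(variable = sel$variable,
                                         threshold = ci$point,
                                         direction = "left"))),
                       depth + 1L)
    node$right <- build(c(path, list(list(variable = sel$variable,
                                          threshold = ci$point,
                                          direction = "right"))),
                        depth + 1L)
    node
  }

  root <- build(list(), 0L)
  structure(list(root = root, variables = candidates, control = control,
                 n_learning = n_learning, build_log = build_log,
                 seed = seed),
            class = c("cfs_global_tree", "cfs_tree"))
}
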