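# Recursive-partitioning engine for a binary outcome with continuous
# predictors, written from scratch so the iterative node-stabilised builder
# can drive it. Splitting minimises within-node sum of squares of the 0/1
# outcome (regression-tree criterion, n * p * (1 - p) per node), which
# orders splits identically to Gini for a binary outcome.

#' Split-search control parameters
#'
#' @param minsplit Minimum subjects in a node to attempt a split.
#' @param min_leaf_fraction Minimum fraction of the learning set a leaf may
#'   hold; the 10% default expresses the rule that branch expansion stops
#'   when fewer than 10% of the learning set would remain after a split.
#' @param cp Minimum impurity improvement to accept a split, relative to the
#'   root impurity.
#' @param max_depth Maximum tree depth (root = depth 0 splits allowed up to
#'   `max_depth` levels).
#' @return List of class `split_control`.
#' @export
split_control <- function(minsplit = 20, min_leaf_fraction = 0.10,
                          cp = 0.01, max_depth = 8) {
  stopifnot(minsplit >= 2, min_leaf_fraction >= 0, min_leaf_fraction < 0.5,
            cp >= 0, max_depth >= 0)
  structure(list(minsplit = as.integer(minsplit),
                 min_leaf_fraction = min_leaf_fraction,
                 cp = cp, max_depth = as.integer(max_depth)),
            class = "split_control")
}

#' Node impurity for a binary outcome
#'
#' Sum of squared deviations of a 0/1 outcome from the node mean:
#' `n * p * (1 - p)`, given the per-class counts.
#'
#' @param outcome_counts Length-2 vector `c(n_healthy, n_cancer)` (order
#'   immaterial).
#' @return Impurity, `>= 0`; 0 for a pure or empty node.
#' @export
impurity <- function(outcome_counts) {
  stopifnot(length(outcome_counts) == 2, all(outcome_counts >= 0))
  n <- sum(outcome_counts)
  if (n == 0) return(0)
  outcome_counts[1] * outcome_counts[2] / n
}

# Internal: impurity of a 0/1 vector.
node_ss <- function(y) {
  n <- length(y)
  if (n == 0) return(0)
  s <- sum(y)
  s - s * s / n
}

#' Best single split of a node
#'
#' Exhaustive scan over the allowed variables and the midpoint thresholds
#' between consecutive distinct values, maximising the impurity decrease
#' subject to `minsplit`, the minimum-leaf rule (evaluated against the
#' learning-set size `n_learning`), and the `cp` improvement threshold
#' (relative to `root_ss`, the learning-set root impurity). Ties are broken
#' toward the lower variable index, then the lower threshold.
#'
#' @param x Numeric matrix (or data frame) of predictor columns.
#' @param y 0/1 (or logical) outcome vector.
#' @param control A [split_control()].
#' @param allowed Variable names eligible for splitting.
#' @param n_learning Learning-set size the minimum-leaf rule refers to
#'   (defaults to the node size, i.e. the node is the whole learning set).
#' @param root_ss Root impurity the `cp` rule refers to (defaults to the
#'   node's own impurity).
#' @return List `(variable, threshold, gain)`, or `NULL` when no admissible
#'   split exists.
#' @export
best_split <- function(x, y, control = split_control(),
                       allowed = colnames(x), n_learning = length(y),
                       root_ss = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < control$minsplit) return(NULL)
  parent_ss <- node_ss(y)
  if (parent_ss <= 0) return(NULL)
  if (is.null(root_ss)) root_ss <- parent_ss
  min_leaf <- max(1L, as.integer(ceiling(control$min_leaf_fraction *
                                           n_learning)))
  if (is.data.frame(x)) x <- as.matrix(x)
  best <- NULL
  i <- seq_len(n - 1L)
  for (v in allowed) {
    xv <- x[, v]
    o <- order(xv, method = "radix")
    xs <- xv[o]
    cs <- cumsum(y[o])
    valid <- (xs[i] < xs[i + 1L]) & (i >= min_leaf) & ((n - i) >= min_leaf)
    if (!any(valid)) next
    sl <- cs[i]
    sr <- cs[n] - sl
    nl <- i
    nr <- n - i
    gain <- parent_ss - ((sl - sl^2 / nl) + (sr - sr^2 / nr))
    gain[!valid] <- -Inf
    bi <- which.max(gain)  # first maximum = lowest admissible threshold
    if (gain[bi] >= control$cp * root_ss &&
        (is.null(best) || gain[bi] > best$gain)) {
      best <- list(variable = v, threshold = (xs[bi] + xs[bi + 1L]) / 2,
                   gain = gain[bi])
    }
  }
  best
}

make_leaf <- function(y, n_learning, tie_label = "healthy") {
  n <- length(y)
  nc <- sum(y)
  label <- if (nc * 2 == n) tie_label else if (nc * 2 > n) "cancer" else "healthy"
  list(is_leaf = TRUE, label = label, n = n, n_cancer = nc,
       prop_cancer = if (n > 0) nc / n else NA_real_,
       coverage = n / n_learning)
}

grow_node <- function(x, y, control, allowed, n_learning, root_ss, depth) {
  if (depth >= control$max_depth || length(y) < control$minsplit) {
    return(make_leaf(y, n_learning))
  }
  sp <- best_split(x, y, control, allowed = allowed,
                   n_learning = n_learning, root_ss = root_ss)
  if (is.null(sp)) return(make_leaf(y, n_learning))
  left <- x[, sp$variable] <= sp$threshold
  node <- list(is_leaf = FALSE, variable = sp$variable,
               threshold = sp$threshold, threshold_ci = NULL,
               gain = sp$gain, n = length(y), n_cancer = sum(y),
               prop_cancer = mean(y))
  node$left <- grow_node(x[left, , drop = FALSE], y[left], control, allowed,
                         n_learning, root_ss, depth + 1L)
  node$right <- grow_node(x[!left, , drop = FALSE], y[!left], control,
                          allowed, n_learning, root_ss, depth + 1L)
  node
}

#' Grow a conventional decision tree
#'
#' Standard greedy recursive partitioning with [best_split()]:
#' deterministic given the input, no pruning. Subjects with `value <=
#' threshold` go left. Leaves are labelled by majority class, ties labelled
#' healthy (the conservative screening default). A single-class cohort
#' yields a single-leaf tree.
#'
#' @param cohort Cohort data frame (complete cases on `variables`).
#' @param variables Candidate predictor columns.
#' @param control A [split_control()].
#' @return Object of class `cfs_tree` with elements `root` (nested node
#'   list), `variables`, `control`, `n_learning`.
#' @export
grow_tree <- function(cohort, variables, control = split_control()) {
  x <- as.matrix(cohort[, variables, drop = FALSE])
  if (anyNA(x)) {
    stop_invalid("grow_tree: missing predictor values; run remove_missing()")
  }
  y <- as.numeric(is_cancer_label(cohort$group))
  n_learning <- length(y)
  root_ss <- node_ss(y)
  root <- grow_node(x, y, control, variables, n_learning,
                    if (root_ss > 0) root_ss else 1, 0L)
  structure(list(root = root, variables = variables, control = control,
                 n_learning = n_learning),
            class = "cfs_tree")
}

#' Variable importance of a tree
#'
#' Importance of a variable is the total impurity decrease summed over the
#' internal nodes that split on it; variables never used score 0. No
#' surrogate-split credit is assigned (complete-case analysis upstream makes
#' surrogates unnecessary).
#'
#' @param tree A `cfs_tree` (or `cfs_global_tree`).
#' @return Named numeric vector over `tree$variables`.
#' @export
variable_importance <- function(tree) {
  imp <- stats::setNames(numeric(length(tree$variables)), tree$variables)
  walk <- function(node) {
    if (node$is_leaf) return(invisible())
    imp[node$variable] <<- imp[node$variable] + node$gain
    walk(node$left)
    walk(node$right)
  }
  walk(tree$root)
  imp
}

#' Variable-importance screen over matched resamples
#'
#' For each resample, draws an age-matched bootstrap sample of the cohort,
#' grows a conventional tree and records the per-variable importances,
#' returning the full distribution (one row per resample) for boxplot-style
#' inspection. Age and sex enter as candidate variables by default so their
#' near-zero importance after matching can be verified.
#'
#' @param cohort Cohort data frame (complete cases on the markers).
#' @param variables Marker candidates (default [tree_markers()]).
#' @param scheme [age_scheme()] for the matched draw.
#' @param n_resamples Number of resampled trees (default 500).
#' @param control [split_control()].
#' @param seed RNG seed.
#' @param include_demographics Add `age` and `sex_female` to the candidates.
#' @return Matrix `n_resamples x variables` of importances.
#' @export
importance_over_resamples <- function(cohort, variables = tree_markers(),
                                      scheme = crc_age_scheme(),
                                      n_resamples = 500,
                                      control = split_control(),
                                      seed = NULL,
                                      include_demographics = TRUE) {
  cohort <- remove_missing(cohort, variables)$cohort
  if (include_demographics) {
    cohort$sex_female <- as.numeric(cohort$sex %in% "F")
    cohort$age_years <- as.numeric(cohort$age)
    variables <- c(variables, "age_years", "sex_female")
  }
  cat <- assign_age_categories(cohort, scheme)
  cancer <- is_cancer_label(cohort$group)
  pools <- matched_pools(cat, cancer)
  with_seed(seed, {
    out <- matrix(NA_real_, n_resamples, length(variables),
                  dimnames = list(NULL, variables))
    for (b in seq_len(n_resamples)) {
      idx <- matched_draw(pools, replace = TRUE)
      tree <- grow_tree(cohort[idx, , drop = FALSE], variables, control)
      out[b, ] <- variable_importance(tree)
    }
    out
  })
}
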