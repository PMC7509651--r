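# Tree traversal, rendering and serialisation shared by conventional and
# global trees.

#' Predict class labels from a tree
#'
#' Routes each subject down the tree (`value <= threshold` goes left) and
#' returns the leaf label. A subject with a missing value anywhere on its
#' root-to-leaf path is unclassifiable and gets `NA` (complete-case
#' preparation upstream makes this rare).
#'
#' @param object A `cfs_tree` or `cfs_global_tree`.
#' @param newdata Cohort data frame carrying the tree's variables.
#' @param ... Unused.
#' @return Character vector of `"cancer"` / `"healthy"` labels, `NA` where
#'   unclassifiable.
#' @export
predict.cfs_tree <- function(object, newdata, ...) {
  missing_vars <- setdiff(tree_variables_used(object), names(newdata))
  if (length(missing_vars)) {
    stop_invalid("predict: newdata lacks variable(s): ",
                 paste(missing_vars, collapse = ", "))
  }
  out <- rep(NA_character_, nrow(newdata))
  route <- function(node, idx) {
    if (length(idx) == 0) return(invisible())
    if (node$is_leaf) {
      out[idx] <<- node$label
      return(invisible())
    }
    v <- newdata[[node$variable]][idx]
    na <- is.na(v)
    route(node$left, idx[!na & v <= node$threshold])
    route(node$right, idx[!na & v > node$threshold])
  }
  route(object$root, seq_len(nrow(newdata)))
  out
}

# Variables actually used by internal nodes (may be fewer than candidates).
tree_variables_used <- function(tree) {
  used <- character(0)
  walk <- function(node) {
    if (node$is_leaf) return(invisible())
    used <<- union(used, node$variable)
    walk(node$left)
    walk(node$right)
  }
  walk(tree$root)
  used
}

tree_depth <- function(tree) {
  d <- function(node) {
    if (node$is_leaf) 0L else 1L + max(d(node$left), d(node$right))
  }
  d(tree$root)
}

n_leaves <- function(tree) {
  f <- function(node) if (node$is_leaf) 1L else f(node$left) + f(node$right)
  f(tree$root)
}

#' Render a tree as an indented text diagram
#'
#' One line per node: internal nodes show the split condition (with the
#' threshold confidence interval when available) and the cancer proportion;
#' leaves show the label, class proportions and the fraction of the
#' learning set they cover. The YES branch is the one satisfying the
#' condition.
#'
#' @param x A `cfs_tree`.
#' @param ... Unused.
#' @return Character vector of lines, invisibly printed by
#'   [print.cfs_tree()].
#' @export
format.cfs_tree <- function(x, ...) {
  lines <- character(0)
  emit <- function(node, prefix, branch) {
    if (node$is_leaf) {
      lines <<- c(lines, sprintf(
        "%s%s%s (n=%d, %.0f%% cancer, %.0f%% of learning set)",
        prefix, branch, toupper(node$label), node$n,
        100 * node$prop_cancer, 100 * node$coverage))
      return(invisible())
    }
    ci <- if (!is.null(node$threshold_ci)) {
      sprintf(" [%.4g, %.4g]", node$threshold_ci[1], node$threshold_ci[2])
    } else ""
    lines <<- c(lines, sprintf(
      "%s%s%s <= %.6g%s ? (n=%d, %.0f%% cancer)",
      prefix, branch, node$variable, node$threshold, ci, node$n,
      100 * node$prop_cancer))
    emit(node$left, paste0(prefix, "  "), "YES: ")
    emit(node$right, paste0(prefix, "  "), "NO:  ")
  }
  emit(x$root, "", "")
  lines
}

#' @export
print.cfs_tree <- function(x, ...) {
  kind <- if (inherits(x, "cfs_global_tree")) "stabilised global" else
    "recursive-partitioning"
  cat(sprintf("%s decision tree: %d leaves, depth %d, learning n = %d\n",
              kind, n_leaves(x), tree_depth(x), x$n_learning))
  cat(format(x), sep = "\n")
  invisible(x)
}

tree_as_list <- function(tree) {
  strip <- function(node) {
    if (node$is_leaf) {
      list(type = "leaf", label = node$label, n = node$n,
           n_cancer = node$n_cancer, prop_cancer = node$prop_cancer,
           coverage = node$coverage)
    } else {
      list(type = "internal", variable = node$variable,
           threshold = node$threshold,
           threshold_ci = node$threshold_ci,
           gain = node$gain, n = node$n, n_cancer = node$n_cancer,
           prop_cancer = node$prop_cancer,
           left = strip(node$left), right = strip(node$right))
    }
  }
  list(kind = if (inherits(tree, "cfs_global_tree")) "global" else
         "conventional",
       n_learning = tree$n_learning, variables = tree$variables,
       seed = tree$seed, root = strip(tree$root))
}

#' Serialise a tree as JSON
#'
#' Writes the nested node structure (variable, threshold, threshold CI,
#' class proportions, leaf coverage) plus learning-set metadata.
#'
#' @param tree A `cfs_tree`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  jsonlite::write_json(tree_as_list(tree), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
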