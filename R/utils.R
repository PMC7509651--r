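# Internal helpers shared across modules: seeded evaluation, seed derivation,
# and small input checks.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL evaluates without touching the RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(expr)
}

# Derive a reproducible sub-seed from a base seed and a stage key so that
# changing one stage's number of resamples does not perturb another stage's
# draws. Kept below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(seed, key) {
  if (is.null(seed)) return(NULL)
  m <- 2147483647
  h <- sum(utf8ToInt(as.character(key)) * seq_along(utf8ToInt(as.character(key))))
  as.integer(((abs(seed) %% m) * 48271 + h) %% m)
}

#' Marker name sets
#'
#' `measured_markers()` names the four concentrations read from Q-PCR
#' (copies/mL); `tree_markers()` adds the derived MNR, giving the five
#' panel variables used for ROC screening and tree building.
#'
#' @return Character vector of column names.
#' @export
measured_markers <- function() c("ref_a67", "ref_a145", "ref_a320", "ref_m67")

#' @rdname measured_markers
#' @export
tree_markers <- function() c("ref_a67", "ref_a145", "ref_a320", "ref_m67", "mnr")

is_cancer_label <- function(group) {
  !(as.character(group) %in% c("healthy", "Healthy", "control"))
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_invalid(sprintf("'%s' must be finite numeric", name))
  }
  if (positive && any(x <= 0)) stop_invalid(sprintf("'%s' must be > 0", name))
  if (nonneg && any(x < 0)) stop_invalid(sprintf("'%s' must be >= 0", name))
  invisible(x)
}
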