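# Empirical (basic) bootstrap confidence intervals: percentiles of the
# resampled-statistic deviations added back to the point estimate.

#' Empirical (basic) bootstrap confidence interval
#'
#' Computes the statistic on the full data, resamples the data with
#' replacement `n_resamples` times, forms the deviations
#' `d_b = theta*_b - theta_hat`, and reports
#' `[theta_hat + q_{(1-level)/2}(d), theta_hat + q_{(1+level)/2}(d)]`.
#' Resamples on which the statistic fails (e.g. a single-class draw) are
#' redrawn, up to `max_retries` consecutive failures per slot; failures are
#' counted in the result.
#'
#' @param statistic Function of a dataset returning one number.
#' @param data Numeric vector or data frame; resampled by element or row.
#' @param n_resamples Number of bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed.
#' @param max_retries Maximum consecutive redraws per failed resample.
#' @return Object of class `bootstrap_ci`: `point`, `lower`, `upper`,
#'   `n_resamples`, `level`, `method = "basic"`, `n_failed`.
#' @export
empirical_bootstrap_ci <- function(statistic, data, n_resamples = 2000,
                                   level = 0.95, seed = NULL,
                                   max_retries = 100) {
  stopifnot(is.function(statistic), n_resamples >= 1, level > 0, level < 1)
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n == 0) stop_invalid("empirical_bootstrap_ci: data is empty")
  take <- if (is.data.frame(data)) {
    function(i) data[i, , drop = FALSE]
  } else {
    function(i) data[i]
  }
  point <- statistic(data)
  with_seed(seed, {
    vals <- numeric(n_resamples)
    n_failed <- 0L
    for (b in seq_len(n_resamples)) {
      ok <- FALSE
      for (r in seq_len(max_retries)) {
        v <- tryCatch(statistic(take(sample.int(n, n, replace = TRUE))),
                      error = function(e) NULL)
        if (!is.null(v) && is.finite(v)) {
          vals[b] <- v
          ok <- TRUE
          break
        }
        n_failed <- n_failed + 1L
      }
      if (!ok) {
        stop_invalid("empirical_bootstrap_ci: statistic failed on ",
                     max_retries, " consecutive resamples")
      }
    }
    d <- vals - point
    qs <- stats::quantile(d, c((1 - level) / 2, (1 + level) / 2),
                          names = FALSE, type = 7)
    structure(
      list(point = point, lower = point + qs[1], upper = point + qs[2],
           n_resamples = n_resamples, level = level, method = "basic",
           n_failed = n_failed),
      class = "bootstrap_ci"
    )
  })
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("%.6g  [%.6g, %.6g]  (%d%% basic bootstrap, %d resamples)\n",
              x$point, x$lower, x$upper, round(100 * x$level),
              x$n_resamples))
  invisible(x)
}

# Basic-bootstrap CI from an already-computed vector of replicate statistics
# (internal; used where the resampling scheme is not plain row resampling,
# e.g. matched bootstrap replicates or node-threshold distributions).
basic_ci_from_replicates <- function(point, replicates, level = 0.95) {
  replicates <- replicates[is.finite(replicates)]
  if (length(replicates) == 0) {
    return(structure(list(point = point, lower = NA_real_, upper = NA_real_,
                          n_resamples = 0L, level = level, method = "basic",
                          n_failed = 0L),
                     class = "bootstrap_ci"))
  }
  d <- replicates - point
  qs <- stats::quantile(d, c((1 - level) / 2, (1 + level) / 2),
                        names = FALSE, type = 7)
  structure(
    list(point = point, lower = point + qs[1], upper = point + qs[2],
         n_resamples = length(replicates), level = level, method = "basic",
         n_failed = 0L),
    class = "bootstrap_ci"
  )
}
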