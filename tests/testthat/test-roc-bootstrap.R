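# ROC construction, AUC, closest-corner thresholds, and the empirical
# bootstrap.

test_that("AUC matches exhaustive pair counting on canonical fixtures", {
  r <- roc_curve(c(10, 20, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  r <- roc_curve(c(1, 2, 3, 1, 2, 3), rep(c(TRUE, FALSE), each = 3),
                 orientation = "higher")
  expect_equal(r$auc, 0.5)
  r <- roc_curve(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE),
                 orientation = "higher")
  expect_equal(r$auc, 0.75)
  expect_error(roc_curve(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC equals the pairwise oracle to machine precision (with ties)", {
  set.seed(101)
  for (i in 1:20) {
    n1 <- sample(10:50, 1)
    n2 <- sample(10:50, 1)
    v <- c(round(rnorm(n1, 0.5), 1), round(rnorm(n2), 1))  # rounding -> ties
    cancer <- c(rep(TRUE, n1), rep(FALSE, n2))
    r <- roc_curve(v, cancer, orientation = "higher")
    expect_equal(r$auc, auc_pairwise(v, cancer), tolerance = 1e-12)
  }
})

test_that("AUC is antisymmetric under sign flip for tie-free data", {
  set.seed(33)
  v <- rnorm(60)
  cancer <- rep(c(TRUE, FALSE), 30)
  a <- roc_curve(v, cancer, orientation = "higher")$auc
  b <- roc_curve(-v, cancer, orientation = "higher")$auc
  expect_equal(a + b, 1)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(9)
  v <- rnorm(80)
  cancer <- rep(c(TRUE, FALSE), 40)
  ours <- roc_curve(v, cancer, orientation = "higher")$auc
  ref <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(response = cancer, predictor = v, direction = "<",
              quiet = TRUE)
  )))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("closest-corner threshold matches brute force and is equivariant", {
  r <- roc_curve(c(10, 20, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(optimal_threshold(r), 6)  # midpoint of 2 and 10, distance 0

  set.seed(7)
  for (i in 1:15) {
    n <- sample(20:150, 1)
    v <- round(rnorm(n), 1)
    cancer <- runif(n) < 0.5
    if (!any(cancer) || all(cancer)) next
    r <- roc_curve(v, cancer, orientation = "higher")
    expect_identical(optimal_threshold(r),
                     brute_optimal_threshold(v, cancer, "higher"))
  }
  # monotone shift moves the threshold by the same constant
  v <- c(3, 5, 8, 1, 4, 2)
  cancer <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  t0 <- optimal_threshold(roc_curve(v, cancer, orientation = "higher"))
  t1 <- optimal_threshold(roc_curve(v + 10, cancer, orientation = "higher"))
  expect_equal(t1, t0 + 10)
  # degenerate all-identical input yields the single finite curve point
  rd <- roc_curve(rep(2, 6), cancer, orientation = "higher")
  expect_equal(length(rd$thresholds), 2)  # -Inf, Inf sentinels only
  expect_true(is.finite(rd$auc))
})

test_that("auto orientation flips markers that are lower in cancer", {
  v <- c(1, 2, 10, 20)
  cancer <- c(TRUE, TRUE, FALSE, FALSE)
  r <- roc_curve(v, cancer, orientation = "auto")
  expect_equal(r$orientation, "lower")
  expect_equal(r$auc, 1)
  expect_equal(roc_auc(r), 1)
  # monotone curve shape: Se non-increasing along the threshold grid
  set.seed(2)
  v <- rnorm(50)
  cancer <- runif(50) < 0.4
  r <- roc_curve(v, cancer, orientation = "higher")
  expect_true(all(diff(r$sensitivity) <= 0))
  expect_true(all(diff(r$specificity) >= 0))
})

test_that("basic bootstrap CI follows the difference-percentile definition", {
  ci <- empirical_bootstrap_ci(mean, rep(3, 20), n_resamples = 100, seed = 1)
  expect_equal(ci$point, 3)
  expect_equal(ci$lower, 3)
  expect_equal(ci$upper, 3)

  set.seed(5)
  x <- rnorm(50)
  a <- empirical_bootstrap_ci(mean, x, n_resamples = 200, seed = 9)
  b <- empirical_bootstrap_ci(mean, x, n_resamples = 200, seed = 9)
  expect_identical(a, b)
  expect_lte(a$lower, a$upper)

  # single resample: degenerate but well-defined
  d <- empirical_bootstrap_ci(mean, x, n_resamples = 1, seed = 2)
  expect_equal(d$lower, d$upper)
})

test_that("bootstrap CI width shrinks with sample size", {
  set.seed(77)
  widths <- sapply(c(100, 400), function(n) {
    median(replicate(30, {
      x <- rnorm(n)
      ci <- empirical_bootstrap_ci(mean, x, n_resamples = 200)
      ci$upper - ci$lower
    }))
  })
  expect_lt(widths[2], widths[1])
})

test_that("marker evaluation emits a screening-table row with coherent CIs", {
  co <- generate_cohort(shifted_config(120, 120, zero_shift), seed = 15)
  row <- evaluate_marker(co, "ref_a67", n_resamples = 200, seed = 3)
  # null cohort: the AUC interval straddles chance
  expect_lte(row$auc_lo, 0.55)
  expect_gte(row$auc_hi, 0.45)
  expect_true(all(c("threshold", "se", "sp", "auc") %in% names(row)))

  # age-matched evaluation re-draws matched samples inside each replicate
  co2 <- generate_cohort(default_crc_config(150, 150), seed = 16)
  co2 <- remove_missing(co2, "ref_a67")$cohort
  row2 <- evaluate_marker(co2, "ref_a67", age_matched = TRUE,
                          n_resamples = 100, seed = 4)
  expect_equal(row2$n_cancer, row2$n_healthy)
  expect_gt(row2$auc, 0.5)
  # single resample runs without error
  row3 <- evaluate_marker(co2, "mnr", n_resamples = 1, seed = 5)
  expect_true(is.finite(row3$auc_lo))
})
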