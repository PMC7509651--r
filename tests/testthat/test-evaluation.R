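# Tree application and performance reporting.

# hand-built depth-2 tree: x <= 5 ? (z <= 1 ? healthy : cancer) : cancer
hand_tree <- function() {
  leaf <- function(label, n, nc) {
    list(is_leaf = TRUE, label = label, n = n, n_cancer = nc,
         prop_cancer = nc / n, coverage = n / 8)
  }
  root <- list(is_leaf = FALSE, variable = "x", threshold = 5,
               threshold_ci = NULL, gain = 1, n = 8, n_cancer = 4,
               prop_cancer = 0.5,
               left = list(is_leaf = FALSE, variable = "z", threshold = 1,
                           threshold_ci = NULL, gain = 0.5, n = 4,
                           n_cancer = 1, prop_cancer = 0.25,
                           left = leaf("healthy", 3, 0),
                           right = leaf("cancer", 1, 1)),
               right = leaf("cancer", 4, 3))
  structure(list(root = root, variables = c("x", "z"),
                 control = split_control(), n_learning = 8),
            class = "cfs_tree")
}

test_that("prediction routes subjects exactly as the node conditions say", {
  tr <- hand_tree()
  nd <- data.frame(x = c(4, 4, 6, 5), z = c(0, 2, -5, 1))
  expect_equal(predict(tr, nd), c("healthy", "cancer", "cancer", "healthy"))
  # missing value on the path -> unclassifiable
  nd2 <- data.frame(x = c(NA, 6), z = c(0, NA))
  expect_equal(predict(tr, nd2), c(NA, "cancer"))
  expect_error(predict(tr, data.frame(x = 1)), "lacks variable")

  leaf_only <- structure(
    list(root = list(is_leaf = TRUE, label = "healthy", n = 5, n_cancer = 0,
                     prop_cancer = 0, coverage = 1),
         variables = character(0), control = split_control(),
         n_learning = 5),
    class = "cfs_tree"
  )
  expect_equal(predict(leaf_only, nd), rep("healthy", 4))
})

test_that("performance reproduces the confusion-matrix definitions", {
  # depth-1 tree x <= 0.5 -> healthy; craft TP=72 FN=28 TN=87 FP=13
  co <- toy_cohort(c(rep(1, 72), rep(0, 28), rep(0, 87), rep(1, 13)),
                   c(rep(TRUE, 100), rep(FALSE, 100)))
  tr <- grow_tree(toy_cohort(c(0, 0, 1, 1), c(FALSE, FALSE, TRUE, TRUE)),
                  "x", loose_control())
  rep <- performance(tr, co, n_resamples = 200, seed = 1)
  expect_equal(c(rep$tp, rep$fn, rep$tn, rep$fp), c(72, 28, 87, 13))
  expect_equal(rep$se, 0.72)
  expect_equal(rep$sp, 0.87)
  expect_true(all(c(rep$se_lo, rep$se_hi, rep$sp_lo, rep$sp_hi) >= 0))
  expect_true(all(c(rep$se_lo, rep$se_hi, rep$sp_lo, rep$sp_hi) <= 1))

  # perfect classifier: degenerate unit CIs
  co_perf <- toy_cohort(c(rep(0, 20), rep(1, 20)),
                        c(rep(FALSE, 20), rep(TRUE, 20)))
  rep2 <- performance(tr, co_perf, n_resamples = 100, seed = 2)
  expect_equal(c(rep2$se, rep2$sp, rep2$se_lo, rep2$se_hi,
                 rep2$sp_lo, rep2$sp_hi), rep(1, 6))

  # constant-healthy classifier
  always_h <- grow_tree(co_perf[co_perf$group == "healthy", ], "x",
                        loose_control())
  rep3 <- performance(always_h, co_perf, n_resamples = 50, seed = 3)
  expect_equal(rep3$se, 0)
  expect_equal(rep3$sp, 1)

  # single-class evaluation set: Se computed, Sp reported NA
  rep4 <- performance(tr, co_perf[co_perf$group == "crc", ],
                      n_resamples = 50, seed = 4)
  expect_true(is.na(rep4$sp))
  expect_equal(rep4$se, 1)
})

test_that("train/test split is a disjoint age-matched partition", {
  co <- generate_cohort(default_crc_config(250, 150), seed = 12)
  co <- remove_missing(co, tree_markers())$cohort
  sp <- split_train_test(co, seed = 3)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(co))
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  cat_train <- assign_age_categories(sp$train, crc_age_scheme())
  tab <- table(cat_train, sp$train$group)
  expect_true(all(tab[, "crc"] == tab[, "healthy"]))
  sp2 <- split_train_test(co, seed = 3)
  expect_identical(sp$train$subject_id, sp2$train$subject_id)
})

test_that("subgroup and cross-cohort evaluation honour their contracts", {
  co <- generate_cohort(default_crc_config(200, 200), seed = 23)
  co <- remove_missing(co, tree_markers())$cohort
  tr <- grow_tree(co, tree_markers())
  all_stage <- performance(tr, co, n_resamples = 100, seed = 1)
  sub <- subgroup_performance(tr, co, filter = unique(na.omit(co$stage)),
                              n_resamples = 100, seed = 1)
  expect_equal(sub$se, all_stage$se)
  expect_error(subgroup_performance(tr, co, filter = "XX",
                                    set_name = "absent"), "absent")

  same <- cross_cohort_apply(tr, co, n_resamples = 100, seed = 1)
  expect_equal(same$se, all_stage$se)
  expect_equal(same$sp, all_stage$sp)
  expect_true(same$cross_cohort)
  expect_error(cross_cohort_apply(tr, co[, setdiff(names(co), "mnr")]),
               "lacks")

  # a small other-cancers set: tally of cancer calls is well-defined
  other <- generate_cohort(default_crc_config(23, 0), seed = 31)
  other$group <- "other"
  other <- remove_missing(other, tree_markers())$cohort
  calls <- predict(tr, other)
  expect_true(sum(calls == "cancer") >= 0)
  expect_length(calls, nrow(other))
})

test_that("early stages are harder to detect under a graded effect", {
  cfg <- default_crc_config(n_cancer = 300, n_healthy = 200)
  cfg$stage_shift_frac <- c("0" = 0.5, "I" = 0.5, "II" = 0.5,
                            "III" = 1, "IV" = 1.4)
  wins <- 0
  for (s in 1:5) {
    co <- generate_cohort(cfg, seed = 400 + s)
    co <- remove_missing(co, tree_markers())$cohort
    tr <- grow_tree(co, tree_markers())
    se_all <- performance(tr, co, n_resamples = 1, seed = 1)$se
    se_early <- subgroup_performance(tr, co, filter = c("0", "I", "II"),
                                     n_resamples = 1, seed = 1)$se
    if (se_early <= se_all) wins <- wins + 1
  }
  expect_gte(wins, 4)
})

test_that("stability comparison returns the paired dispersion summary", {
  co <- toy_cohort(c(rnorm(60, 0), rnorm(60, 8)),
                   rep(c(FALSE, TRUE), each = 60),
                   age = rep(c(45L, 55L), 60))
  res <- compare_stability(co, n_splits = 3, candidates = "x",
                           control = loose_control(max_depth = 2),
                           n_trees = 20, n_thresh = 30, ci_resamples = 50,
                           seed = 8)
  expect_equal(nrow(res$results), 6)
  expect_equal(res$summary$method, c("conventional", "iterative"))
  # deterministic separable data: both methods are stable
  expect_equal(res$summary$sd_se, c(0, 0), tolerance = 1e-9)

  res1 <- compare_stability(co, n_splits = 1, candidates = "x",
                            control = loose_control(max_depth = 2),
                            n_trees = 10, n_thresh = 20, ci_resamples = 20,
                            seed = 9)
  expect_true(all(is.na(res1$summary$sd_se)))
})
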