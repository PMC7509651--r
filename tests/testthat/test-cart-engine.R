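# The recursive-partitioning engine: impurity, split search, tree growth,
# importance.

test_that("impurity is n * p * (1 - p) in counts form", {
  expect_equal(impurity(c(10, 0)), 0)
  expect_equal(impurity(c(0, 7)), 0)
  expect_equal(impurity(c(5, 5)), 2.5)
  expect_equal(impurity(c(0, 0)), 0)
  # merging two pure opposite nodes of size 5 creates 2.5 of information
  expect_equal(impurity(c(5, 5)) - impurity(c(5, 0)) - impurity(c(0, 5)),
               2.5)
})

test_that("best_split finds the separating midpoint and respects controls", {
  x <- cbind(v = c(1, 2, 10, 20))
  y <- c(0, 0, 1, 1)
  sp <- best_split(x, y, loose_control())
  expect_equal(sp$variable, "v")
  expect_equal(sp$threshold, 6)
  expect_equal(sp$gain, 1)  # the full node impurity

  expect_null(best_split(x, c(1, 1, 1, 1), loose_control()))  # pure node
  expect_null(best_split(x, y, split_control(minsplit = 20)))  # too small
  # min-leaf rule blocks any admissible split in a 4-subject node when the
  # learning set is large
  expect_null(best_split(x, y, split_control(minsplit = 2,
                                             min_leaf_fraction = 0.1),
                         n_learning = 100))
})

test_that("best_split agrees with the exhaustive oracle on random instances", {
  set.seed(55)
  for (i in 1:25) {
    n <- sample(10:60, 1)
    p <- sample(1:5, 1)
    x <- matrix(round(rnorm(n * p), 1), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    y <- as.numeric(runif(n) < 0.5)
    ctrl <- split_control(minsplit = 5, min_leaf_fraction = 0.1, cp = 0.01)
    got <- best_split(x, y, ctrl)
    parent_ss <- sum((y - mean(y))^2)
    want <- brute_best_split(x, y, minsplit = 5,
                             min_leaf = ceiling(0.1 * n),
                             cp_abs = 0.01 * parent_ss)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$variable, want$variable)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$gain, want$gain, tolerance = 1e-12)
    }
  }
})

test_that("the root split matches rpart's anova split on a clean instance", {
  skip_if_not_installed("rpart")
  set.seed(6)
  df <- data.frame(signal = c(rnorm(40, 2), rnorm(40, 0)),
                   noise = rnorm(80),
                   y = rep(c(1, 0), each = 40))
  fit <- rpart::rpart(y ~ signal + noise, data = df, method = "anova",
                      control = rpart::rpart.control(minsplit = 20,
                                                     cp = 0.01,
                                                     maxdepth = 1,
                                                     maxsurrogate = 0,
                                                     maxcompete = 0))
  sp <- best_split(as.matrix(df[, c("signal", "noise")]), df$y,
                   split_control(minsplit = 20, min_leaf_fraction = 0,
                                 cp = 0.01))
  expect_equal(sp$variable, as.character(fit$frame$var[1]))
  expect_equal(sp$threshold, unname(fit$splits[1, "index"]))
})

test_that("grow_tree separates separable data and is deterministic", {
  co <- toy_cohort(c(1, 2, 3, 10, 20, 30),
                   c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  tr <- grow_tree(co, "x", loose_control())
  expect_equal(tree_depth_of(tr), 1)
  expect_equal(predict(tr, co), ifelse(co$group == "crc", "cancer",
                                       "healthy"))
  expect_identical(grow_tree(co, "x", loose_control()), tr)
  # single-class cohort: single-leaf tree, no error
  leaf_tree <- grow_tree(co[co$group == "healthy", ], "x", loose_control())
  expect_true(leaf_tree$root$is_leaf)
  expect_equal(predict(leaf_tree, co), rep("healthy", 6))
})

test_that("training error never exceeds the majority-class baseline", {
  set.seed(14)
  for (i in 1:5) {
    n <- 120
    co <- toy_cohort(rnorm(n), runif(n) < 0.4)
    co$z <- rnorm(n)
    tr <- grow_tree(co, c("x", "z"), split_control())
    pred <- predict(tr, co)
    err <- mean((pred == "cancer") != (co$group == "crc"))
    expect_lte(err, min(mean(co$group == "crc"),
                        1 - mean(co$group == "crc")) + 1e-12)
  }
})

test_that("a null outcome stays within the structural depth bound", {
  set.seed(3)
  co <- toy_cohort(rnorm(300), rep(c(TRUE, FALSE), 150))
  co$z <- rnorm(300)
  tr <- grow_tree(co, c("x", "z"), split_control())  # cp = 0.01 default
  expect_lte(tree_depth_of(tr), tr$control$max_depth)
})

test_that("variable importance sums the split gains and conserves impurity", {
  co <- toy_cohort(c(1, 2, 3, 10, 20, 30),
                   c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  co$z <- c(5, 1, 4, 2, 6, 3)
  tr <- grow_tree(co, c("x", "z"), loose_control())
  imp <- variable_importance(tr)
  expect_equal(unname(imp["x"]), 1.5)  # root impurity of 3/3 split
  expect_equal(unname(imp["z"]), 0)

  leaf_tree <- grow_tree(co[co$group == "crc", ], c("x", "z"),
                         loose_control())
  expect_true(all(variable_importance(leaf_tree) == 0))

  # conservation: total importance = root impurity - sum of leaf impurities
  set.seed(20)
  co2 <- toy_cohort(rnorm(100), runif(100) < 0.5)
  co2$z <- co2$x + rnorm(100)
  tr2 <- grow_tree(co2, c("x", "z"), split_control(minsplit = 10, cp = 0))
  y <- as.numeric(co2$group == "crc")
  leaf_ss <- 0
  walk <- function(node, idx) {
    if (node$is_leaf) {
      leaf_ss <<- leaf_ss + impurity(c(sum(y[idx] == 0), sum(y[idx] == 1)))
      return(invisible())
    }
    l <- idx[co2[[node$variable]][idx] <= node$threshold]
    walk(node$left, l)
    walk(node$right, setdiff(idx, l))
  }
  walk(tr2$root, seq_len(100))
  expect_equal(sum(variable_importance(tr2)),
               impurity(c(sum(y == 0), sum(y == 1))) - leaf_ss,
               tolerance = 1e-9)
})

test_that("resampled importance ranks the strongest marker first and age near zero", {
  shift <- zero_shift
  shift["ref_a67"] <- 0.9
  shift["ref_a145"] <- 0.2
  cfg <- shifted_config(200, 200, shift, age_bias = TRUE)
  co <- generate_cohort(cfg, seed = 17)
  imp <- importance_over_resamples(co, n_resamples = 40, seed = 18)
  med <- apply(imp, 2, median)
  expect_equal(names(which.max(med)), "ref_a67")
  expect_lte(med[["age_years"]], 0.1 * med[["ref_a67"]])
  # single resample returns one tree's importances
  imp1 <- importance_over_resamples(co, n_resamples = 1, seed = 19)
  expect_equal(nrow(imp1), 1)
})
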