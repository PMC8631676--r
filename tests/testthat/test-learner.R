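test_that("entropy and information gain match hand calculations", {
  expect_equal(entropy(c(5, 0)), 0)
  expect_equal(entropy(c(1, 1)), 1)
  expect_equal(entropy(c(2, 6)), -(0.25 * log2(0.25) + 0.75 * log2(0.75)))
  expect_equal(entropy(c(2, 6)), 0.8113, tolerance = 1e-4)
  expect_error(entropy(c(0, 0)), "positive total")

  expect_equal(information_gain(c(4, 4), list(c(4, 0), c(0, 4))), 1)
  expect_equal(information_gain(c(4, 4), list(c(2, 2), c(2, 2))), 0)
  # H(2,6) minus half a bit for the maximally impure child
  expect_equal(information_gain(c(2, 6), list(c(2, 2), c(0, 4))),
               0.8113 - 0.5, tolerance = 1e-4)
  expect_error(information_gain(c(2, 6), list(c(2, 2), c(1, 4))),
               "partition")
})

test_that("best_threshold picks the argmax-gain midpoint", {
  r <- best_threshold(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$threshold, 2.5)
  expect_equal(r$gain, 1)

  expect_true(is.na(best_threshold(rep(2, 5), c(TRUE, FALSE, TRUE, FALSE, TRUE))$threshold))
  expect_equal(best_threshold(c(1, 2), c(TRUE, TRUE))$gain, 0)

  # ties are broken by the smallest threshold
  r2 <- best_threshold(c(1, 2, 3), c(TRUE, FALSE, TRUE))
  expect_equal(r2$threshold, 1.5)
})

test_that("the learner recovers a planted separable threshold", {
  d <- tibble::tibble(x = c(1, 2, 3, 4), y = c(FALSE, FALSE, TRUE, TRUE))
  tree <- train_tree(d, "y")
  td <- tidy(tree)
  expect_equal(glance(tree)$depth, 1)
  expect_equal(td$threshold[1], 2.5)
  expect_equal(td$feature[1], "x")

  # pure labels: a single leaf, no splits
  d2 <- tibble::tibble(x = rnorm(20), y = rep(TRUE, 20))
  expect_equal(glance(train_tree(d2, "y"))$n_nodes, 1)
})

test_that("identical data and parameters give an identical serialized tree", {
  cohort <- generate_cohort(cohort_config(n_patients = 200, seed = 21))
  feats <- recovery_features(cohort)
  t1 <- train_tree(cohort, "lvh_positive", features = feats)
  t2 <- train_tree(cohort, "lvh_positive", features = feats)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  save_tree(t1, p1); save_tree(t2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("the root split matches exhaustive search on small datasets", {
  withr::with_seed(55, {
    for (rep in 1:40) {
      n <- sample(4:12, 1)
      X <- tibble::tibble(f1 = rnorm(n), f2 = rnorm(n))
      y <- sample(c(TRUE, FALSE), n, replace = TRUE)
      oracle <- oracle_best_split(X, y)
      d <- dplyr::mutate(X, y = y)
      tree <- train_tree(d, "y", features = c("f1", "f2"),
                         params = learner_params(min_cases_per_leaf = 1,
                                                 prune = FALSE,
                                                 mdl_correction = FALSE))
      td <- tidy(tree)
      if (is.na(oracle$feature)) {
        expect_true(td$is_leaf[1])
      } else if (!td$is_leaf[1]) {
        expect_equal(td$feature[1], oracle$feature)
        expect_equal(td$threshold[1], oracle$threshold)
      } else {
        # learner may only decline when no split improves purity
        expect_lt(oracle$gain, 1e-9)
      }
    }
  })
})

test_that("the learner agrees with an independent recursive-partitioning fit
           on cleanly separable data", {
  withr::with_seed(66, {
    x <- runif(200, 0, 10)
    y <- x > 6.35
    d <- tibble::tibble(x = x, y = y)
    ours <- tidy(train_tree(d, "y"))
    rp <- rpart::rpart(y ~ x, data = d, method = "class",
                       control = rpart::rpart.control(minsplit = 4, cp = 0.01))
    rp_thr <- rp$splits[1, "index"]
    # both must place the cut inside the empty margin around the separator
    gap <- range(max(x[!y]), min(x[y]))
    expect_gt(ours$threshold[1], gap[1]); expect_lt(ours$threshold[1], gap[2])
    expect_gt(rp_thr, gap[1]); expect_lt(rp_thr, gap[2])
  })
})

test_that("pruning never grows a tree and is identity on a leaf", {
  lone <- as_lvh_tree(tree_leaf("negative", p = 0))
  d <- tibble::tibble(x = rnorm(10), y = rep(FALSE, 10))
  expect_equal(unclass(prune_tree(lone, d, "y")), unclass(lone))

  withr::with_seed(99, {
    for (rep in 1:10) {
      d <- tibble::tibble(x1 = rnorm(100), x2 = rnorm(100),
                          y = sample(c(TRUE, FALSE), 100, replace = TRUE))
      grown <- train_tree(d, "y", params = learner_params(
        prune = FALSE, mdl_correction = FALSE))
      pruned <- prune_tree(grown, d, "y")
      expect_lte(glance(pruned)$n_nodes, glance(grown)$n_nodes)
    }
  })
})

test_that("cost-weighted leaves obey the minimum-expected-cost rule", {
  # 3 positives vs 5 negatives: majority negative, but 2:1 FN cost ties and
  # 5:1 flips the call
  d <- tibble::tibble(x = rep(1, 8), y = c(rep(TRUE, 3), rep(FALSE, 5)))
  t_eq <- train_tree(d, "y", cost = cost_matrix(1, 1))
  expect_equal(tidy(t_eq)$class[1], "negative")
  expect_equal(tidy(t_eq)$p[1], 3 / 8)
  t_cost <- train_tree(d, "y", cost = cost_matrix(5, 1))
  expect_equal(tidy(t_cost)$class[1], "positive")
  expect_equal(tidy(t_cost)$p[1], 15 / 20)
  expect_error(cost_matrix(0, 0), "not both zero")
})

test_that("split_cohort produces seed-stable disjoint exhaustive splits", {
  s <- split_cohort(tibble::tibble(i = 1:439), 0.70, seed = 3)
  expect_equal(nrow(s$train), 307)
  expect_equal(nrow(s$test), 132)
  expect_length(intersect(s$train$i, s$test$i), 0)
  expect_setequal(c(s$train$i, s$test$i), 1:439)

  s2 <- split_cohort(tibble::tibble(i = 1:10), 0.5, seed = 8)
  expect_equal(c(nrow(s2$train), nrow(s2$test)), c(5, 5))

  expect_identical(split_cohort(tibble::tibble(i = 1:50), 0.7, seed = 4),
                   split_cohort(tibble::tibble(i = 1:50), 0.7, seed = 4))
  expect_error(split_cohort(tibble::tibble(i = 1), 0.5), "at least 2")
  expect_error(split_cohort(tibble::tibble(i = 1:10), 1.2), "\\(0, 1\\)")
})
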