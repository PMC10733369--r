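test_that("balanced accuracy is the unweighted mean of per-class recall", {
  expect_equal(balanced_accuracy(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)
  expect_equal(balanced_accuracy(c(0, 0, 0, 1), c(0, 0, 0, 0)), 0.5)
  # per-class recalls 2/3 and 1
  expect_equal(balanced_accuracy(c(0, 0, 0, 1), c(0, 0, 1, 1)), 5 / 6)
  expect_error(balanced_accuracy(integer(0), integer(0)), "empty")
})

test_that("ROC-AUC equals exhaustive concordant-pair counting", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9), positive = 1), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), c(0.5, 0.5, 0.5, 0.5), positive = 1), 0.5)
  # positives {0.9, 0.4} vs negatives {0.1, 0.8}: 3 of 4 pairs concordant
  expect_equal(roc_auc(c(0, 1, 0, 1), c(0.1, 0.9, 0.8, 0.4), positive = 1), 0.75)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3), positive = 1), "both classes")

  pair_oracle <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(15)
  for (i in 1:20) {
    y <- rbinom(12, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, 0.25), 12, replace = TRUE)  # plenty of ties
    expect_equal(roc_auc(y, s, positive = 1), pair_oracle(y, s))
  }
})

test_that("holdout split is class-proportional and seeded", {
  y <- rep(c("a", "b"), times = c(49, 50))
  sch <- cv_scheme(seed = 3)
  sp <- split_holdout(y, sch)
  expect_equal(length(sp$train), 66)
  expect_equal(length(sp$validation), 33)
  # proportions preserved within one subject per class
  expect_lte(abs(sum(y[sp$train] == "a") - 49 * 2 / 3), 1)
  expect_identical(sp, split_holdout(y, sch))
  expect_error(split_holdout(rep("a", 30), sch), "single-class")
})

test_that("tuning finds a separating forest and is deterministic", {
  set.seed(8)
  x <- data.frame(f1 = c(rnorm(30, 0), rnorm(30, 8)), f2 = rnorm(60))
  y <- rep(c("lo", "hi"), each = 30)
  sch <- cv_scheme(tuning_budget = 3, seed = 4)
  m1 <- tune_and_train(x, y, sch)
  expect_equal(balanced_accuracy(y, predict(m1, x)), 1)
  m2 <- tune_and_train(x, y, sch)
  expect_identical(m1$params, m2$params)

  one <- tune_and_train(x, y, cv_scheme(tuning_budget = 1, seed = 5))
  expect_true(all(c("num.trees", "mtry", "min.node.size") %in% names(one$params)))
})

test_that("permutation importance separates signal from noise features", {
  set.seed(9)
  n <- 120
  y <- factor(rep(c("a", "b"), each = n / 2))
  x <- as.data.frame(matrix(rnorm(n * 9), ncol = 9))
  x$signal <- as.numeric(y == "b")
  m <- tune_and_train(x, y, cv_scheme(tuning_budget = 0, seed = 6))
  imp <- permutation_importance(m, x, y, n_repeats = 20, seed = 7)
  expect_equal(nrow(imp), 10)
  best <- imp$feature[which.max(imp$mean_importance)]
  expect_equal(best, "signal")
  expect_gt(imp$mean_importance[imp$feature == "signal"], 0.2)
  noise <- imp$mean_importance[imp$feature != "signal"]
  expect_true(all(abs(noise) <= 0.05))
})

test_that("cABC partitions follow the curve geometry", {
  res <- cabc(c(w = 100, x = 1, y = 1, z = 1))
  expect_equal(res$A, "w")

  eq <- cabc(setNames(rep(3, 4), letters[1:4]))
  expect_equal(length(eq$A), 2)  # diagonal curve: closest point to (0,1) at 0.5

  v <- c(a = 5, b = 40, c = 1, d = 12, e = 0.2)
  r1 <- cabc(v)
  r2 <- cabc(v[c(3, 5, 1, 2, 4)])
  expect_setequal(r1$A, r2$A)
  expect_setequal(r1$C, r2$C)
  expect_setequal(c(r1$A, r1$B, r1$C), names(v))
  expect_equal(anyDuplicated(c(r1$A, r1$B, r1$C)), 0)
  expect_gte(min(v[r1$A]), max(v[r1$C]))

  expect_message(neg <- cabc(c(a = 4, b = -1, c = 2)), "clipping")
  expect_error(cabc(c(a = 0, b = 0)), "<= 0")
})

test_that("nested cross-validation separates signal from permuted control", {
  set.seed(10)
  n <- 90
  y <- factor(rep(c("a", "b"), length.out = n))
  x <- data.frame(f1 = rnorm(n, ifelse(y == "b", 6, 0)), f2 = rnorm(n))
  sch <- cv_scheme(outer_repeats = 2, inner_repeats = 5, tuning_budget = 1,
                   seed = 11)
  perf <- nested_cv_evaluate(x, y, scheme = sch)
  expect_equal(nrow(perf$runs), 10)
  expect_gte(perf$median[["balanced_accuracy"]], 0.95)
  expect_lte(perf$ci["balanced_accuracy", 1], perf$median[["balanced_accuracy"]])
  expect_gte(perf$ci["balanced_accuracy", 2], perf$median[["balanced_accuracy"]])

  ctrl <- nested_cv_evaluate(x, y, scheme = sch, permute_features = TRUE)
  expect_gte(perf$median[["balanced_accuracy"]],
             ctrl$median[["balanced_accuracy"]])
})

test_that("cluster membership attribution recovers the defining component", {
  set.seed(12)
  n <- 120
  cl <- rep(1:2, each = n / 2)
  x <- as.data.frame(matrix(rnorm(n * 4), ncol = 4))
  names(x) <- c("tjc", "sjc", "crp", "gh")
  x$crp <- x$crp + ifelse(cl == 2, 6, 0)  # cluster 2 defined by high crp
  sch <- cv_scheme(outer_repeats = 1, inner_repeats = 2, tuning_budget = 1,
                   seed = 13)
  res <- cluster_membership_importance(x, cl, sch, n_repeats = 10,
                                       evaluate = FALSE)
  expect_equal(names(res), c("cluster_1", "cluster_2"))
  for (entry in res) {
    expect_equal(nrow(entry$importance), 4)
    expect_equal(entry$top_feature, "crp")
  }
})
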