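test_that("normalized ranks span 0 to 1 with mid-rank ties", {
  expect_equal(unname(perFoldTargetRanks(c(a = 3, b = 2, c = 1))),
               c(0, 0.5, 1))
  expect_equal(unname(perFoldTargetRanks(c(a = 5))), 0)
  r <- perFoldTargetRanks(c(a = 9, b = 5, c = 5, d = 1))
  expect_equal(unname(r), c(0, 0.5, 0.5, 1))
  expect_error(perFoldTargetRanks(numeric()), "empty")
})

test_that("permutation importance isolates predictive features", {
  set.seed(3)
  n <- 600
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- X[, 1]
  dat <- data.frame(X, .y = y, check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                        num.trees = 200, num.threads = 1, seed = 1)
  pi1 <- permutationImportance(fit, X, y, nRepeats = 5, seed = 9)
  expect_gt(pi1$mean[["f1"]], 10 * max(abs(pi1$mean[c("f2", "f3", "f4")])))
  # deterministic given seed
  pi2 <- permutationImportance(fit, X, y, nRepeats = 5, seed = 9)
  expect_identical(pi1, pi2)
  # a constant feature is never used by a split: importance exactly 0
  X2 <- cbind(X, f5 = 0)
  dat2 <- data.frame(X2, .y = y, check.names = FALSE)
  fit2 <- ranger::ranger(dependent.variable.name = ".y", data = dat2,
                         num.trees = 100, num.threads = 1, seed = 2)
  pi3 <- permutationImportance(fit2, X2, y, nRepeats = 3, seed = 4)
  expect_equal(pi3$mean[["f5"]], 0)
  expect_error(permutationImportance(fit, X, y, nRepeats = 0), "at least 1")
})

rawFixture <- function(ranksByFoldTarget, nRepeats = 1) {
  lapply(ranksByFoldTarget, function(byTarget)
    lapply(byTarget, function(v)
      matrix(rep(v, each = nRepeats), nrow = nRepeats,
             dimnames = list(NULL, names(v)))))
}

test_that("rank aggregation follows the absent-ranked-last rule", {
  cfg <- rankingConfig(nRepeats = 1, targets = c("age", "bmi"))
  # feature first everywhere -> 0; last everywhere -> 1
  raw <- rawFixture(list(list(age = c(a = 0, b = 1), bmi = c(a = 0, b = 1))))
  rt <- aggregateRank(raw, cfg)
  agg <- rankAggregate(rt)
  expect_equal(agg$mean[agg$feature == "a"], 0)
  expect_equal(agg$mean[agg$feature == "b"], 1)

  # first (0) for one target, unselected for the other -> (0 + 1)/2
  raw2 <- rawFixture(list(list(age = c(a = 0, b = 1), bmi = c(b = 0))))
  rt2 <- aggregateRank(raw2, cfg)
  agg2 <- rankAggregate(rt2)
  expect_equal(agg2$mean[agg2$feature == "a"], 0.5)

  # all aggregates bounded in [0, 1]
  set.seed(2)
  rawR <- rawFixture(lapply(1:3, function(i)
    list(age = setNames(runif(4), letters[1:4]),
         bmi = setNames(runif(3), letters[2:4]))))
  aggR <- rankAggregate(aggregateRank(rawR, cfg))
  foldCols <- grep("^fold", names(aggR))
  expect_true(all(aggR[foldCols] >= 0 & aggR[foldCols] <= 1))
})

test_that("order is preserved and never-selected features are excluded", {
  cfg <- rankingConfig(nRepeats = 1, targets = c("age", "bmi"))
  # a beats b in every fold and target -> aggregate(a) < aggregate(b)
  raw <- rawFixture(list(
    list(age = c(a = 0, b = 0.5, c = 1), bmi = c(a = 0, b = 0.5, c = 1)),
    list(age = c(a = 0, b = 1), bmi = c(a = 0, b = 0.5, c = 1))))
  agg <- rankAggregate(aggregateRank(raw, cfg))
  expect_lt(agg$mean[agg$feature == "a"], agg$mean[agg$feature == "b"])
  expect_lt(agg$mean[agg$feature == "b"], agg$mean[agg$feature == "c"])
  # a feature selected for no target anywhere never appears
  expect_false("zz" %in% agg$feature)
})

test_that("cross-fold ranking surfaces the planted predictors", {
  fx <- cascadeFixture(500, 12, 0.7, 21, nRepeats = 5)
  tab <- fx$tab; folds <- fx$folds; trace <- fx$trace; rk <- fx$rk
  agg <- rankAggregate(rk)
  foldCols <- grep("^fold", names(agg))
  expect_true(all(agg[foldCols] >= 0 & agg[foldCols] <= 1))
  # the three signal carriers take the three best aggregate ranks
  expect_setequal(head(agg$feature, 3),
                  sprintf("original_synthetic_f%04d", 1:3))
  # per-target aggregation puts each dominant predictor first
  for (t in c("age", "bmi", "ff")) {
    rkt <- rankFeatures(tab, trace, folds,
                        rankingConfig(nRepeats = 5, targets = t), seed = 13)
    at <- rankAggregate(rkt)
    expect_identical(at$feature[1],
                     sprintf("original_synthetic_f%04d",
                             match(t, c("age", "bmi", "ff"))))
  }
})
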