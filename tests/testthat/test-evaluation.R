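test_that("the subgroup classifier is deterministic and separates toy data", {
  set.seed(1)
  X <- matrix(c(rnorm(50, -3), rnorm(50, 3)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- rep(c(1, 2), each = 50)
  fit <- trainClassifier(X, y, evalConfig(), seed = 4)
  pred <- predict(fit, data.frame(X, check.names = FALSE))$predictions
  expect_equal(mean(colnames(pred)[max.col(pred)] == as.character(y)), 1)
  fit2 <- trainClassifier(X, y, evalConfig(), seed = 4)
  pred2 <- predict(fit2, data.frame(X, check.names = FALSE))$predictions
  expect_identical(pred, pred2)
  expect_error(trainClassifier(X, rep(1, 100)), "at least 2 classes")
})

test_that("micro-averaged OvR AUC matches the worked example and oracles", {
  # one-hot scores: perfect ranking
  sc <- diag(3)[c(1, 2, 3, 1), ]; colnames(sc) <- c("a", "b", "c")
  expect_equal(ovrMicroRoc(sc, c("a", "b", "c", "a"))$auc, 1)

  # uniform scores: chance
  su <- matrix(1 / 3, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_equal(ovrMicroRoc(su, c("a", "b", "c", "a"))$auc, 0.5)

  # 4-sample binary worked set -> 0.75
  p1 <- c(0.9, 0.8, 0.4, 0.3)
  sb <- cbind(`1` = p1, `0` = 1 - p1)
  expect_equal(ovrMicroRoc(sb, c(1, 0, 1, 0))$auc, 0.75)

  # random multi-class scores vs brute-force threshold sweep (<= 20 samples)
  set.seed(9)
  for (i in 1:5) {
    n <- sample(6:20, 1)
    raw <- matrix(runif(n * 3), n, 3)
    sc <- raw / rowSums(raw); colnames(sc) <- c("a", "b", "c")
    lab <- sample(c("a", "b", "c"), n, TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(ovrMicroRoc(sc, lab)$auc, bruteMicroAUC(sc, lab),
                 tolerance = 1e-12)
  }
  expect_error(ovrMicroRoc(su, rep("a", 4)), "2 classes")
  expect_error(ovrMicroRoc(su * 2, c("a", "b", "a", "b")), "sum to 1")
})

test_that("micro-averaged AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(4)
  n <- 60
  p <- plogis(rnorm(n))
  sc <- cbind(pos = p, neg = 1 - p)
  lab <- ifelse(runif(n) < p, "pos", "neg")
  ours <- ovrMicroRoc(sc, lab)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(as.integer(lab == "pos"), p,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
  # multi-class flattening against pROC on the flattened pairs
  raw <- matrix(runif(90), 30, 3)
  sc3 <- raw / rowSums(raw); colnames(sc3) <- c("a", "b", "c")
  lab3 <- sample(c("a", "b", "c"), 30, TRUE)
  flatResp <- as.vector(vapply(colnames(sc3), function(cl)
    as.integer(lab3 == cl), integer(30)))
  ref3 <- as.numeric(pROC::auc(pROC::roc(flatResp, as.vector(sc3),
                                         quiet = TRUE, direction = "<")))
  expect_equal(ovrMicroRoc(sc3, lab3)$auc, ref3, tolerance = 1e-10)
})

test_that("chance accuracy is the uniform-guess rate", {
  expect_equal(chanceAccuracy(6), 16.67)
  expect_equal(chanceAccuracy(7), 14.29)
  expect_equal(chanceAccuracy(1), 100)
  expect_error(chanceAccuracy(0), "at least 1")
})

test_that("evaluation separates planted signal from permuted labels", {
  fx <- cascadeFixture(600, 10, 0.95, 31, perTarget = 2)
  tab <- fx$tab; folds <- fx$folds; trace <- fx$trace; rk <- fx$rk
  schemes <- defaultBinningSchemes(subjectMeta(tab)$ff)
  ev <- evalResults(evaluateSelection(tab, trace, rk, folds, schemes,
                                      evalConfig(trees = 200), seed = 5))
  expect_true(all(ev$aucMean >= 0 & ev$aucMean <= 1))
  expect_true(all(ev$accMean >= 0 & ev$accMean <= 1))
  val <- ev[ev$split == "validation" & ev$set == "full", ]
  expect_true(all(val$accMean > val$chance))
  # fold hygiene: validation ids never intersect training ids
  a <- foldAssignment(folds)
  for (fi in 1:5)
    expect_length(intersect(names(a)[a == fi], names(a)[a != fi]), 0)
})
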