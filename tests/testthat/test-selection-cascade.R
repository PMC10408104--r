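test_that("fold splits are uniform, disjoint and reproducible", {
  f <- makeFolds(paste0("s", 1:10), k = 5, seed = 1)
  expect_true(all(tabulate(foldAssignment(f), 5) == 2))
  expect_identical(foldAssignment(makeFolds(paste0("s", 1:10), 5, 1)),
                   foldAssignment(f))
  big <- makeFolds(paste0("s", 1:10672), 5, 3)
  expect_setequal(tabulate(foldAssignment(big), 5), c(2134, 2135))
  expect_error(makeFolds(paste0("s", 1:3), 5, 1), "at least k")
})

makeTinyTable <- function(values, meta) MuscleFeatureTable(values, meta)

test_that("stratum-averaged correlation averages with equal weights", {
  # single stratum (one sex present only would error; use equal data in both)
  set.seed(2)
  n <- 40
  meta <- data.frame(subject_id = sprintf("x%02d", 1:n),
                     sex = rep(c("male", "female"), each = n / 2),
                     age = runif(n, 20, 69))
  a <- rnorm(n); b <- rnorm(n)
  # feature g duplicated from f -> off-diagonal 1
  vals <- cbind(a, a, b)
  colnames(vals) <- instanceKey("m1", "left", "water",
    canonicalKey("original", "synthetic", c("f", "g", "h")))
  tab <- makeTinyTable(vals, meta)
  ac <- averagedCorrelation(tab)
  expect_equal(ac$corr["original_synthetic_f", "original_synthetic_g"], 1)

  # +1 in one sex, -1 in the other -> averaged 0
  s <- rnorm(n / 2)
  vals2 <- cbind(c(s, s), c(s, -s))
  colnames(vals2) <- instanceKey("m1", "left", "water",
    canonicalKey("original", "synthetic", c("p", "q")))
  tab2 <- makeTinyTable(vals2, meta)
  ac2 <- averagedCorrelation(tab2)
  expect_equal(ac2$corr["original_synthetic_p", "original_synthetic_q"], 0,
               tolerance = 1e-12)
})

test_that("cluster representatives follow priority and sub-category limits", {
  # all distances >= threshold: everyone is a representative
  canon <- canonicalKey("original", "glcm", c("a", "b", "c"))
  corr <- diag(3); dimnames(corr) <- list(canon, canon)
  cr <- clusterRepresentatives(corr)
  expect_setequal(cr$representatives, canon)

  # perfectly correlated variants: original wins over LoG and wavelet
  canon2 <- c(canonicalKey("wavelet-llh", "glcm", "x"),
              canonicalKey("original", "glcm", "x"),
              canonicalKey("log-sigma-1-0", "glcm", "x"))
  corr2 <- matrix(1, 3, 3, dimnames = list(canon2, canon2))
  cr2 <- clusterRepresentatives(corr2)
  expect_identical(cr2$representatives, "original_glcm_x")

  # perfect correlation across different sub-categories: both retained
  canon3 <- c(canonicalKey("original", "glcm", "x"),
              canonicalKey("original", "glrlm", "x"))
  corr3 <- matrix(1, 2, 2, dimnames = list(canon3, canon3))
  cr3 <- clusterRepresentatives(corr3)
  expect_setequal(cr3$representatives, canon3)

  # anti-correlated duplicates merge too (absolute correlation distance)
  canon4 <- canonicalKey("original", "glcm", c("a", "b"))
  corr4 <- matrix(c(1, -1, -1, 1), 2, dimnames = list(canon4, canon4))
  expect_length(clusterRepresentatives(corr4)$representatives, 1)

  # idempotence: clustering the representatives changes nothing
  set.seed(5)
  p <- 12
  canon5 <- canonicalKey("original", "glcm", sprintf("f%02d", 1:p))
  z <- matrix(rnorm(200 * 4), 200, 4)
  X <- z[, sample(1:4, p, TRUE)] + matrix(rnorm(200 * p, 0, 0.1), 200, p)
  corr5 <- cor(X); dimnames(corr5) <- list(canon5, canon5)
  r1 <- clusterRepresentatives(corr5)$representatives
  r2 <- clusterRepresentatives(corr5[r1, r1])$representatives
  expect_setequal(r1, r2)
})

test_that("left/right reproducibility filtering keeps only reliable features", {
  # right identical to left -> r = 1, kept
  tabHi <- generateFeatureTable(plantedTableSpec(
    nSubjects = 100, nFeatures = 2, lrReliability = 1, seed = 1))
  feats <- unique(featureKeys(tabHi)$canonical)
  ids <- subjectMeta(tabHi)$subject_id
  out <- lrReproducibilityFilter(tabHi, feats, ids)
  expect_setequal(out$kept, feats)
  expect_true(all(abs(out$r - 1) < 1e-12))

  # independent sides at n = 5000 -> discarded (|r| << 0.7)
  tabLo <- generateFeatureTable(plantedTableSpec(
    nSubjects = 5000, nFeatures = 2, lrReliability = 0, seed = 2))
  outLo <- lrReproducibilityFilter(tabLo,
    unique(featureKeys(tabLo)$canonical), subjectMeta(tabLo)$subject_id)
  expect_length(outLo$kept, 0)
  expect_true(all(abs(outLo$r) < 0.05))

  # constant side vector -> degenerate, discarded with reason
  n <- 50
  meta <- data.frame(subject_id = sprintf("c%02d", 1:n),
                     sex = rep(c("male", "female"), n / 2),
                     age = runif(n))
  vals <- cbind(rep(1, n), rnorm(n))
  colnames(vals) <- c(
    instanceKey("m1", "left", "water", "original_synthetic_f"),
    instanceKey("m1", "right", "water", "original_synthetic_f"))
  tabC <- MuscleFeatureTable(vals, meta)
  outC <- lrReproducibilityFilter(tabC, "original_synthetic_f",
                                  meta$subject_id)
  expect_length(outC$kept, 0)
  expect_match(outC$discarded$reason, "zero-variance")
})

test_that("VIF pruning removes collinear features in oracle order", {
  set.seed(4)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  # identical columns: one removed with infinite VIF
  Xdup <- cbind(a = x1, b = x1)
  out <- vifPrune(Xdup)
  expect_length(out$kept, 1)
  expect_true(is.infinite(out$removed$vif[1]))

  # orthogonal columns: all kept, VIF 1
  q <- qr.Q(qr(matrix(rnorm(n * 4), n)))
  Xor <- q; colnames(Xor) <- letters[1:4]
  outOr <- vifPrune(Xor)
  expect_setequal(outOr$kept, letters[1:4])
  expect_equal(unname(myotexture:::vifValues(Xor)), rep(1, 4),
               tolerance = 1e-4)

  # x3 = x1 + x2 + small noise: x3 has the max VIF, removed first
  x3 <- x1 + x2 + rnorm(n, 0, 0.05)
  X <- cbind(x1 = x1, x2 = x2, x3 = x3)
  v <- myotexture:::vifValues(X)
  expect_equal(unname(v), unname(bruteVIF(X)), tolerance = 1e-6)
  expect_equal(names(which.max(v)), "x3")
  outX <- vifPrune(X)
  expect_identical(outX$removed$feature[1], "x3")
  expect_setequal(outX$kept, c("x1", "x2"))
})

test_that("shadow selection confirms real predictors and rejects noise", {
  set.seed(6)
  n <- 1000
  X <- matrix(rnorm(n * 21), n, 21,
              dimnames = list(NULL, sprintf("f%02d", 1:21)))
  y <- X[, 7]  # y equals one feature exactly
  out <- shadowSelect(X, y, selectionConfig(), seed = 11)
  expect_true("f07" %in% out$selected)
  expect_lt(length(out$selected), 4)
  expect_error(shadowSelect(X[, 1, drop = FALSE], rep(1, n)), "constant")
  # determinism
  out2 <- shadowSelect(X, y, selectionConfig(), seed = 11)
  expect_identical(out$selected, out2$selected)
})

test_that("the cascade trace is monotone and recovers planted signal", {
  fx <- cascadeFixture(500, 12, 0.7, 21, nRepeats = 5)
  trace <- fx$trace
  for (fi in 1:5) {
    st <- trace@steps[[fi]]
    expect_true(all(st$reproducible %in% trace@representatives))
    expect_true(all(st$vifPruned %in% st$reproducible))
    for (t in c("age", "bmi", "ff"))
      expect_true(all(st$selected[[t]] %in% st$vifPruned))
  }
  # strong planted signals recovered in >= 4/5 folds for their target
  sig <- c(age = "original_synthetic_f0001", bmi = "original_synthetic_f0002",
           ff = "original_synthetic_f0003")
  for (t in names(sig)) {
    hits <- sum(vapply(trace@steps, function(s) sig[[t]] %in% s$selected[[t]],
                       TRUE))
    expect_gte(hits, 4)
  }
  sm <- cascadeSummary(trace)
  expect_true(all(diff(sm$mean[1:3]) <= 0))
})

test_that("a block of identical features yields a single representative", {
  tab <- generateFeatureTable(plantedTableSpec(
    nSubjects = 200, nFeatures = 10,
    clusterBlocks = list(list(size = 10, rho = 1)), seed = 5))
  ac <- averagedCorrelation(tab)
  cr <- clusterRepresentatives(ac$corr)
  expect_length(cr$representatives, 1)
})
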