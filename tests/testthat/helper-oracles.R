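# Independent oracles and small fixture builders used across the suite.

# Brute-force symmetric co-occurrence counting over the 13 unique 3-D
# directions (independent of the compiled path).
bruteGLCM <- function(img, mask, ng) {
  dims <- dim(img)
  dirs <- list()
  for (a in -1:1) for (b in -1:1) for (c in -1:1) {
    if (a == 0 && b == 0 && c == 0) next
    if (c > 0 || (c == 0 && b > 0) || (c == 0 && b == 0 && a > 0))
      dirs[[length(dirs) + 1L]] <- c(a, b, c)
  }
  P <- matrix(0, ng, ng)
  for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
    for (z in seq_len(dims[3])) {
      if (!mask[x, y, z]) next
      for (d in dirs) {
        xx <- x + d[1]; yy <- y + d[2]; zz <- z + d[3]
        if (xx < 1 || xx > dims[1] || yy < 1 || yy > dims[2] ||
            zz < 1 || zz > dims[3]) next
        if (!mask[xx, yy, zz]) next
        gi <- img[x, y, z]; gj <- img[xx, yy, zz]
        P[gi, gj] <- P[gi, gj] + 1
        P[gj, gi] <- P[gj, gi] + 1
      }
    }
  P
}

# Direct least-squares VIF oracle: VIF_j from summary.lm R^2
bruteVIF <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    df <- data.frame(y = X[, j], X[, -j, drop = FALSE])
    r2 <- summary(stats::lm(y ~ ., data = df))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
}

# Brute-force iterative VIF pruning using the oracle above
bruteVifPrune <- function(X, threshold = 10) {
  repeat {
    if (ncol(X) < 2) break
    v <- bruteVIF(X)
    if (max(v) <= threshold) break
    drop <- sort(colnames(X)[v == max(v)])[1]
    X <- X[, colnames(X) != drop, drop = FALSE]
  }
  colnames(X)
}

# Brute-force micro-averaged OvR AUC via exhaustive threshold sweep (binary
# problems use the positive-class column, matching the package convention)
bruteMicroAUC <- function(scores, labels) {
  if (ncol(scores) == 2L) {
    truth <- as.integer(as.character(labels) == colnames(scores)[1])
    s <- scores[, 1]
  } else {
    truth <- as.vector(vapply(colnames(scores), function(cl)
      as.integer(as.character(labels) == cl), integer(length(labels))))
    s <- as.vector(scores)
  }
  ths <- sort(unique(s))
  pts <- t(vapply(c(Inf, ths), function(th) {
    pred <- s >= th
    c(fpr = sum(pred & truth == 0) / sum(truth == 0),
      tpr = sum(pred & truth == 1) / sum(truth == 1))
  }, c(0, 0)))
  pts <- pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
  pts <- rbind(c(0, 0), pts, c(1, 1))
  sum(diff(pts[, 1]) * (head(pts[, 2], -1) + tail(pts[, 2], -1)) / 2)
}

# label volume with the given list of voxel-index blocks assigned to labels
makeLabelVolume <- function(dims, blocks, labels = seq_along(blocks),
                            map = NULL) {
  a <- array(0L, dims)
  for (i in seq_along(blocks)) a[blocks[[i]]] <- as.integer(labels[i])
  if (is.null(map))
    map <- data.frame(label = unique(as.integer(labels)),
                      muscle = paste0("m", unique(as.integer(labels))),
                      side = "left")
  LabelVolume(a, map, c(1, 1, 1))
}

# a ready feature table with planted target signals for cascade tests;
# perTarget = 2 plants a second, independent carrier per target (a strong
# combined signal for classifier validation)
plantedTableFixture <- function(n = 400, p = 12, effect = 0.7, seed = 42,
                                perTarget = 1) {
  sig <- if (perTarget == 1) {
    list(age = list(idx = 1, effect = effect),
         bmi = list(idx = 2, effect = effect),
         ff = list(idx = 3, effect = effect))
  } else {
    list(age = list(idx = c(1, 4), effect = effect),
         bmi = list(idx = c(2, 5), effect = effect),
         ff = list(idx = c(3, 6), effect = effect))
  }
  generateFeatureTable(plantedTableSpec(
    nSubjects = n, nFeatures = p, signalFeatures = sig, seed = seed))
}

# memoized cascade fixtures shared across test files (computed once per
# test_dir session)
.fixtureCache <- new.env(parent = emptyenv())

cascadeFixture <- function(n, p, effect, seed, nRepeats = 3, perTarget = 1) {
  key <- paste(n, p, effect, seed, nRepeats, perTarget, sep = "_")
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  tab <- plantedTableFixture(n = n, p = p, effect = effect, seed = seed,
                             perTarget = perTarget)
  folds <- makeFolds(subjectMeta(tab)$subject_id, 5, 2)
  trace <- runCascade(tab, folds, seed = 3)
  rk <- rankFeatures(tab, trace, folds, rankingConfig(nRepeats = nRepeats),
                     seed = 13)
  out <- list(tab = tab, folds = folds, trace = trace, rk = rk)
  .fixtureCache[[key]] <- out
  out
}
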