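#' Ranking configuration
#'
#' The post-selection importance forest (100 trees, squared-error splits,
#' depth 8), the number of permutation repeats, and the targets over which
#' ranks are aggregated.
#'
#' @param trees,depth regression forest size and depth
#' @param nRepeats permutation repeats per fold/target (>= 1), default 10
#' @param targets auxiliary targets to aggregate over
#' @return list of class `rankingConfig`
#' @export
rankingConfig <- function(trees = 100, depth = 8, nRepeats = 10,
                          targets = c("age", "bmi", "ff")) {
  if (nRepeats < 1) stopf("nRepeats must be at least 1")
  structure(list(trees = trees, depth = depth, nRepeats = nRepeats,
                 targets = targets), class = "rankingConfig")
}

#' Permutation importance on validation data
#'
#' For each feature, the drop in the fitted forest's validation score
#' (coefficient of determination) when that feature's column is permuted,
#' once per repeat. Deterministic for a fixed seed.
#'
#' @param model a fitted `ranger` regression forest
#' @param Xval validation matrix (columns = model features)
#' @param yval validation target
#' @param nRepeats number of permutations per feature
#' @param seed integer seed
#' @return list(mean = named mean drops, perRepeat = nRepeats x p matrix of
#'   per-repeat drops)
#' @export
permutationImportance <- function(model, Xval, yval, nRepeats = 10,
                                  seed = 1) {
  if (nRepeats < 1) stopf("nRepeats must be at least 1")
  base <- scoreR2(stats::predict(model,
    data.frame(Xval, check.names = FALSE))$predictions, yval)
  p <- ncol(Xval)
  drops <- matrix(0, nRepeats, p, dimnames = list(NULL, colnames(Xval)))
  with_seed(seed, {
    for (k in seq_len(nRepeats)) {
      for (j in seq_len(p)) {
        Xp <- Xval
        Xp[, j] <- Xp[sample(nrow(Xp)), j]
        pred <- stats::predict(model,
          data.frame(Xp, check.names = FALSE))$predictions
        drops[k, j] <- base - scoreR2(pred, yval)
      }
    }
  })
  list(mean = colMeans(drops), perRepeat = drops)
}

scoreR2 <- function(pred, y) {
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(0)
  1 - sum((y - pred)^2) / tss
}

#' Normalized ranks of a set of importances
#'
#' Features are sorted by decreasing importance; the 0-based position p among
#' N features maps to p/(N-1) so the first feature ranks 0 and the last 1
#' (0 for a single feature). Ties share the mean of their positions before
#' normalization.
#'
#' @param importances named numeric vector over the selected set
#' @return named numeric ranks in \[0,1\]
#' @export
perFoldTargetRanks <- function(importances) {
  n <- length(importances)
  if (n == 0) stopf("empty selected set")
  if (n == 1) return(stats::setNames(0, names(importances)))
  pos <- rank(-importances, ties.method = "average") - 1
  stats::setNames(pos / (n - 1), names(importances))
}

#' Aggregate permutation-importance ranks across repeats, targets and folds
#'
#' Implements the rank-aggregation scheme: per fold, the aggregate rank of a
#' feature is the mean over permutation repeats and targets of its
#' normalized rank, where a feature absent from a target's selected set (but
#' selected for at least one target) is ranked last, i.e. contributes 1 for
#' that target. Cross-fold mean, median and quartiles are reported for
#' boxplot-style summaries.
#'
#' @param raw nested list raw[[fold]][[target]]: nRepeats x p matrix of
#'   normalized ranks for that fold/target's selected set
#' @param config a [rankingConfig()]
#' @return a \linkS4class{RankTable}
#' @export
aggregateRank <- function(raw, config = rankingConfig()) {
  targets <- config$targets
  nFolds <- length(raw)
  allFeatures <- sort(unique(unlist(lapply(raw, function(f)
    lapply(f, colnames)))))
  if (!length(allFeatures)) stopf("no feature selected for any target")
  agg <- matrix(NA_real_, length(allFeatures), nFolds,
                dimnames = list(allFeatures, paste0("fold", seq_len(nFolds))))
  sizes <- list()
  for (fi in seq_len(nFolds)) {
    acc <- stats::setNames(rep(0, length(allFeatures)), allFeatures)
    for (t in targets) {
      m <- raw[[fi]][[t]]
      sizes[[length(sizes) + 1L]] <- data.frame(fold = fi, target = t,
                                                nFeatures = ncol(m))
      # mean over repeats for selected features; absent features rank 1
      r <- stats::setNames(rep(1, length(allFeatures)), allFeatures)
      r[colnames(m)] <- colMeans(m)
      acc <- acc + r
    }
    agg[, fi] <- acc / length(targets)
  }
  aggdf <- data.frame(feature = allFeatures, agg, check.names = FALSE)
  aggdf$mean <- rowMeans(agg)
  aggdf$median <- apply(agg, 1, stats::median)
  aggdf$q1 <- apply(agg, 1, stats::quantile, 0.25, names = FALSE)
  aggdf$q3 <- apply(agg, 1, stats::quantile, 0.75, names = FALSE)
  aggdf <- aggdf[order(aggdf$mean, aggdf$feature), ]
  rownames(aggdf) <- NULL
  new("RankTable", aggregate = aggdf, raw = raw,
      sizes = do.call(rbind, sizes), nRepeats = as.integer(config$nRepeats),
      targets = targets)
}

#' Compute the cross-fold importance ranking from a selection trace
#'
#' For every fold and target: fits the ranking forest on the training
#' subjects with the fold's selected features, computes permutation
#' importance on the validation subjects (per repeat), turns each repeat's
#' importances into normalized ranks and aggregates via [aggregateRank()].
#'
#' @param table \linkS4class{MuscleFeatureTable}
#' @param trace \linkS4class{SelectionTrace} from [runCascade()]
#' @param folds \linkS4class{FoldSplit}
#' @param config a [rankingConfig()]
#' @param seed integer seed
#' @return a \linkS4class{RankTable}
#' @export
rankFeatures <- function(table, trace, folds, config = rankingConfig(),
                         seed = 1) {
  assign <- foldAssignment(folds)
  ids <- names(assign)
  contrast <- trace@config$contrast
  muscle <- trace@config$muscle
  sideCombine <- trace@config$selection$sideCombine
  meta <- subjectMeta(table)
  raw <- list()
  for (fi in seq_len(folds@k)) {
    train <- ids[assign != fi]
    val <- ids[assign == fi]
    raw[[fi]] <- list()
    for (t in config$targets) {
      feats <- trace@steps[[fi]]$selected[[t]]
      if (!length(feats)) {
        raw[[fi]][[t]] <- matrix(0, config$nRepeats, 0)
        next
      }
      X <- combinedFeatureMatrix(table, feats, contrast, muscle, sideCombine)
      y <- targetVector(table, t, muscle)
      dtr <- data.frame(X[train, , drop = FALSE], check.names = FALSE)
      dtr$.y <- y[match(train, meta$subject_id)]
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = dtr,
        num.trees = config$trees, max.depth = config$depth,
        splitrule = "variance", num.threads = 1,
        seed = deriveSeed(seed, paste0("rf", fi, t)))
      pi <- permutationImportance(
        fit, X[val, , drop = FALSE], y[match(val, meta$subject_id)],
        config$nRepeats, deriveSeed(seed, paste0("perm", fi, t)))
      ranks <- t(apply(pi$perRepeat, 1, function(row)
        perFoldTargetRanks(stats::setNames(row, colnames(pi$perRepeat)))))
      if (ncol(pi$perRepeat) == 1)
        ranks <- matrix(0, config$nRepeats, 1,
                        dimnames = list(NULL, colnames(pi$perRepeat)))
      raw[[fi]][[t]] <- ranks
    }
  }
  aggregateRank(raw, config)
}

#' Boxplot of aggregate ranks for the top features
#'
#' @param rankTable a \linkS4class{RankTable}
#' @param topK number of lowest-ranked (best) features to show
#' @param file optional PNG path; NULL plots to the active device
#' @return invisibly, the plotted feature names
#' @export
plotRankBoxes <- function(rankTable, topK = 10, file = NULL) {
  agg <- rankAggregate(rankTable)
  top <- utils::head(agg, topK)
  foldCols <- grep("^fold", names(top))
  m <- t(as.matrix(top[, foldCols]))
  colnames(m) <- top$feature
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::par(mar = c(14, 4, 2, 1))
  graphics::boxplot(m, las = 2, ylab = "aggregated rank", ylim = c(0, 1),
                    cex.axis = 0.7)
  graphics::points(seq_len(ncol(m)), top$mean, pch = 17, col = "darkgreen")
  invisible(top$feature)
}
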