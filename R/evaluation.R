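#' Evaluation configuration
#'
#' The validation classifier: a classification random forest with 500 trees
#' and maximum depth 10 (Gini impurity splits), scored per fold on the
#' subgroup bins of each auxiliary target, for the full selected set and the
#' top-k features of the aggregate ranking.
#'
#' @param trees,depth forest size and depth
#' @param topK size of the top-ranked subset, default 10
#' @return list of class `evalConfig`
#' @export
evalConfig <- function(trees = 500, depth = 10, topK = 10) {
  if (topK < 1) stopf("topK must be at least 1")
  structure(list(trees = trees, depth = depth, topK = topK),
            class = "evalConfig")
}

#' Train the subgroup classifier
#'
#' @param X training matrix (named columns)
#' @param yBins integer/factor class labels (>= 2 classes present)
#' @param config an [evalConfig()]
#' @param seed integer seed
#' @return fitted `ranger` probability forest
#' @export
trainClassifier <- function(X, yBins, config = evalConfig(), seed = 1) {
  yBins <- factor(yBins)
  if (nlevels(droplevels(yBins)) < 2) stopf("need at least 2 classes")
  dat <- data.frame(X, check.names = FALSE)
  dat$.y <- droplevels(yBins)
  ranger::ranger(dependent.variable.name = ".y", data = dat,
                 num.trees = config$trees, max.depth = config$depth,
                 probability = TRUE, num.threads = 1, seed = seed)
}

#' Micro-averaged one-vs-rest ROC and AUC
#'
#' Flattens all (class, sample) pairs into a single binary problem: the
#' indicator that the sample belongs to the class against the predicted
#' probability for that class, then computes one ROC curve and its
#' trapezoidal AUC.
#'
#' @param scores n x K matrix of class probabilities (columns named by class)
#' @param labels vector of true class labels
#' @return list(fpr, tpr, auc)
#' @export
ovrMicroRoc <- function(scores, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stopf("need at least 2 classes in labels")
  if (is.null(colnames(scores))) stopf("scores must have class column names")
  rs <- rowSums(scores)
  if (any(abs(rs - 1) > 1e-6)) stopf("score rows must sum to 1")
  if (ncol(scores) == 2L) {
    # two complementary columns are a single binary problem; flattening
    # them would double-count each sample
    truth <- as.integer(labels == colnames(scores)[1])
    score <- scores[, 1]
  } else {
    truth <- as.vector(vapply(colnames(scores), function(cl)
      as.integer(labels == cl), integer(length(labels))))
    score <- as.vector(scores)
  }
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]; score <- score[ord]
  # step through distinct thresholds
  tp <- cumsum(truth); fp <- cumsum(1 - truth)
  last <- c(diff(score) != 0, TRUE)
  tp <- tp[last]; fp <- fp[last]
  P <- sum(truth); N <- length(truth) - P
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Chance accuracy of uniform subgroup guessing
#'
#' @param nBins number of subgroups (>= 1)
#' @return percentage, rounded to 2 decimals (e.g. 16.67 for six bins)
#' @export
chanceAccuracy <- function(nBins) {
  if (nBins < 1) stopf("nBins must be at least 1")
  round(100 / nBins, 2)
}

#' Classifier-based validation of selected and ranked features
#'
#' For each target: per fold, fits the subgroup classifier on the training
#' subjects with that fold's selected features and, separately, with the
#' top-k features of the aggregate ranking; scores micro-averaged OvR AUC
#' and accuracy on the training and validation subjects.
#'
#' @param table \linkS4class{MuscleFeatureTable}
#' @param trace \linkS4class{SelectionTrace}
#' @param rankTable \linkS4class{RankTable}
#' @param folds \linkS4class{FoldSplit}
#' @param schemes named list of [binningScheme()]s
#' @param config an [evalConfig()]
#' @param seed integer seed
#' @return an \linkS4class{EvalReport}
#' @export
evaluateSelection <- function(table, trace, rankTable, folds, schemes,
                              config = evalConfig(), seed = 1) {
  assign <- foldAssignment(folds)
  ids <- names(assign)
  meta <- subjectMeta(table)
  contrast <- trace@config$contrast
  muscle <- trace@config$muscle
  sideCombine <- trace@config$selection$sideCombine
  scope <- if (is.null(muscle)) "all" else muscle
  topFeats <- utils::head(rankAggregate(rankTable)$feature, config$topK)
  rows <- list()
  for (t in intersect(trace@config$targets, names(schemes))) {
    y <- targetVector(table, t, muscle)
    bins <- assignBins(y, schemes[[t]])
    perFold <- list()
    for (fi in seq_len(folds@k)) {
      train <- ids[assign != fi]
      val <- ids[assign == fi]
      itr <- match(train, meta$subject_id)
      iva <- match(val, meta$subject_id)
      for (set in c("full", "top")) {
        feats <- if (set == "full") trace@steps[[fi]]$selected[[t]]
                 else topFeats
        if (!length(feats)) next
        X <- combinedFeatureMatrix(table, feats, contrast, muscle,
                                   sideCombine)
        fit <- trainClassifier(X[itr, , drop = FALSE], bins[itr], config,
                               deriveSeed(seed, paste0("eval", t, fi, set)))
        for (split in c("train", "validation")) {
          ii <- if (split == "train") itr else iva
          pred <- stats::predict(fit,
            data.frame(X[ii, , drop = FALSE],
                       check.names = FALSE))$predictions
          present <- colnames(pred)
          lab <- as.character(bins[ii])
          keep <- lab %in% present
          roc <- ovrMicroRoc(pred[keep, , drop = FALSE], lab[keep])
          acc <- mean(present[max.col(pred)] == lab)
          perFold[[length(perFold) + 1L]] <- data.frame(
            fold = fi, set = set, split = split, auc = roc$auc, acc = acc)
        }
      }
    }
    pf <- do.call(rbind, perFold)
    for (set in unique(pf$set)) for (split in unique(pf$split)) {
      sub <- pf[pf$set == set & pf$split == split, ]
      rows[[length(rows) + 1L]] <- data.frame(
        scope = scope, contrast = contrast, target = t, set = set,
        split = split, aucMean = mean(sub$auc), aucSd = stats::sd(sub$auc),
        accMean = mean(sub$acc), accSd = stats::sd(sub$acc),
        chance = chanceAccuracy(schemes[[t]]$nBins) / 100)
    }
  }
  new("EvalReport", results = do.call(rbind, rows))
}
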