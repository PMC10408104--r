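#' Selection cascade configuration
#'
#' Pins the thresholds of the five-step cascade: correlation-cluster distance
#' 0.1 (step I), left/right reproducibility threshold 0.7 (step II), VIF
#' threshold 10 (step III), and the shadow-feature forest (100 trees, squared
#' error splits, depth 5) with its confirmation test (step IV).
#'
#' @param clusterDistanceThreshold dendrogram cut on 1-|rho|, default 0.1
#' @param lrCorrThreshold minimum mean left/right Pearson r, default 0.7
#' @param vifThreshold variance-inflation-factor removal threshold (> 1)
#' @param shadowTrees,shadowDepth forest size/depth for shadow selection
#' @param shadowIterations maximum shadow iterations, default 50
#' @param shadowAlpha two-sided binomial confirmation level, default 0.05
#' @param sideCombine how surviving features combine sides downstream
#' @return list of class `selectionConfig`
#' @export
selectionConfig <- function(clusterDistanceThreshold = 0.1,
                            lrCorrThreshold = 0.7, vifThreshold = 10,
                            shadowTrees = 100, shadowDepth = 5,
                            shadowIterations = 50, shadowAlpha = 0.05,
                            sideCombine = c("mean", "left")) {
  if (vifThreshold <= 1) stopf("vifThreshold must exceed 1")
  if (clusterDistanceThreshold <= 0 || lrCorrThreshold <= 0)
    stopf("thresholds must be positive")
  structure(list(clusterDistanceThreshold = clusterDistanceThreshold,
                 lrCorrThreshold = lrCorrThreshold,
                 vifThreshold = vifThreshold, shadowTrees = shadowTrees,
                 shadowDepth = shadowDepth,
                 shadowIterations = shadowIterations,
                 shadowAlpha = shadowAlpha,
                 sideCombine = match.arg(sideCombine)),
            class = "selectionConfig")
}

#' Cross-validation folds over subjects
#'
#' Uniform random partition into k disjoint folds whose sizes differ by at
#' most one; each fold serves once as the validation set.
#'
#' @param ids subject identifiers
#' @param k number of folds (>= 2, <= length(ids))
#' @param seed integer seed
#' @return a \linkS4class{FoldSplit}
#' @export
makeFolds <- function(ids, k = 5, seed = 1) {
  if (k < 2) stopf("k must be at least 2")
  if (length(ids) < k) stopf("need at least k subjects")
  with_seed(seed, {
    fold <- sample(rep(seq_len(k), length.out = length(ids)))
    storage.mode(fold) <- "integer"
    names(fold) <- ids
    new("FoldSplit", k = as.integer(k), assignment = fold)
  })
}

#' Stratum-averaged feature correlation matrix
#'
#' Pearson correlations between features computed separately within every
#' (sex x muscle x side) stratum and averaged with equal stratum weights, so
#' that one representative set serves all investigated cases. Features that
#' are constant in a stratum get missing correlations there and are flagged.
#'
#' @param table a \linkS4class{MuscleFeatureTable} (one contrast)
#' @param contrast contrast to use, default `"water"`
#' @return list(corr = canonical-feature correlation matrix, flagged =
#'   character vector of features constant in at least one stratum)
#' @export
averagedCorrelation <- function(table, contrast = "water") {
  keys <- featureKeys(table)
  meta <- subjectMeta(table)
  vals <- featureValues(table)
  sel <- keys$contrast == contrast
  keys <- keys[sel, ]; vals <- vals[, sel, drop = FALSE]
  canon <- sort(unique(keys$canonical))
  strata <- split(seq_len(nrow(meta)), meta$sex)
  groups <- unique(keys[, c("muscle", "side")])
  acc <- matrix(0, length(canon), length(canon),
                dimnames = list(canon, canon))
  cnt <- 0
  flagged <- character()
  for (g in seq_len(nrow(groups))) {
    gsel <- keys$muscle == groups$muscle[g] & keys$side == groups$side[g]
    sub <- vals[, gsel, drop = FALSE]
    colnames(sub) <- keys$canonical[gsel]
    sub <- sub[, canon, drop = FALSE]
    for (s in names(strata)) {
      block <- sub[strata[[s]], , drop = FALSE]
      sds <- apply(block, 2, stats::sd)
      bad <- !is.finite(sds) | sds == 0
      flagged <- union(flagged, canon[bad])
      r <- suppressWarnings(stats::cor(block))
      r[!is.finite(r)] <- 0
      diag(r) <- 1
      acc <- acc + r
      cnt <- cnt + 1
    }
  }
  corr <- acc / cnt
  diag(corr) <- 1
  list(corr = corr, flagged = flagged)
}

# cut a dendrogram at a height by traversing merges in order; equivalent to
# cutree for monotone heights and well-defined under centroid inversions
cutMerges <- function(hc, h) {
  n <- length(hc$order)
  grp <- seq_len(n)                  # leaf -> group id
  nodeGroup <- integer(nrow(hc$merge))  # internal node -> group id (0 = cut)
  for (m in seq_len(nrow(hc$merge))) {
    a <- hc$merge[m, 1]; b <- hc$merge[m, 2]
    ga <- if (a < 0) grp[-a] else nodeGroup[a]
    gb <- if (b < 0) grp[-b] else nodeGroup[b]
    if (hc$height[m] < h && ga > 0 && gb > 0) {
      grp[grp == gb] <- ga
      nodeGroup[m] <- ga
    } else nodeGroup[m] <- 0L
  }
  match(grp, unique(grp))
}

#' Step I: cluster-representative feature selection
#'
#' Within each feature sub-category independently, agglomerative clustering
#' (centroid criterion) on the distance 1-|rho| with clusters formed below
#' the distance threshold; one representative per cluster, chosen with
#' priority original > LoG > wavelet, alphabetical within a priority tier.
#' Features with missing correlations become flagged singletons.
#'
#' @param corr canonical-feature correlation matrix (e.g. from
#'   [averagedCorrelation()])
#' @param config a [selectionConfig()]
#' @return list(representatives = character, clusters = named integer vector
#'   of cluster ids per feature)
#' @export
clusterRepresentatives <- function(corr, config = selectionConfig()) {
  canon <- rownames(corr)
  subcat <- subcategoryOf(canon)
  reps <- character()
  clusters <- integer(length(canon))
  names(clusters) <- canon
  offset <- 0L
  for (sc in sort(unique(subcat))) {
    members <- canon[subcat == sc]
    if (length(members) == 1L) {
      cl <- 1L
    } else {
      d <- 1 - abs(corr[members, members, drop = FALSE])
      d[!is.finite(d)] <- 1
      hc <- stats::hclust(stats::as.dist(d), method = "centroid")
      cl <- cutMerges(hc, config$clusterDistanceThreshold)
    }
    for (k in sort(unique(cl))) {
      mem <- members[cl == k]
      ord <- order(variantPriority(mem), mem)
      reps <- c(reps, mem[ord[1]])
    }
    clusters[members] <- cl + offset
    offset <- offset + max(cl)
  }
  list(representatives = sort(reps), clusters = clusters)
}

#' Step II: left/right reproducibility filter
#'
#' Per feature and muscle, the Pearson correlation across training subjects
#' between the left-side and right-side values; features are kept iff their
#' mean-over-muscles correlation reaches the threshold. Zero-variance side
#' vectors make the correlation undefined and the feature is discarded with
#' a reason.
#'
#' @param table \linkS4class{MuscleFeatureTable}
#' @param features canonical feature names to test
#' @param trainIds training subject ids
#' @param contrast contrast to use
#' @param threshold minimum mean correlation, default 0.7
#' @return list(kept = character, r = named numeric of mean correlations,
#'   discarded = data.frame(feature, reason))
#' @export
lrReproducibilityFilter <- function(table, features, trainIds,
                                    contrast = "water", threshold = 0.7) {
  keys <- featureKeys(table)
  vals <- featureValues(table)[trainIds, , drop = FALSE]
  if (length(trainIds) < 3) stopf("need at least 3 training subjects")
  muscles <- unique(keys$muscle)
  rbar <- stats::setNames(rep(NA_real_, length(features)), features)
  reasons <- character(length(features))
  for (fi in seq_along(features)) {
    f <- features[fi]
    rs <- numeric()
    degenerate <- FALSE
    for (m in muscles) {
      li <- instanceKey(m, "left", contrast, f)
      ri <- instanceKey(m, "right", contrast, f)
      if (!(li %in% colnames(vals)) || !(ri %in% colnames(vals))) next
      lv <- vals[, li]; rv <- vals[, ri]
      if (stats::sd(lv) == 0 || stats::sd(rv) == 0) {
        degenerate <- TRUE
        break
      }
      rs <- c(rs, stats::cor(lv, rv))
    }
    if (degenerate || !length(rs)) {
      reasons[fi] <- "zero-variance side vector"
      rbar[fi] <- NA_real_
    } else rbar[fi] <- mean(rs)
  }
  kept <- features[!is.na(rbar) & rbar >= threshold]
  disc <- features[!(features %in% kept)]
  list(kept = kept, r = rbar,
       discarded = data.frame(
         feature = disc,
         reason = ifelse(reasons[match(disc, features)] == "",
                         "mean left/right correlation below threshold",
                         reasons[match(disc, features)])))
}

# VIF of every column of X via least squares of each column on the others
vifValues <- function(X) {
  p <- ncol(X)
  stats::setNames(vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    tss <- sum((X[, j] - mean(X[, j]))^2)
    rss <- sum(fit$residuals^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0), colnames(X))
}

#' Step III: iterative variance-inflation-factor pruning
#'
#' Repeatedly regresses every remaining feature on all the others (with
#' intercept), computes VIF = 1/(1-R^2), and removes the feature with the
#' largest VIF while it exceeds the threshold (ties broken alphabetically;
#' perfect collinearity is treated as infinite VIF and removed first).
#'
#' @param X numeric training matrix (columns named by feature), one feature
#'   sub-category
#' @param threshold removal threshold, default 10
#' @return list(kept = character, removed = data.frame(feature, vif) in
#'   removal order)
#' @export
vifPrune <- function(X, threshold = 10) {
  if (ncol(X) < 2)
    return(list(kept = colnames(X),
                removed = data.frame(feature = character(), vif = numeric())))
  removed <- list()
  repeat {
    if (ncol(X) < 2) break
    v <- vifValues(X)
    mx <- max(v)
    if (mx <= threshold) break
    cand <- colnames(X)[v == mx]
    drop <- sort(cand)[1]
    removed[[length(removed) + 1L]] <- data.frame(feature = drop, vif = mx)
    X <- X[, colnames(X) != drop, drop = FALSE]
  }
  list(kept = colnames(X),
       removed = if (length(removed)) do.call(rbind, removed)
                 else data.frame(feature = character(), vif = numeric()))
}

#' Step IV: shadow-feature (Boruta-style) selection
#'
#' Iteratively augments the predictors with a permuted (shadow) copy of every
#' undecided column, fits the configured regression forest and scores a hit
#' for every real feature whose importance exceeds the maximum shadow
#' importance. At least five shadow attributes are kept so the shadow
#' maximum remains a competitive reference late in the run. Features are
#' confirmed or rejected by a two-sided binomial test on their hit counts,
#' Bonferroni-adjusted for the number of features entering the selection;
#' decided features leave the pool, and the procedure stops early when
#' nothing is left undecided. Features still undecided after the final
#' iteration are rejected.
#'
#' @param X numeric training matrix, named columns
#' @param y numeric target
#' @param config a [selectionConfig()]
#' @param seed integer seed
#' @return list(selected = character, history = data.frame(feature, hits,
#'   iterations, decision))
#' @export
shadowSelect <- function(X, y, config = selectionConfig(), seed = 1) {
  if (stats::sd(y) == 0) stopf("target is constant")
  if (ncol(X) < 1) stopf("need at least one feature")
  feats <- colnames(X)
  hits <- stats::setNames(integer(length(feats)), feats)
  iters <- stats::setNames(integer(length(feats)), feats)
  decision <- stats::setNames(rep("tentative", length(feats)), feats)
  with_seed(seed, {
    for (it in seq_len(config$shadowIterations)) {
      open <- names(decision)[decision == "tentative"]
      if (!length(open)) break
      Xo <- X[, open, drop = FALSE]
      shadow <- apply(Xo, 2, sample)
      # keep at least 5 shadow attributes so the shadow maximum stays a
      # competitive reference even when few features remain undecided
      if (ncol(shadow) < 5) {
        extra <- sample(seq_len(ncol(Xo)), 5 - ncol(shadow), replace = TRUE)
        shadow <- cbind(shadow, apply(Xo[, extra, drop = FALSE], 2, sample))
      }
      colnames(shadow) <- paste0(".shadow.", seq_len(ncol(shadow)))
      dat <- data.frame(cbind(Xo, shadow), check.names = FALSE)
      dat$.y <- y
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = dat,
        num.trees = config$shadowTrees, max.depth = config$shadowDepth,
        splitrule = "variance", importance = "impurity",
        num.threads = 1, seed = sample.int(.Machine$integer.max, 1))
      imp <- fit$variable.importance
      shadowMax <- max(imp[startsWith(names(imp), ".shadow.")])
      hit <- imp[open] > shadowMax
      hits[open] <- hits[open] + as.integer(hit)
      iters[open] <- iters[open] + 1L
      # two-sided binomial test with Bonferroni multiplicity adjustment
      # over the features entering the selection
      thr <- config$shadowAlpha / length(feats)
      for (f in open) {
        pv <- stats::binom.test(hits[f], iters[f], 0.5)$p.value
        if (pv < thr) {
          decision[f] <- if (hits[f] > iters[f] / 2) "confirmed"
                         else "rejected"
        }
      }
    }
    decision[decision == "tentative"] <- "rejected"
    list(selected = sort(names(decision)[decision == "confirmed"]),
         history = data.frame(feature = feats, hits = hits[feats],
                              iterations = iters[feats],
                              decision = decision[feats], row.names = NULL))
  })
}

# subject-level feature matrix for the downstream steps: sides combined per
# muscle, then (all-muscles scope) averaged over muscle groups
combinedFeatureMatrix <- function(table, features, contrast, muscle = NULL,
                                  sideCombine = "mean") {
  keys <- featureKeys(table)
  vals <- featureValues(table)
  muscles <- if (is.null(muscle)) unique(keys$muscle) else muscle
  out <- matrix(0, nrow(vals), length(features),
                dimnames = list(rownames(vals), features))
  for (fi in seq_along(features)) {
    f <- features[fi]
    per <- sapply(muscles, function(m) {
      li <- instanceKey(m, "left", contrast, f)
      ri <- instanceKey(m, "right", contrast, f)
      if (sideCombine == "left" || !(ri %in% colnames(vals)))
        vals[, li]
      else (vals[, li] + vals[, ri]) / 2
    })
    out[, fi] <- if (is.matrix(per)) rowMeans(per) else per
  }
  out
}

targetVector <- function(table, target, muscle = NULL) {
  meta <- subjectMeta(table)
  if (target %in% c("age", "bmi")) return(meta[[target]])
  if (target == "ff") {
    if (!is.null(muscle) && paste0("ff_", muscle) %in% names(meta))
      return(meta[[paste0("ff_", muscle)]])
    return(meta[["ff"]])
  }
  stopf("unknown target '%s'", target)
}

#' Run the feature-selection cascade
#'
#' Step I (cluster representatives) is computed once on all subjects; steps
#' II (left/right reproducibility), III (VIF pruning, per sub-category) and
#' IV (shadow selection, per target) run per cross-validation fold on that
#' fold's training subjects. The returned trace records every step's
#' surviving set; survivor sets are nested by construction.
#'
#' @param table \linkS4class{MuscleFeatureTable}
#' @param folds \linkS4class{FoldSplit}
#' @param targets character subset of c("age","bmi","ff")
#' @param contrast `"water"` or `"fat"`
#' @param muscle NULL for the joint all-muscles scope, or one muscle name
#' @param config a [selectionConfig()]
#' @param seed integer seed
#' @return a \linkS4class{SelectionTrace}
#' @export
runCascade <- function(table, folds, targets = c("age", "bmi", "ff"),
                       contrast = "water", muscle = NULL,
                       config = selectionConfig(), seed = 1) {
  ac <- averagedCorrelation(table, contrast)
  repSel <- clusterRepresentatives(ac$corr, config)
  reps <- repSel$representatives
  assign <- foldAssignment(folds)
  ids <- names(assign)
  steps <- list()
  countRows <- list()
  for (fi in seq_len(folds@k)) {
    train <- ids[assign != fi]
    s2 <- lrReproducibilityFilter(table, reps, train, contrast,
                                  config$lrCorrThreshold)
    X <- combinedFeatureMatrix(table, s2$kept, contrast, muscle,
                               config$sideCombine)[train, , drop = FALSE]
    sub <- subcategoryOf(s2$kept)
    kept3 <- character()
    for (sc in sort(unique(sub))) {
      pr <- vifPrune(X[, s2$kept[sub == sc], drop = FALSE],
                     config$vifThreshold)
      kept3 <- c(kept3, pr$kept)
    }
    kept3 <- sort(kept3)
    s4 <- list()
    for (t in targets) {
      y <- targetVector(table, t, muscle)[match(train,
             subjectMeta(table)$subject_id)]
      s4[[t]] <- shadowSelect(X[, kept3, drop = FALSE], y, config,
                              deriveSeed(seed, paste0("shadow", fi, t)))$selected
    }
    steps[[fi]] <- list(reproducible = s2$kept, vifPruned = kept3,
                        selected = s4)
    countRows[[fi]] <- data.frame(
      fold = fi, step1 = length(reps), step2 = length(s2$kept),
      step3 = length(kept3),
      t(vapply(targets, function(t) length(s4[[t]]), 0)))
  }
  counts <- do.call(rbind, countRows)
  new("SelectionTrace", representatives = reps, steps = steps,
      counts = counts,
      config = list(selection = config, targets = targets,
                    contrast = contrast, muscle = muscle))
}

#' Per-step survivor summary in min/mean/max style
#'
#' @param trace a \linkS4class{SelectionTrace}
#' @return data.frame: step, mean, min, max, unique count across folds
#' @export
cascadeSummary <- function(trace) {
  cnt <- trace@counts
  targets <- trace@config$targets
  rows <- list(data.frame(step = "cluster_representatives",
                          mean = cnt$step1[1], min = cnt$step1[1],
                          max = cnt$step1[1], unique = cnt$step1[1]))
  sets2 <- lapply(trace@steps, `[[`, "reproducible")
  sets3 <- lapply(trace@steps, `[[`, "vifPruned")
  rows[[2]] <- data.frame(step = "lr_reproducibility",
                          mean = mean(cnt$step2), min = min(cnt$step2),
                          max = max(cnt$step2),
                          unique = length(unique(unlist(sets2))))
  rows[[3]] <- data.frame(step = "vif_pruning",
                          mean = mean(cnt$step3), min = min(cnt$step3),
                          max = max(cnt$step3),
                          unique = length(unique(unlist(sets3))))
  for (t in targets) {
    sets4 <- lapply(trace@steps, function(s) s$selected[[t]])
    sizes <- lengths(sets4)
    rows[[length(rows) + 1L]] <- data.frame(
      step = paste0("shadow_", t), mean = mean(sizes), min = min(sizes),
      max = max(sizes), unique = length(unique(unlist(sets4))))
  }
  do.call(rbind, rows)
}
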