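#' Subgroup binning scheme
#'
#' Ordered interior bin edges defining half-open bins `[e_i, e_{i+1})`;
#' values below the first edge fall into the first bin and values at or
#' above the last edge into the last bin (tail clamping). With m interior
#' edges there are m+1 bins.
#'
#' @param target one of "age", "bmi", "ff"
#' @param edges strictly increasing interior edges
#' @return list of class `binningScheme`
#' @export
binningScheme <- function(target, edges) {
  if (any(diff(edges) <= 0)) stopf("edges must be strictly increasing")
  if (length(edges) < 1) stopf("need at least one interior edge")
  structure(list(target = target, edges = as.numeric(edges),
                 nBins = length(edges) + 1L), class = "binningScheme")
}

#' Default binning schemes
#'
#' Age: six decade-style bins (interior edges 30, 40, 50, 60, 65); BMI:
#' seven bins (20, 22.5, 25, 27.5, 30, 35); FF: six equal-width bins over
#' the observed central 95% range of the supplied values.
#'
#' @param ffValues numeric fat-fraction values used to place the FF edges
#' @return named list of [binningScheme()]s
#' @export
defaultBinningSchemes <- function(ffValues = NULL) {
  out <- list(age = binningScheme("age", c(30, 40, 50, 60, 65)),
              bmi = binningScheme("bmi", c(20, 22.5, 25, 27.5, 30, 35)))
  if (!is.null(ffValues)) {
    r <- stats::quantile(ffValues, c(0.025, 0.975), names = FALSE)
    out$ff <- binningScheme("ff", seq(r[1], r[2], length.out = 7)[2:6])
  }
  out
}

#' Assign values to subgroup bins
#'
#' @param values numeric vector (finite)
#' @param scheme a [binningScheme()]
#' @return integer bin indices in 1..nBins
#' @export
assignBins <- function(values, scheme) {
  bad <- which(!is.finite(values))
  if (length(bad)) stopf("non-finite value at position %d", bad[1])
  findInterval(values, scheme$edges) + 1L
}

#' Kruskal-Wallis H-test across subgroups
#'
#' One-way analysis of variance on mid-ranks with tie correction; p-value
#' from the chi-squared approximation with (groups - 1) degrees of freedom.
#' If all values are identical, H = 0 and p = 1.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups)
#' @return list(H, p, df)
#' @export
kruskalWallis <- function(groups) {
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stopf("need at least 2 non-empty groups")
  x <- unlist(groups)
  if (length(x) < 3) stopf("need at least 3 observations")
  if (length(unique(x)) == 1L)
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter))
}

#' Mann-Whitney U test between two groups
#'
#' Two-sided p-value via the normal approximation with tie and continuity
#' correction; the reported U is min(U_a, U_b).
#'
#' @param a,b numeric vectors (non-empty)
#' @return list(U, p)
#' @export
mannWhitney <- function(a, b) {
  if (!length(a) || !length(b)) stopf("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  ua <- unname(wt$statistic)
  list(U = min(ua, length(a) * length(b) - ua), p = wt$p.value)
}

#' Bonferroni-corrected significance threshold
#'
#' alpha/m, rounded to three decimals for reporting; the unrounded value is
#' attached as attribute `exact` and used for flagging.
#'
#' @param alpha family-wise level in (0,1)
#' @param m number of concurrent tests (>= 1)
#' @return rounded threshold with attribute `exact`
#' @export
bonferroniThreshold <- function(alpha = 0.05, m = 10) {
  if (m < 1) stopf("m must be at least 1")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0,1)")
  structure(round(alpha / m, 3), exact = alpha / m)
}

#' Subgroup statistics for the top-ranked features
#'
#' For the k lowest-ranked (best) features: a Kruskal-Wallis H-test per sex
#' across each target's subgroup bins (Bonferroni-corrected for the k
#' concurrent features), and a Mann-Whitney U test male vs female within
#' each bin (Bonferroni-corrected for the number of bins).
#'
#' @param rankTable \linkS4class{RankTable}
#' @param table \linkS4class{MuscleFeatureTable}
#' @param schemes named list of [binningScheme()]s per target
#' @param contrast contrast the ranking refers to
#' @param muscle NULL (all-muscles scope) or one muscle
#' @param topK number of top features, default 10
#' @param alpha family-wise level, default 0.05
#' @param sideCombine side combination rule, default "mean"
#' @return list(kw, mwu, thresholds): data.frames of test results with
#'   significance flags, in the style of per-feature subgroup tables
#' @export
subgroupReport <- function(rankTable, table, schemes, contrast = "water",
                           muscle = NULL, topK = 10, alpha = 0.05,
                           sideCombine = "mean") {
  if (topK < 1) stopf("topK must be at least 1")
  agg <- rankAggregate(rankTable)
  feats <- utils::head(agg$feature, topK)
  meta <- subjectMeta(table)
  X <- combinedFeatureMatrix(table, feats, contrast, muscle, sideCombine)
  kwThr <- bonferroniThreshold(alpha, length(feats))
  kwRows <- list(); mwuRows <- list()
  for (t in names(schemes)) {
    y <- targetVector(table, t, muscle)
    bins <- assignBins(y, schemes[[t]])
    mwuThr <- bonferroniThreshold(alpha, schemes[[t]]$nBins)
    for (f in feats) {
      for (sx in c("male", "female")) {
        sel <- meta$sex == sx
        gr <- split(X[sel, f], bins[sel])
        gr <- gr[lengths(gr) > 0]
        if (length(gr) < 2) {
          kwRows[[length(kwRows) + 1L]] <- data.frame(
            feature = f, target = t, sex = sx, H = NA, p = NA,
            significant = NA, note = "fewer than 2 non-empty bins")
          next
        }
        kw <- kruskalWallis(gr)
        kwRows[[length(kwRows) + 1L]] <- data.frame(
          feature = f, target = t, sex = sx, H = kw$H, p = kw$p,
          significant = kw$p < attr(kwThr, "exact"), note = "")
      }
      for (b in seq_len(schemes[[t]]$nBins)) {
        am <- X[meta$sex == "male" & bins == b, f]
        af <- X[meta$sex == "female" & bins == b, f]
        if (!length(am) || !length(af)) {
          mwuRows[[length(mwuRows) + 1L]] <- data.frame(
            feature = f, target = t, bin = b, U = NA, p = NA,
            significant = NA, note = "empty bin, skipped")
          next
        }
        mw <- mannWhitney(am, af)
        mwuRows[[length(mwuRows) + 1L]] <- data.frame(
          feature = f, target = t, bin = b, U = mw$U, p = mw$p,
          significant = mw$p < attr(mwuThr, "exact"), note = "")
      }
    }
  }
  list(kw = do.call(rbind, kwRows), mwu = do.call(rbind, mwuRows),
       thresholds = data.frame(
         test = c("kruskal_wallis",
                  paste0("mann_whitney_", names(schemes))),
         threshold = c(as.numeric(kwThr),
                       vapply(schemes, function(s)
                         as.numeric(bonferroniThreshold(alpha, s$nBins)),
                         0))))
}
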