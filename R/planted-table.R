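#' Specification of a planted-structure feature table
#'
#' Describes a tabular cohort with known statistical structure for exercising
#' the selection cascade: correlation-cluster blocks (via a shared latent
#' factor per block, which guarantees positive semi-definiteness), per-feature
#' left/right reliability, and target-linked signal features with stated
#' standardized linear effect sizes.
#'
#' @param nSubjects number of subjects
#' @param nFeatures number of base features (each realized as a left and a
#'   right replicate)
#' @param clusterBlocks list of `list(size=, rho=)` blocks; block members are
#'   assigned from the first unassigned feature indices. `rho` is the
#'   within-block correlation of the feature latents; the realized side-level
#'   correlation is `rho * lrReliability`
#' @param lrReliability per-feature left/right correlation in \[0,1\]
#'   (recycled); 1 means both sides carry the identical latent value
#' @param signalFeatures named list per target (`age`, `bmi`, `ff`) of
#'   `list(idx=, effect=)`: standardized linear effect of the target on the
#'   shared latent of those features
#' @param noiseSd residual sd of the latent; `NULL` (default) completes each
#'   latent to unit variance
#' @param fclass feature sub-category tag for all features (default
#'   `"synthetic"`)
#' @param seed integer seed
#' @return list of class `plantedTableSpec`
#' @export
plantedTableSpec <- function(nSubjects, nFeatures, clusterBlocks = list(),
                             lrReliability = 1, signalFeatures = list(),
                             noiseSd = NULL, fclass = "synthetic", seed = 1) {
  sizes <- vapply(clusterBlocks, function(b) b$size, 0)
  rhos <- vapply(clusterBlocks, function(b) b$rho, 0)
  if (sum(sizes) > nFeatures) stopf("block sizes exceed nFeatures")
  if (any(rhos < 0 | rhos > 1))
    stopf("within-block correlations must be in [0,1]")
  if (any(lrReliability < 0 | lrReliability > 1))
    stopf("lrReliability must be in [0,1]")
  for (t in names(signalFeatures)) {
    if (any(signalFeatures[[t]]$idx > nFeatures))
      stopf("signal index out of range for target %s", t)
  }
  structure(list(nSubjects = nSubjects, nFeatures = nFeatures,
                 clusterBlocks = clusterBlocks,
                 lrReliability = rep_len(lrReliability, nFeatures),
                 signalFeatures = signalFeatures, noiseSd = noiseSd,
                 fclass = rep_len(fclass, nFeatures), seed = seed),
            class = "plantedTableSpec")
}

#' Generate a feature table with planted statistical structure
#'
#' Each base feature j has a latent value
#' `L_j = sum_t beta_tj z_t + sqrt(rho_b) F_b + w_j eps_j`
#' (standardized targets z_t, block factor F_b, unit-variance residual), and
#' left/right replicates
#' `side = sqrt(r_j) L_j + sqrt(1 - r_j) e_side` so that the left/right
#' correlation equals `r_j` and within-block correlations equal `rho_b`.
#'
#' @param spec a [plantedTableSpec()]
#' @return a \linkS4class{MuscleFeatureTable} (muscle `"m1"`, contrast
#'   `"water"`, sides left/right); the generating structure is stored in
#'   `metadata(x)$truth`
#' @export
generateFeatureTable <- function(spec) {
  stopifnot(inherits(spec, "plantedTableSpec"))
  n <- spec$nSubjects
  p <- spec$nFeatures
  meta <- generateCohort(n, deriveSeed(spec$seed, "meta"))
  with_seed(deriveSeed(spec$seed, "table"), {
    meta$ff <- pmin(pmax(0.2 + 0.06 * stats::rnorm(n), 0.01), 0.6)
    z <- cbind(age = as.numeric(scale(meta$age)),
               bmi = as.numeric(scale(meta$bmi)),
               ff = as.numeric(scale(meta$ff)))
    blockOf <- rep(0L, p)
    nxt <- 1L
    for (b in seq_along(spec$clusterBlocks)) {
      sz <- spec$clusterBlocks[[b]]$size
      blockOf[nxt:(nxt + sz - 1L)] <- b
      nxt <- nxt + sz
    }
    factors <- matrix(stats::rnorm(n * max(1L, length(spec$clusterBlocks))),
                      nrow = n)
    beta <- matrix(0, p, 3, dimnames = list(NULL, colnames(z)))
    for (t in names(spec$signalFeatures)) {
      sf <- spec$signalFeatures[[t]]
      beta[sf$idx, t] <- sf$effect
    }
    latent <- matrix(0, n, p)
    for (j in seq_len(p)) {
      v <- z %*% beta[j, ]
      rho <- 0
      if (blockOf[j] > 0L) {
        rho <- spec$clusterBlocks[[blockOf[j]]]$rho
        v <- v + sqrt(rho) * factors[, blockOf[j]]
      }
      varExplained <- sum(beta[j, ]^2) + rho
      w <- if (is.null(spec$noiseSd)) sqrt(max(0, 1 - varExplained))
           else spec$noiseSd
      latent[, j] <- v + w * stats::rnorm(n)
    }
    left <- right <- matrix(0, n, p)
    for (j in seq_len(p)) {
      r <- spec$lrReliability[j]
      left[, j] <- sqrt(r) * latent[, j] + sqrt(1 - r) * stats::rnorm(n)
      right[, j] <- sqrt(r) * latent[, j] + sqrt(1 - r) * stats::rnorm(n)
    }
    canon <- canonicalKey("original", spec$fclass,
                          sprintf("f%04d", seq_len(p)))
    values <- cbind(left, right)
    colnames(values) <- c(instanceKey("m1", "left", "water", canon),
                          instanceKey("m1", "right", "water", canon))
    tab <- MuscleFeatureTable(values, meta)
    S4Vectors::metadata(tab)$truth <- list(
      beta = beta, blockOf = blockOf,
      lrReliability = spec$lrReliability, spec = spec)
    tab
  })
}
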