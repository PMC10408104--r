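textureClassNames <- function() c("firstorder", "glcm", "glrlm", "glszm",
                                  "ngtdm", "gldm")

classFeatureNames <- function(fclass) {
  switch(fclass,
         shape = shapeFeatureNames(),
         firstorder = firstorderFeatureNames(),
         glcm = glcmFeatureNames(),
         glrlm = glrlmFeatureNames(),
         glszm = glszmFeatureNames(),
         ngtdm = ngtdmFeatureNames(),
         gldm = gldmFeatureNames(),
         stopf("unknown feature class '%s'", fclass))
}

#' Enumerate the feature catalog
#'
#' Deterministic enumeration of the canonical feature identifiers for one
#' contrast: every enabled texture class under every image variant, plus the
#' shape features (original variant only; shape is computed from the mask
#' geometry and is contrast-independent). Under the reference configuration
#' this yields 18+22+16+16+5+14 = 91 texture features x 11 variants + 14
#' shape features = 1015 identifiers per contrast, i.e. 4060 values per
#' muscle group (2 contrasts x 2 sides) per subject.
#'
#' @param config an [extractionConfig()]
#' @return character vector of canonical identifiers, stable order
#' @export
featureCatalog <- function(config = extractionConfig()) {
  out <- character()
  if ("shape" %in% config$classes)
    out <- canonicalKey("original", "shape", shapeFeatureNames())
  tex <- intersect(textureClassNames(), config$classes)
  for (v in variantNames(config))
    for (cl in tex)
      out <- c(out, canonicalKey(v, cl, classFeatureNames(cl)))
  if (anyDuplicated(out)) stopf("catalog enumeration produced duplicates")
  out
}

#' Mean fat fraction over a mask
#'
#' `mean(fat / (water + fat))` over the mask voxels. Voxels with
#' non-positive total signal are excluded and counted; an empty mask or a
#' mask with only degenerate voxels is an error. The result is invariant to
#' joint rescaling of both contrasts.
#'
#' @param water,fat 3-D numeric arrays
#' @param mask 3-D logical array
#' @return fat fraction in \[0,1\]; the number of excluded voxels is attached
#'   as attribute `excluded`
#' @export
computeFatFraction <- function(water, fat, mask) {
  if (!any(mask)) stopf("mask is empty")
  w <- water[mask]
  f <- fat[mask]
  tot <- w + f
  ok <- tot > 0
  if (!any(ok)) stopf("all mask voxels have non-positive total signal")
  structure(mean(f[ok] / tot[ok]), excluded = sum(!ok))
}

# texture features of one discretized region
textureFeaturesForRegion <- function(vals, mask, dims, config, classes) {
  dz <- discretizeFixedWidth(vals[mask], config$binWidth)
  binImg <- array(0L, dims)
  binImg[mask] <- dz$bins
  maskV <- as.vector(mask)
  binV <- as.vector(binImg)
  nvox <- sum(mask)
  vvol <- prod(config$targetSpacing)
  out <- numeric()
  if ("firstorder" %in% classes)
    out <- c(out, stats::setNames(
      firstorderFeatures(vals[mask], dz$bins, dz$ng, vvol),
      canonicalKey("", "firstorder", firstorderFeatureNames())))
  if ("glcm" %in% classes)
    out <- c(out, stats::setNames(
      glcmFeatures(glcm_count_cpp(binV, maskV, dims, dz$ng)),
      canonicalKey("", "glcm", glcmFeatureNames())))
  if ("glrlm" %in% classes)
    out <- c(out, stats::setNames(
      glrlmFeatures(glrlm_count_cpp(binV, maskV, dims, dz$ng), nvox),
      canonicalKey("", "glrlm", glrlmFeatureNames())))
  if ("glszm" %in% classes) {
    z <- glszm_zones_cpp(binV, maskV, dims)
    out <- c(out, stats::setNames(
      glszmFeatures(z$gray, z$size, dz$ng, nvox),
      canonicalKey("", "glszm", glszmFeatureNames())))
  }
  if ("ngtdm" %in% classes)
    out <- c(out, stats::setNames(
      ngtdmFeatures(ngtdm_count_cpp(binV, maskV, dims, dz$ng)),
      canonicalKey("", "ngtdm", ngtdmFeatureNames())))
  if ("gldm" %in% classes)
    out <- c(out, stats::setNames(
      gldmFeatures(gldm_count_cpp(binV, maskV, dims, dz$ng, 0L)),
      canonicalKey("", "gldm", gldmFeatureNames())))
  out
}

cropBox <- function(mask, margin = 1L) {
  idx <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, dim(mask))
  list(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
}

#' Extract all features for one subject
#'
#' Runs the reference extraction on one subject: resampling both contrasts
#' and the labels to the target spacing, z-score normalization, image
#' variants (original, LoG, wavelet sub-bands), per-muscle/side/contrast
#' texture features over the eroded mask with fixed-bin-width
#' discretization, shape features from the uneroded pruned mask, and the
#' per-muscle/side fat fraction from the unnormalized contrasts.
#'
#' @param volumes \linkS4class{DixonVolumes}
#' @param labels \linkS4class{LabelVolume} (already component-pruned)
#' @param config an [extractionConfig()]
#' @return list with `features` (named numeric vector over instance keys
#'   `<muscle>|<side>|<contrast>|<canonical>`), `fatFraction` (data.frame
#'   muscle, side, ff) and `missing` (character vector of skipped regions
#'   with reasons, e.g. masks emptied by erosion)
#' @export
extractFeatures <- function(volumes, labels, config = extractionConfig()) {
  rs <- resampleGrid(volumes, config$targetSpacing)
  lr <- resampleGrid(labels, config$targetSpacing)
  er <- erodeMask(lr, config$erosionRadius)
  dims <- dim(labelArray(lr))
  lm <- labelMap(lr)
  contrasts <- list(water = waterVolume(rs), fat = fatVolume(rs))
  variants <- lapply(contrasts, function(g)
    imageVariants(normalizeGrid(g, config$normalizationScale), config,
                  config$targetSpacing))
  tex <- intersect(textureClassNames(), config$classes)
  features <- numeric()
  missing <- character()
  ffRows <- list()
  for (r in seq_len(nrow(lm))) {
    lv <- lm$label[r]; mus <- lm$muscle[r]; side <- lm$side[r]
    maskFull <- labelArray(lr) == lv
    maskEro <- labelArray(er$labels) == lv
    if (!any(maskFull)) { missing <- c(missing,
        sprintf("%s|%s: empty mask", mus, side)); next }
    if ("shape" %in% config$classes) {
      sf <- shapeFeatures(maskFull, config$targetSpacing)
      for (ct in names(contrasts))
        features[instanceKey(mus, side, ct,
          canonicalKey("original", "shape", shapeFeatureNames()))] <- sf
    }
    ff <- computeFatFraction(contrasts$water, contrasts$fat, maskFull)
    ffRows[[length(ffRows) + 1L]] <-
      data.frame(muscle = mus, side = side, ff = as.numeric(ff))
    if (!any(maskEro)) {
      missing <- c(missing, sprintf("%s|%s: mask emptied by erosion",
                                    mus, side))
      next
    }
    box <- cropBox(maskEro)
    msub <- maskEro[box$x, box$y, box$z, drop = FALSE]
    dsub <- dim(msub)
    for (ct in names(variants)) {
      for (v in names(variants[[ct]])) {
        vals <- variants[[ct]][[v]][box$x, box$y, box$z, drop = FALSE]
        tf <- textureFeaturesForRegion(vals, msub, dsub, config, tex)
        names(tf) <- instanceKey(mus, side, ct, paste0(v, names(tf)))
        features[names(tf)] <- tf
      }
    }
  }
  list(features = features,
       fatFraction = do.call(rbind, ffRows),
       missing = missing)
}

#' Extract a cohort feature table from phantom volumes
#'
#' Convenience wrapper: prunes, extracts and assembles the per-subject
#' feature vectors of a phantom cohort into a \linkS4class{MuscleFeatureTable}
#' whose colData carries the subject metadata and the per-muscle fat
#' fractions (`ff_<muscle>` columns plus their mean `ff`).
#'
#' @param cohort list as produced by the simulate stage: `meta` data.frame
#'   and per-subject `volumes`/`labels` lists
#' @param config an [extractionConfig()]
#' @param relThreshold component-pruning threshold
#' @return a \linkS4class{MuscleFeatureTable}
#' @export
extractCohortFeatures <- function(cohort, config = extractionConfig(),
                                  relThreshold = 0.025) {
  n <- nrow(cohort$meta)
  rows <- vector("list", n)
  ffs <- vector("list", n)
  for (i in seq_len(n)) {
    pruned <- removeSmallComponents(cohort$labels[[i]], relThreshold)
    ex <- extractFeatures(cohort$volumes[[i]], pruned$labels, config)
    rows[[i]] <- ex$features
    ffs[[i]] <- ex$fatFraction
  }
  keys <- names(rows[[1]])
  values <- do.call(rbind, lapply(rows, function(r) r[keys]))
  colnames(values) <- keys
  meta <- cohort$meta
  ffMuscle <- lapply(ffs, function(f)
    tapply(f$ff, f$muscle, mean))
  muscles <- sort(unique(ffs[[1]]$muscle))
  for (m in muscles)
    meta[[paste0("ff_", m)]] <- vapply(ffMuscle, function(x) x[[m]], 0)
  meta$ff <- rowMeans(as.matrix(meta[paste0("ff_", muscles)]))
  MuscleFeatureTable(values, meta)
}
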