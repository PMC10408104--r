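#' Extraction configuration
#'
#' Pins the reference extraction: resampling to 3x3x3 mm, z-score
#' normalization with a scale constant, two LoG sigmas (1 and 3 mm), one
#' level of a coiflet-1 separable 3-D wavelet decomposition (8 sub-bands),
#' fixed-bin-width gray-level discretization, and erosion radius 1. Under
#' this configuration the catalog enumerates 91 texture features x 11
#' variants + 14 shape features = 1015 identifiers per contrast.
#'
#' @param targetSpacing mm per axis after resampling
#' @param normalizationScale multiplier applied after z-scoring (intensity
#'   units of the normalized image)
#' @param logSigmas LoG filter widths in mm
#' @param binWidth gray-level discretization bin width, in normalized units
#' @param erosionRadius mask erosion radius (voxels) before texture
#'   extraction
#' @param classes texture/shape classes to enable
#' @return list of class `extractionConfig`
#' @export
extractionConfig <- function(targetSpacing = c(3, 3, 3),
                             normalizationScale = 100,
                             logSigmas = c(1, 3), binWidth = 25,
                             erosionRadius = 1,
                             classes = c("shape", "firstorder", "glcm",
                                         "glrlm", "glszm", "ngtdm", "gldm")) {
  if (any(targetSpacing <= 0)) stopf("target spacing must be positive")
  if (any(logSigmas <= 0)) stopf("LoG sigmas must be positive")
  if (binWidth <= 0) stopf("bin width must be positive")
  structure(list(targetSpacing = as.numeric(targetSpacing),
                 normalizationScale = normalizationScale,
                 logSigmas = logSigmas, binWidth = binWidth,
                 erosionRadius = erosionRadius, classes = classes),
            class = "extractionConfig")
}

#' Resample a volume or label grid to a target spacing
#'
#' Intensity grids are interpolated trilinearly, label grids with nearest
#' neighbour. The physical extent is preserved to within one voxel.
#'
#' @param x a \linkS4class{DixonVolumes} or \linkS4class{LabelVolume}
#' @param targetSpacing mm per axis (length 3)
#' @return same class as `x`, on the resampled grid
#' @export
resampleGrid <- function(x, targetSpacing) {
  if (any(targetSpacing <= 0)) stopf("target spacing must be positive")
  if (is(x, "DixonVolumes")) {
    DixonVolumes(
      water = resampleArray(waterVolume(x), voxelSpacing(x), targetSpacing,
                            nearest = FALSE),
      fat = resampleArray(fatVolume(x), voxelSpacing(x), targetSpacing,
                          nearest = FALSE),
      spacing = targetSpacing)
  } else if (is(x, "LabelVolume")) {
    lab <- resampleArray(labelArray(x), voxelSpacing(x), targetSpacing,
                         nearest = TRUE)
    storage.mode(lab) <- "integer"
    LabelVolume(lab, labelMap(x), targetSpacing)
  } else stopf("unsupported input class")
}

# Resample one 3-D array from spacing `sp` to `tsp` (voxel-centre aligned).
resampleArray <- function(a, sp, tsp, nearest = FALSE) {
  if (isTRUE(all.equal(as.numeric(sp), as.numeric(tsp)))) return(a)
  dIn <- dim(a)
  extent <- dIn * sp
  dOut <- pmax(1L, as.integer(round(extent / tsp)))
  # continuous input voxel coordinate of each output voxel centre
  coord <- lapply(1:3, function(ax)
    ((seq_len(dOut[ax]) - 0.5) * tsp[ax]) / sp[ax] + 0.5)
  if (nearest) {
    ix <- pmin(pmax(round(coord[[1]]), 1), dIn[1])
    iy <- pmin(pmax(round(coord[[2]]), 1), dIn[2])
    iz <- pmin(pmax(round(coord[[3]]), 1), dIn[3])
    return(a[ix, iy, iz, drop = FALSE])
  }
  lo <- lapply(1:3, function(ax) floor(coord[[ax]]))
  fr <- lapply(1:3, function(ax) coord[[ax]] - lo[[ax]])
  # edge replication: when both bounding indices clamp to the same voxel the
  # interpolation weight is irrelevant
  i0 <- lapply(1:3, function(ax) pmin(pmax(lo[[ax]], 1), dIn[ax]))
  i1 <- lapply(1:3, function(ax) pmin(pmax(lo[[ax]] + 1, 1), dIn[ax]))
  out <- array(0, dOut)
  wz <- fr[[3]]
  for (k in seq_len(dOut[3])) {
    z0 <- i0[[3]][k]; z1 <- i1[[3]][k]; fz <- wz[k]
    # bilinear in-plane on the two bounding slices, then linear in z
    plane <- function(zi) {
      s00 <- a[i0[[1]], i0[[2]], zi, drop = FALSE][, , 1]
      s10 <- a[i1[[1]], i0[[2]], zi, drop = FALSE][, , 1]
      s01 <- a[i0[[1]], i1[[2]], zi, drop = FALSE][, , 1]
      s11 <- a[i1[[1]], i1[[2]], zi, drop = FALSE][, , 1]
      fx <- fr[[1]]; fy <- fr[[2]]
      s00 * outer(1 - fx, 1 - fy) + s10 * outer(fx, 1 - fy) +
        s01 * outer(1 - fx, fy) + s11 * outer(fx, fy)
    }
    out[, , k] <- (1 - fz) * plane(z0) + fz * plane(z1)
  }
  out
}

#' Z-score normalize an intensity grid
#'
#' Centers to mean 0, scales to unit variance, then multiplies by the
#' configured scale constant. Constant grids are a degenerate input and
#' raise an error.
#'
#' @param grid 3-D numeric array
#' @param scale multiplier after standardization (default 100)
#' @return normalized array
#' @export
normalizeGrid <- function(grid, scale = 100) {
  s <- stats::sd(grid)
  if (!is.finite(s) || s == 0) stopf("cannot normalize a zero-variance grid")
  (grid - mean(grid)) / s * scale
}

gaussKernel1d <- function(sigmaVox) {
  r <- max(1L, ceiling(3.5 * sigmaVox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigmaVox^2))
  k / sum(k)
}

# second-derivative-of-Gaussian kernel (unnormalized scale handled by caller)
gaussDeriv2Kernel1d <- function(sigmaVox) {
  r <- max(2L, ceiling(3.5 * sigmaVox))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigmaVox^2))
  g <- g / sum(g)
  k <- (x^2 / sigmaVox^4 - 1 / sigmaVox^2) * g
  k - mean(k)  # zero DC gain: the response to a constant grid is exactly 0
}

convSep <- function(vol, kernels, mode = 0L) {
  dims <- dim(vol)
  v <- as.vector(vol)
  for (ax in 1:3) v <- conv_axis_cpp(v, dims, kernels[[ax]], ax - 1L, mode)
  array(v, dims)
}

#' Gaussian smoothing of a 3-D grid
#'
#' @param vol 3-D numeric array
#' @param sigmaMm Gaussian sigma in mm
#' @param spacing voxel spacing in mm
#' @return smoothed array
#' @export
gaussianSmooth <- function(vol, sigmaMm, spacing) {
  ks <- lapply(1:3, function(ax) gaussKernel1d(sigmaMm / spacing[ax]))
  convSep(vol, ks)
}

#' Laplacian-of-Gaussian filtered grid
#'
#' Separable scale-normalized LoG: the sum over axes of the second Gaussian
#' derivative along that axis with plain Gaussian smoothing along the other
#' two, multiplied by sigma^2.
#'
#' @param vol 3-D numeric array
#' @param sigmaMm filter width in mm (> 0)
#' @param spacing voxel spacing in mm
#' @return filtered array
#' @export
logFilter <- function(vol, sigmaMm, spacing) {
  if (sigmaMm <= 0) stopf("sigma must be positive")
  dims <- dim(vol)
  out <- array(0, dims)
  for (dax in 1:3) {
    ks <- lapply(1:3, function(ax) {
      sv <- sigmaMm / spacing[ax]
      if (ax == dax) gaussDeriv2Kernel1d(sv) else gaussKernel1d(sv)
    })
    out <- out + convSep(vol, ks)
  }
  # scale normalization in voxel units (kernels differentiate per voxel)
  (sigmaMm / prod(spacing)^(1 / 3))^2 * out
}

# coiflet-1 decomposition filters
coif1Lo <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
             0.852572020212255, 0.337897662457809, -0.072732619512854)
coif1Hi <- rev(coif1Lo) * rep_len(c(1, -1), length(coif1Lo))

#' Image variants for feature extraction
#'
#' Returns the original grid, one LoG-filtered grid per configured sigma and
#' the eight sub-bands of a one-level undecimated separable 3-D coiflet-1
#' wavelet decomposition (low/high-pass per axis, periodic boundary), all on
#' the original grid shape. Under the reference configuration this yields 11
#' variants.
#'
#' @param grid 3-D numeric array (already normalized)
#' @param config an [extractionConfig()]
#' @param spacing voxel spacing in mm
#' @return named list of arrays, names matching the variant tags
#'   (`original`, `log-sigma-1-0`, ..., `wavelet-lll`, ..., `wavelet-hhh`)
#' @export
imageVariants <- function(grid, config = extractionConfig(),
                          spacing = config$targetSpacing) {
  out <- list(original = grid)
  for (s in config$logSigmas) {
    tag <- sprintf("log-sigma-%s", gsub("\\.", "-", format(s, nsmall = 1)))
    out[[tag]] <- logFilter(grid, s, spacing)
  }
  for (bits in waveletBandOrder()) {
    ks <- lapply(strsplit(bits, "")[[1]], function(b)
      if (b == "l") coif1Lo else coif1Hi)
    out[[paste0("wavelet-", bits)]] <- convSep(grid, ks, mode = 1L)
  }
  out
}

waveletBandOrder <- function()
  c("lll", "llh", "lhl", "lhh", "hll", "hlh", "hhl", "hhh")

#' Names of the image variants under a configuration
#' @param config an [extractionConfig()]
#' @return character vector of variant tags
#' @export
variantNames <- function(config = extractionConfig()) {
  c("original",
    vapply(config$logSigmas, function(s)
      sprintf("log-sigma-%s", gsub("\\.", "-", format(s, nsmall = 1))), ""),
    paste0("wavelet-", waveletBandOrder()))
}
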