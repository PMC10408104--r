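# Morphological (shape) features of a binary mask. Computed on the pruned,
# uneroded mask: the erosion serves boundary-texture hygiene, not morphology.

shapeFeatureNames <- function() c(
  "meshvolume", "voxelvolume", "surfacearea", "surfacevolumeratio",
  "sphericity", "maximum3ddiameter", "maximum2ddiameterslice",
  "maximum2ddiametercolumn", "maximum2ddiameterrow", "majoraxislength",
  "minoraxislength", "leastaxislength", "elongation", "flatness")

# Surface area via the coarea formula on a Gaussian-mollified indicator:
# integral of |grad u| over the volume converges to the boundary area as the
# mollification width shrinks relative to the boundary curvature radius.
smoothedSurfaceArea <- function(mask, spacing, sigmaVox = 1.2) {
  u <- array(as.numeric(mask), dim(mask))
  ks <- lapply(1:3, function(ax) gaussKernel1d(sigmaVox))
  u <- convSep(u, ks)
  d <- dim(u)
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  gx[2:(d[1] - 1), , ] <- (u[3:d[1], , ] - u[1:(d[1] - 2), , ]) /
    (2 * spacing[1])
  gy[, 2:(d[2] - 1), ] <- (u[, 3:d[2], ] - u[, 1:(d[2] - 2), ]) /
    (2 * spacing[2])
  gz[, , 2:(d[3] - 1)] <- (u[, , 3:d[3]] - u[, , 1:(d[3] - 2)]) /
    (2 * spacing[3])
  sum(sqrt(gx^2 + gy^2 + gz^2)) * prod(spacing)
}

# boundary voxels: in mask with at least one face neighbour outside
boundaryVoxels <- function(mask) {
  dims <- dim(mask)
  er <- array(binary_erode_cpp(as.vector(mask), dims, 1L), dims)
  which(mask & !er, arr.ind = TRUE)
}

maxPairDist <- function(pts) {
  if (nrow(pts) < 2) return(0)
  if (nrow(pts) > 2500) { # deterministic thinning for very large surfaces
    keep <- seq(1, nrow(pts), length.out = 2500)
    pts <- pts[unique(as.integer(keep)), , drop = FALSE]
  }
  max(stats::dist(pts))
}

#' Shape features of one mask
#'
#' The 14 morphological descriptors: volumes, mollified-indicator surface
#' area, surface/volume ratio, sphericity, maximum 3-D diameter and the three
#' maximum in-plane diameters (projections), and the principal-axis lengths
#' with elongation and flatness from the eigenvalues of the voxel-coordinate
#' covariance.
#'
#' @param mask 3-D logical array
#' @param spacing voxel spacing in mm
#' @return named numeric vector of length 14
#' @export
shapeFeatures <- function(mask, spacing) {
  if (!any(mask)) stopf("mask is empty")
  nvox <- sum(mask)
  vvol <- prod(spacing)
  V <- nvox * vvol
  SA <- smoothedSurfaceArea(mask, spacing)
  bd <- boundaryVoxels(mask)
  if (nrow(bd) == 0) bd <- which(mask, arr.ind = TRUE)
  mm <- sweep(bd, 2, spacing[c(1, 2, 3)], "*")
  d3 <- maxPairDist(mm)
  d2slice <- maxPairDist(mm[, c(1, 2), drop = FALSE])  # ignore z
  d2col <- maxPairDist(mm[, c(1, 3), drop = FALSE])    # ignore y
  d2row <- maxPairDist(mm[, c(2, 3), drop = FALSE])    # ignore x
  coords <- which(mask, arr.ind = TRUE)
  coords <- sweep(coords, 2, spacing, "*")
  ev <- if (nvox > 1) {
    eigen(stats::cov(coords) * (nvox - 1) / nvox, symmetric = TRUE,
          only.values = TRUE)$values
  } else c(0, 0, 0)
  ev <- pmax(ev, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  c(meshvolume = V, voxelvolume = V, surfacearea = SA,
    surfacevolumeratio = SA / V,
    sphericity = (36 * pi * V^2)^(1 / 3) / SA,
    maximum3ddiameter = d3, maximum2ddiameterslice = d2slice,
    maximum2ddiametercolumn = d2col, maximum2ddiameterrow = d2row,
    majoraxislength = major, minoraxislength = minor,
    leastaxislength = least,
    elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}
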