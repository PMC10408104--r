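#' Remove small isolated components from a label volume
#'
#' For every label value independently, computes 26-connected components and
#' removes (sets to background) each component whose voxel count is strictly
#' below `relThreshold` times the voxel count of that label's largest
#' component. The largest component is always retained. Labels with no voxels
#' are skipped and noted in the report. The operation is idempotent.
#'
#' @param labels \linkS4class{LabelVolume}
#' @param relThreshold relative size threshold in (0,1), default 0.025
#' @return list(labels = pruned \linkS4class{LabelVolume}, report =
#'   data.frame of all components with columns label, component, size,
#'   removed, note)
#' @export
removeSmallComponents <- function(labels, relThreshold = 0.025) {
  if (relThreshold <= 0 || relThreshold >= 1)
    stopf("relThreshold must be in (0,1)")
  lab <- labelArray(labels)
  dims <- dim(lab)
  report <- list()
  for (lv in labelMap(labels)$label) {
    mask <- lab == lv
    if (!any(mask)) {
      report[[length(report) + 1L]] <- data.frame(
        label = lv, component = NA_integer_, size = 0L, removed = FALSE,
        note = "empty label, skipped")
      next
    }
    comp <- array(cc_label_cpp(as.vector(mask), dims, 26L), dims)
    sizes <- tabulate(comp[mask])
    largest <- max(sizes)
    for (ci in seq_along(sizes)) {
      rm <- sizes[ci] < relThreshold * largest
      if (rm) lab[comp == ci] <- 0L
      report[[length(report) + 1L]] <- data.frame(
        label = lv, component = ci, size = sizes[ci], removed = rm,
        note = "")
    }
  }
  list(labels = LabelVolume(lab, labelMap(labels), voxelSpacing(labels)),
       report = do.call(rbind, report))
}

#' Morphological erosion of a label volume
#'
#' Per-label binary erosion with a 3-D cross-shaped (face-connected)
#' structuring element of the given radius, applied before texture feature
#' extraction so that partial-volume boundary voxels are excluded. Radius 0
#' is the identity. Labels whose mask is emptied by the erosion are listed in
#' the `emptied` element.
#'
#' @param labels \linkS4class{LabelVolume}
#' @param radius erosion radius in voxels (>= 0), default 1
#' @return list(labels = eroded \linkS4class{LabelVolume}, emptied = integer
#'   vector of label values whose mask became empty)
#' @export
erodeMask <- function(labels, radius = 1) {
  if (radius < 0) stopf("radius must be >= 0")
  lab <- labelArray(labels)
  if (radius == 0) return(list(labels = labels, emptied = integer()))
  dims <- dim(lab)
  out <- array(0L, dims)
  emptied <- integer()
  for (lv in labelMap(labels)$label) {
    mask <- lab == lv
    if (!any(mask)) next
    er <- binary_erode_cpp(as.vector(mask), dims, as.integer(radius))
    if (!any(er)) emptied <- c(emptied, lv)
    out[er] <- lv  # arrays index linearly; no reshape needed
  }
  list(labels = LabelVolume(out, labelMap(labels), voxelSpacing(labels)),
       emptied = emptied)
}

#' Centroid of a mask, in voxel indices
#'
#' Arithmetic mean of the mask voxel coordinates, rounded to the nearest
#' voxel. Used to place the cross-sections of the consistency-check overlay.
#'
#' @param mask 3-D logical array
#' @return integer(3) voxel index
#' @export
maskCentroid <- function(mask) {
  if (!any(mask)) stopf("mask is empty")
  idx <- which(mask, arr.ind = TRUE)
  as.integer(round(colMeans(idx)))
}

mipPanel <- function(vol, mask, others, axis, main) {
  m <- apply(vol, setdiff(1:3, axis), max)
  mm <- apply(mask, setdiff(1:3, axis), max)
  graphics::image(m, col = grDevices::gray(seq(0, 1, length.out = 128)),
                  axes = FALSE, main = main, useRaster = TRUE)
  hl <- m; hl[] <- NA
  hl[mm > 0] <- 1
  graphics::image(hl, col = grDevices::adjustcolor("yellow", 0.45),
                  add = TRUE, useRaster = TRUE)
}

slicePanel <- function(vol, mask, others, axis, at, main) {
  sl <- switch(axis, `1` = vol[at, , ], `2` = vol[, at, ], `3` = vol[, , at])
  ms <- switch(axis, `1` = mask[at, , ], `2` = mask[, at, ],
               `3` = mask[, , at])
  os <- switch(axis, `1` = others[at, , ], `2` = others[, at, ],
               `3` = others[, , at])
  graphics::image(sl, col = grDevices::gray(seq(0, 1, length.out = 128)),
                  axes = FALSE, main = main, useRaster = TRUE)
  o <- sl; o[] <- NA; o[os] <- 1
  graphics::image(o, col = grDevices::adjustcolor("turquoise", 0.5),
                  add = TRUE, useRaster = TRUE)
  h <- sl; h[] <- NA; h[ms] <- 1
  graphics::image(h, col = grDevices::adjustcolor("yellow", 0.6),
                  add = TRUE, useRaster = TRUE)
}

#' Render a consistency-check overlay for one muscle
#'
#' Produces the 2x3 panel used for the manual consistency check: the top row
#' shows maximum intensity projections of the water contrast along the three
#' axes with the selected muscle mask highlighted; the bottom row shows
#' cross-sections through the mask centroid with the selected mask in yellow
#' and all other labels in turquoise.
#'
#' @param volumes \linkS4class{DixonVolumes}
#' @param labels \linkS4class{LabelVolume}
#' @param muscle muscle group name (must be present in the label map)
#' @param side `"left"` or `"right"`
#' @param file output PNG path
#' @return invisibly, the centroid voxel indices used for the cross-sections
#' @export
renderOverlay <- function(volumes, labels, muscle, side, file) {
  lm <- labelMap(labels)
  row <- lm[lm$muscle == muscle & lm$side == side, ]
  if (nrow(row) != 1L) stopf("muscle '%s' (%s) not in label map", muscle, side)
  lab <- labelArray(labels)
  mask <- lab == row$label
  if (!any(mask)) stopf("mask for muscle '%s' (%s) is empty", muscle, side)
  others <- lab != 0L & !mask
  ctr <- maskCentroid(mask)
  vol <- waterVolume(volumes)
  grDevices::png(file, width = 900, height = 620)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(2, 3), mar = c(1, 1, 2, 1))
  axesNames <- c("sagittal", "coronal", "axial")
  for (a in 1:3) mipPanel(vol, mask, others, a,
                          sprintf("MIP %s", axesNames[a]))
  for (a in 1:3) slicePanel(vol, mask, others, a, ctr[a],
                            sprintf("section %s @ %d", axesNames[a], ctr[a]))
  invisible(ctr)
}
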