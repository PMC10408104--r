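blockIdx <- function(dims, xs, ys, zs) {
  idx <- expand.grid(x = xs, y = ys, z = zs)
  (idx$z - 1) * dims[1] * dims[2] + (idx$y - 1) * dims[1] + idx$x
}

test_that("component pruning removes only sub-threshold components", {
  dims <- c(30, 30, 30)
  # single component: unchanged
  lv1 <- makeLabelVolume(dims, list(blockIdx(dims, 2:11, 2:11, 2:11)))
  out1 <- removeSmallComponents(lv1)
  expect_identical(labelArray(out1$labels), labelArray(lv1))

  # 1000 + 24 voxels: 24/1000 = 2.4% < 2.5% -> removed
  lv2 <- makeLabelVolume(dims, list(
    c(blockIdx(dims, 2:11, 2:11, 2:11),          # 1000 voxels
      blockIdx(dims, 20:23, 20:22, 20:21))))     # 24 voxels, disconnected
  out2 <- removeSmallComponents(lv2)
  expect_equal(sum(labelArray(out2$labels) == 1L), 1000)
  expect_true(any(out2$report$removed))

  # 1000 + 30 voxels: 3.0% >= 2.5% -> both kept
  lv3 <- makeLabelVolume(dims, list(
    c(blockIdx(dims, 2:11, 2:11, 2:11),
      blockIdx(dims, 20:24, 20:22, 20:21))))     # 30 voxels
  out3 <- removeSmallComponents(lv3)
  expect_equal(sum(labelArray(out3$labels) == 1L), 1030)
  expect_false(any(out3$report$removed))
})

test_that("pruning is idempotent and leaves other labels untouched", {
  dims <- c(30, 30, 30)
  lv <- makeLabelVolume(dims, list(
    c(blockIdx(dims, 2:11, 2:11, 2:11), blockIdx(dims, 20:21, 20:21, 20:21)),
    blockIdx(dims, 15:17, 2:4, 15:17)),
    labels = c(1, 2),
    map = data.frame(label = 1:2, muscle = c("a", "b"), side = "left"))
  once <- removeSmallComponents(lv)
  twice <- removeSmallComponents(once$labels)
  expect_identical(labelArray(once$labels), labelArray(twice$labels))
  expect_identical(which(labelArray(once$labels) == 2L),
                   which(labelArray(lv) == 2L))
})

test_that("empty labels are skipped with a note", {
  dims <- c(10, 10, 10)
  lv <- makeLabelVolume(dims, list(blockIdx(dims, 2:4, 2:4, 2:4)),
    map = data.frame(label = 1:2, muscle = c("a", "b"), side = "left"))
  out <- removeSmallComponents(lv)
  expect_true(any(grepl("empty label", out$report$note)))
})

test_that("erosion matches the cross-element definition", {
  cube <- array(0L, c(7, 7, 7)); cube[2:6, 2:6, 2:6] <- 1L
  lv <- LabelVolume(cube, data.frame(label = 1L, muscle = "m",
                                     side = "left"))
  expect_identical(labelArray(erodeMask(lv, 0)$labels), labelArray(lv))
  er <- erodeMask(lv, 1)
  expect_equal(sum(labelArray(er$labels) == 1L), 27)  # 5^3 cube -> 3^3
  # eroded mask is a subset of the original
  expect_true(all(labelArray(er$labels)[labelArray(lv) == 0L] == 0L))
  # erosion by 1 twice equals erosion by 2
  expect_identical(labelArray(erodeMask(er$labels, 1)$labels),
                   labelArray(erodeMask(lv, 2)$labels))
  # a 1-voxel sheet erodes to nothing and is flagged
  sheet <- array(0L, c(5, 5, 5)); sheet[, , 3] <- 1L
  lvs <- LabelVolume(sheet, data.frame(label = 1L, muscle = "m",
                                       side = "left"))
  es <- erodeMask(lvs, 1)
  expect_equal(es$emptied, 1L)
  expect_equal(sum(labelArray(es$labels)), 0)
})

test_that("overlay rendering produces the six-panel check image", {
  meta <- generateCohort(1, seed = 1)
  ph <- generatePhantom(meta, phantomSpec(), seed = 2)
  f <- tempfile(fileext = ".png")
  ctr <- renderOverlay(ph$volumes, ph$labels, "gluteus", "left", f)
  expect_true(file.exists(f) && file.info(f)$size > 0)
  mask <- labelArray(ph$labels) == 1L
  expect_identical(ctr, maskCentroid(mask))
  idx <- which(mask, arr.ind = TRUE)
  expect_identical(maskCentroid(mask), as.integer(round(colMeans(idx))))
  expect_error(renderOverlay(ph$volumes, ph$labels, "deltoid", "left",
                             tempfile()), "not in label map")
})
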