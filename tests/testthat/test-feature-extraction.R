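test_that("resampling preserves constants and linear ramps", {
  a <- array(5, c(8, 8, 8))
  dv <- DixonVolumes(a, a, spacing = c(2, 2, 2))
  out <- resampleGrid(dv, c(1, 1, 1))
  expect_equal(dim(waterVolume(out)), c(16, 16, 16))
  expect_true(all(waterVolume(out) == 5))

  # trilinear interpolation is exact on a linear ramp (interior voxels)
  ramp <- array(rep(seq_len(16), 16 * 16), c(16, 16, 16))
  rv <- resampleGrid(DixonVolumes(ramp, ramp, c(1, 1, 1)), c(2, 2, 2))
  w <- waterVolume(rv)
  interior <- w[2:7, 2:7, 2:7]
  # output centres sit at input coordinate 2i - 0.5 on the ramp
  expected <- array(rep(2 * (2:7) - 0.5, 36), c(6, 6, 6))
  expect_equal(interior, expected, tolerance = 1e-6)

  # labels resample by nearest neighbour and keep integer values
  lab <- array(0L, c(8, 8, 8)); lab[3:6, 3:6, 3:6] <- 1L
  lv <- LabelVolume(lab, data.frame(label = 1L, muscle = "m", side = "left"),
                    c(2, 2, 2))
  lr <- resampleGrid(lv, c(1, 1, 1))
  expect_true(all(labelArray(lr) %in% c(0L, 1L)))
  expect_equal(voxelSpacing(lr), c(1, 1, 1))
})

test_that("normalization standardizes and is affine invariant", {
  set.seed(1)
  x <- array(rnorm(1000), c(10, 10, 10))
  xs <- (x - mean(x)) / sd(x)
  expect_equal(normalizeGrid(xs, scale = 1), xs, tolerance = 1e-12)
  expect_equal(normalizeGrid(2 * xs + 3, scale = 1), xs, tolerance = 1e-12)
  expect_equal(mean(normalizeGrid(x, 100)), 0, tolerance = 1e-10)
  expect_equal(sd(normalizeGrid(x, 100)), 100, tolerance = 1e-10)
  expect_error(normalizeGrid(array(2, c(4, 4, 4))), "zero-variance")
})

test_that("image variants enumerate original, LoG and wavelet sub-bands", {
  cfg <- extractionConfig()
  expect_length(variantNames(cfg), 11)  # 1 + 2 + 8
  const <- array(3, c(12, 12, 12))
  v <- imageVariants(const, cfg, c(3, 3, 3))
  expect_named(v, variantNames(cfg))
  # LoG of a constant is zero; lll of a constant is constant
  expect_true(all(abs(v[["log-sigma-1-0"]]) < 1e-10))
  expect_true(all(abs(v[["log-sigma-3-0"]]) < 1e-10))
  expect_lt(diff(range(v[["wavelet-lll"]])), 1e-10)
  expect_error(extractionConfig(logSigmas = -1), "positive")
})

test_that("the reference catalog reproduces the published counts", {
  cat <- featureCatalog()
  expect_length(cat, 1015)
  expect_false(anyDuplicated(cat) > 0)
  expect_identical(cat, featureCatalog())  # stable enumeration
  expect_length(featureCatalog(extractionConfig(classes = "shape")), 14)
  expect_true("original_gldm_largedependencehighgraylevelemphasis" %in% cat)
  expect_true("wavelet-lhl_gldm_largedependencehighgraylevelemphasis" %in% cat)
  expect_true("original_shape_elongation" %in% cat)
})

test_that("fat fraction follows its definition and invariances", {
  mask <- array(FALSE, c(2, 2, 1)); mask[1:2, 1, 1] <- TRUE
  w <- array(0, c(2, 2, 1)); f <- array(0, c(2, 2, 1))
  w[1, 1, 1] <- 4; f[1, 1, 1] <- 1   # ff 0.2
  w[2, 1, 1] <- 1; f[2, 1, 1] <- 1   # ff 0.5
  expect_equal(as.numeric(computeFatFraction(w, f, mask)), 0.35)

  z <- array(0, c(2, 2, 1))
  expect_equal(as.numeric(computeFatFraction(w, z, mask)), 0)
  expect_equal(as.numeric(computeFatFraction(w, w, mask)), 0.5)
  # invariant under joint rescaling
  expect_equal(as.numeric(computeFatFraction(3 * w, 3 * f, mask)),
               as.numeric(computeFatFraction(w, f, mask)))
  expect_error(computeFatFraction(w, f, array(FALSE, c(2, 2, 1))), "empty")
  # degenerate voxels excluded and counted
  w2 <- w; f2 <- f; w2[2, 1, 1] <- 0; f2[2, 1, 1] <- 0
  r <- computeFatFraction(w2, f2, mask)
  expect_equal(as.numeric(r), 0.2)
  expect_equal(attr(r, "excluded"), 1)
})

test_that("constant regions give zero entropy and variance", {
  vals <- array(7, c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  tf <- myotexture:::textureFeaturesForRegion(vals, mask, c(4L, 4L, 4L),
    extractionConfig(), c("firstorder"))
  expect_equal(unname(tf["_firstorder_entropy"]), 0)
  expect_equal(unname(tf["_firstorder_variance"]), 0)
})

test_that("co-occurrence features agree with brute-force counting", {
  # 4x4x1 two-gray-level checkerboard
  img <- array(0L, c(4, 4, 1))
  img[] <- as.integer((row(matrix(0, 4, 4)) + col(matrix(0, 4, 4))) %% 2) + 1L
  mask <- array(TRUE, c(4, 4, 1))
  Poracle <- bruteGLCM(img, mask, 2)
  p <- Poracle / sum(Poracle)
  i <- row(p); j <- col(p)
  contrastOracle <- sum((i - j)^2 * p)

  vals <- array(as.numeric(img) * 25, c(4, 4, 1))  # two bins of width 25
  tf <- myotexture:::textureFeaturesForRegion(vals, mask, c(4L, 4L, 1L),
    extractionConfig(), "glcm")
  expect_equal(unname(tf["_glcm_contrast"]), contrastOracle)

  # random image: the whole co-occurrence matrix matches the oracle
  set.seed(8)
  rimg <- array(sample(1:4, 5 * 4 * 3, TRUE), c(5, 4, 3))
  rmask <- array(runif(60) < 0.8, c(5, 4, 3))
  rmask[1, 1, 1] <- TRUE
  P1 <- myotexture:::glcm_count_cpp(as.integer(rimg), as.vector(rmask),
                                    c(5L, 4L, 3L), 4L)
  expect_equal(unname(P1), unname(bruteGLCM(rimg, rmask, 4)))
})

test_that("co-occurrence accumulation is symmetric under transposition", {
  set.seed(3)
  vals <- array(rnorm(4 * 4 * 4) * 60, c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  tf1 <- myotexture:::textureFeaturesForRegion(vals, mask, c(4L, 4L, 4L),
    extractionConfig(), "glcm")
  tvals <- aperm(vals, c(2, 1, 3))
  tf2 <- myotexture:::textureFeaturesForRegion(tvals, mask, c(4L, 4L, 4L),
    extractionConfig(), "glcm")
  expect_equal(tf1, tf2, tolerance = 1e-12)
})

test_that("digital sphere shape features approach the analytic limit", {
  n <- 48; ctr <- (n + 1) / 2
  xs <- seq_len(n)
  d2 <- outer(outer((xs - ctr)^2, (xs - ctr)^2, "+"), (xs - ctr)^2, "+")
  mask <- d2 <= 20^2
  sf <- shapeFeatures(mask, c(1, 1, 1))
  expect_lt(abs(sf[["sphericity"]] - 1), 0.02)
  expect_lt(abs(sf[["voxelvolume"]] / (4 / 3 * pi * 20^3) - 1), 0.01)
  expect_lt(abs(sf[["surfacearea"]] / (4 * pi * 20^2) - 1), 0.02)
  expect_lt(abs(sf[["elongation"]] - 1), 0.02)  # isotropic
})

test_that("masks emptied by erosion are flagged as missing, not zeros", {
  meta <- generateCohort(1, seed = 1)
  # one muscle too thin to survive erosion at 3 mm voxels
  spec <- phantomSpec(muscles = data.frame(
    muscle = c("gluteus", "thin"),
    cx = c(24, 30), cy = c(30, 70), cz = c(60, 30),
    rx = c(14, 10), ry = c(12, 10), rz = c(12, 2.5)))
  ph <- generatePhantom(meta, spec, seed = 2)
  ex <- extractFeatures(ph$volumes, ph$labels)
  expect_true(any(grepl("emptied by erosion", ex$missing)))
  expect_false(any(grepl("thin", names(ex$features)) &
                     grepl("glcm", names(ex$features))))
})

test_that("feature values ignore relabeling of other structures", {
  meta <- generateCohort(1, seed = 3)
  ph <- generatePhantom(meta, phantomSpec(), seed = 4)
  ex1 <- extractFeatures(ph$volumes, ph$labels)
  # merge two unrelated labels into one: gluteus values must not change
  lab <- labelArray(ph$labels)
  lab[lab == 4L] <- 3L
  lm <- labelMap(ph$labels)
  lm <- lm[lm$label != 4L, ]
  ex2 <- extractFeatures(ph$volumes,
                         LabelVolume(lab, lm, voxelSpacing(ph$labels)))
  g1 <- ex1$features[grepl("^gluteus\\|left", names(ex1$features))]
  g2 <- ex2$features[grepl("^gluteus\\|left", names(ex2$features))]
  expect_equal(g1, g2)
})
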