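test_that("cohort generation is deterministic and respects the age range", {
  a <- generateCohort(1, seed = 7)
  b <- generateCohort(1, seed = 7)
  expect_identical(a, b)

  big <- generateCohort(10000, seed = 1)
  expect_gte(min(big$age), 20)
  expect_lte(max(big$age), 69)
  expect_setequal(unique(generateCohort(10, seed = 3)$sex),
                  c("male", "female"))
  expect_error(generateCohort(0, seed = 1), "at least 1")
})

test_that("BMI calibration matches the generating distribution", {
  big <- generateCohort(10000, seed = 1, bmiMean = 26.81, bmiSd = 4.71)
  se <- 4.71 / sqrt(10000)
  expect_lt(abs(mean(big$bmi) - 26.81), 3 * se)
  expect_true(all(abs(big$bmi - big$weight / big$height^2) < 1e-9))
  expect_true(all(big$age > 0 & big$height > 0 & big$weight > 0))
})

test_that("phantom fat content follows the voxelwise model", {
  meta <- generateCohort(1, seed = 2)
  meta$age <- 60
  noiseless <- function(intercept, ageCoef = 0) phantomSpec(
    ffModel = data.frame(
      muscle = c("gluteus", "psoas", "extensors", "adductors"),
      intercept = intercept, ageCoef = ageCoef, bmiCoef = 0,
      noiseSd = 0, subjectSd = 0),
    textureAmplitude = 0, textureAmpSubjectSd = 0, noiseSd = 0)

  ph0 <- generatePhantom(meta, noiseless(0), seed = 5)
  inside <- labelArray(ph0$labels) > 0
  expect_true(all(fatVolume(ph0$volumes)[inside] == 0))

  ph5 <- generatePhantom(meta, noiseless(0.5), seed = 5)
  inside <- labelArray(ph5$labels) > 0
  expect_equal(waterVolume(ph5$volumes)[inside],
               fatVolume(ph5$volumes)[inside])

  # ff = 0.1 + 0.005 (age - 20) at age 60 -> 0.30 (reparametrized to the
  # model's age centring at 45)
  ph <- generatePhantom(meta, noiseless(0.225, ageCoef = 0.005), seed = 5)
  inside <- labelArray(ph$labels) > 0
  w <- waterVolume(ph$volumes)[inside]
  f <- fatVolume(ph$volumes)[inside]
  expect_equal(mean(f / (w + f)), 0.30, tolerance = 1e-8)
})

test_that("left and right labels are mirror images about the mid-sagittal plane", {
  meta <- generateCohort(1, seed = 9)
  ph <- generatePhantom(meta, phantomSpec(), seed = 4)
  lab <- labelArray(ph$labels)
  flipped <- lab[dim(lab)[1]:1, , ]
  lm <- labelMap(ph$labels)
  # reflection maps each left label onto its right partner exactly
  for (g in unique(lm$muscle)) {
    l <- lm$label[lm$muscle == g & lm$side == "left"]
    r <- lm$label[lm$muscle == g & lm$side == "right"]
    expect_identical(which(flipped == l), which(lab == r))
  }
})

test_that("out-of-grid ellipsoids are rejected", {
  expect_error(phantomSpec(muscles = data.frame(
    muscle = "gluteus", cx = 5, cy = 48, cz = 48,
    rx = 20, ry = 10, rz = 10)), "outside the grid")
})

test_that("artifact injection follows the configured rates", {
  meta <- generateCohort(1, seed = 2)
  spec0 <- phantomSpec()
  ph <- generatePhantom(meta, spec0, seed = 1)

  none <- injectArtifacts(ph$volumes, ph$labels, spec0, seed = 3)
  expect_identical(waterVolume(none$volumes), waterVolume(ph$volumes))
  expect_identical(labelArray(none$labels), labelArray(ph$labels))
  expect_equal(nrow(none$log), 0)

  swapSpec <- phantomSpec(swapRate = 1)
  sw <- injectArtifacts(ph$volumes, ph$labels, swapSpec, seed = 3)
  expect_identical(waterVolume(sw$volumes), fatVolume(ph$volumes))
  expect_true("fat_water_swap" %in% sw$log$artifact)

  straySpec <- phantomSpec(strayComponentRate = 1)
  st <- injectArtifacts(ph$volumes, ph$labels, straySpec, seed = 3)
  expect_true("stray_component" %in% st$log$artifact)
  labBefore <- labelArray(ph$labels)
  labAfter <- labelArray(st$labels)
  changed <- which(labAfter != labBefore)
  target <- unique(labAfter[changed])
  expect_length(target, 1)
  # exactly one extra component, strictly below 2.5% of the largest
  nComp <- function(lab, lv) {
    pr <- removeSmallComponents(
      LabelVolume(lab, labelMap(ph$labels), c(1, 1, 1)),
      relThreshold = 1e-9)
    sub <- pr$report[pr$report$label == lv & !is.na(pr$report$component), ]
    sub$size
  }
  before <- nComp(labBefore, target)
  after <- nComp(labAfter, target)
  expect_length(after, length(before) + 1)
  expect_lt(min(after), 0.025 * max(after))
})

test_that("planted feature tables realize the requested structure", {
  # perfect block: all three columns identical up to scale
  tab <- generateFeatureTable(plantedTableSpec(
    nSubjects = 100, nFeatures = 3,
    clusterBlocks = list(list(size = 3, rho = 1)), seed = 1))
  v <- featureValues(tab)
  left <- v[, 1:3]
  cc <- cor(left)
  expect_true(all(abs(cc - 1) < 1e-12))

  # zero reliability: |left/right r| below the sampling bound
  tab0 <- generateFeatureTable(plantedTableSpec(
    nSubjects = 5000, nFeatures = 1, lrReliability = 0, seed = 2))
  v0 <- featureValues(tab0)
  expect_lt(abs(cor(v0[, 1], v0[, 2])), 0.05)

  # pure signal: correlation 1 with its target
  tab1 <- generateFeatureTable(plantedTableSpec(
    nSubjects = 200, nFeatures = 1, noiseSd = 0,
    signalFeatures = list(age = list(idx = 1, effect = 1)), seed = 3))
  expect_equal(abs(cor(featureValues(tab1)[, 1], subjectMeta(tab1)$age)), 1,
               tolerance = 1e-10)

  # realized block correlation within Monte-Carlo tolerance (sides carry the
  # latent exactly at reliability 1)
  tab2 <- generateFeatureTable(plantedTableSpec(
    nSubjects = 2000, nFeatures = 6,
    clusterBlocks = list(list(size = 3, rho = 0.6)),
    lrReliability = 1, seed = 4))
  v2 <- featureValues(tab2)
  cc2 <- cor(v2[, 1:3])
  expect_true(all(abs(cc2[upper.tri(cc2)] - 0.6) < 0.05))

  # realized left/right reliability within Monte-Carlo tolerance; the
  # side-level block correlation attenuates to r * rho
  tab3 <- generateFeatureTable(plantedTableSpec(
    nSubjects = 2000, nFeatures = 6,
    clusterBlocks = list(list(size = 3, rho = 0.6)),
    lrReliability = 0.8, seed = 4))
  v3 <- featureValues(tab3)
  for (j in 1:6)
    expect_lt(abs(cor(v3[, j], v3[, j + 6]) - 0.8), 0.05)
  cc3 <- cor(v3[, 1:3])
  expect_true(all(abs(cc3[upper.tri(cc3)] - 0.8 * 0.6) < 0.05))

  expect_error(plantedTableSpec(10, 2,
    clusterBlocks = list(list(size = 5, rho = 0.5))), "exceed")
  expect_error(plantedTableSpec(10, 2,
    signalFeatures = list(age = list(idx = 7, effect = 1))), "out of range")
})
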