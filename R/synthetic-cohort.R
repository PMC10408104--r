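#' Generate synthetic subject metadata
#'
#' Draws a cohort of adult subjects with age uniform on a configurable range,
#' sex from a Bernoulli split, and per-sex lognormal heights. BMI is drawn
#' lognormal, calibrated so that its mean and standard deviation match the
#' configured values; weight is derived as bmi * height^2 so that the
#' invariant bmi == weight/height^2 holds exactly.
#'
#' @param n number of subjects (>= 1)
#' @param seed integer seed; the draw is a pure function of (arguments, seed)
#' @param ageRange age bounds in years, default c(20, 69)
#' @param maleProb probability of male sex, default 0.514
#' @param bmiMean,bmiSd target BMI mean and sd in kg/m^2
#' @param heightMean named c(male=, female=) mean height in m
#' @param heightSd named height sd in m
#' @return data.frame with columns subject_id, sex, age, height, weight, bmi
#' @export
generateCohort <- function(n, seed, ageRange = c(20, 69), maleProb = 0.514,
                           bmiMean = 26.81, bmiSd = 4.71,
                           heightMean = c(male = 1.78, female = 1.65),
                           heightSd = c(male = 0.07, female = 0.065)) {
  if (n < 1) stopf("n must be at least 1")
  with_seed(seed, {
    sex <- ifelse(stats::runif(n) < maleProb, "male", "female")
    age <- stats::runif(n, ageRange[1], ageRange[2])
    hm <- heightMean[sex]
    hs <- heightSd[sex]
    # lognormal parametrized to hit the requested arithmetic mean/sd
    hsl2 <- log(1 + (hs / hm)^2)
    height <- stats::rlnorm(n, log(hm) - hsl2 / 2, sqrt(hsl2))
    bsl2 <- log(1 + (bmiSd / bmiMean)^2)
    bmi <- stats::rlnorm(n, log(bmiMean) - bsl2 / 2, sqrt(bsl2))
    weight <- bmi * height^2
    data.frame(subject_id = sprintf("S%05d", seq_len(n)),
               sex = sex, age = age, height = height, weight = weight,
               bmi = weight / height^2, stringsAsFactors = FALSE)
  })
}

#' Specification of the phantom cohort
#'
#' Defines the voxel grid, the bilateral ellipsoidal muscle regions, the
#' per-muscle fat-fraction model (intercept + age and BMI coefficients on the
#' voxelwise fat proportion), the texture model and artifact-injection rates.
#' Right-side ellipsoids are mirror images of the left about the mid-sagittal
#' plane (first axis).
#'
#' @param gridShape integer(3), voxels per axis
#' @param spacing voxel spacing in mm
#' @param muscles data.frame of left-side ellipsoids: muscle, cx, cy, cz (mm),
#'   rx, ry, rz (mm). Defaults to four groups (gluteus, psoas, extensors,
#'   adductors) filling the default 96 mm grid.
#' @param ffModel data.frame per muscle: intercept, ageCoef (per year, centred
#'   at 45 y), bmiCoef (per kg/m^2, centred at 26.8), voxelwise noise sd, and
#'   subjectSd (between-subject sd of a random fat-fraction offset shared by
#'   the left and right side, emulating biological variation). Defaults are
#'   calibrated so that cohort-average fat fractions sit near typical in-vivo
#'   muscle values.
#' @param textureAmplitude sd of the structured (correlated) part of the
#'   voxelwise fat proportion
#' @param textureAmpSubjectSd lognormal sd of a per-subject multiplier on the
#'   texture amplitude, shared by all muscles and sides (between-subject
#'   variation in texture granularity)
#' @param textureCorrBase,textureCorrAgeCoef correlation length of the texture
#'   field in mm: base + coef * (age - 45)
#' @param noiseSd additive intensity noise sd (signal units)
#' @param signalScale total Dixon signal inside muscle (arbitrary units)
#' @param strayComponentRate,swapRate per-subject artifact probabilities
#' @return list of class `phantomSpec`
#' @export
phantomSpec <- function(gridShape = c(32, 32, 32), spacing = c(3, 3, 3),
                        muscles = NULL, ffModel = NULL,
                        textureAmplitude = 0.05, textureAmpSubjectSd = 0.5,
                        textureCorrBase = 3.5,
                        textureCorrAgeCoef = 0.06, noiseSd = 2,
                        signalScale = 500,
                        strayComponentRate = 0, swapRate = 0) {
  if (is.null(muscles)) {
    muscles <- data.frame(
      muscle = c("gluteus", "psoas", "extensors", "adductors"),
      cx = c(24, 32, 24, 36), cy = c(28, 64, 32, 66),
      cz = c(68, 72, 26, 28),
      rx = c(15, 10, 14, 11), ry = c(14, 10, 14, 11),
      rz = c(13, 15, 16, 15))
  }
  if (is.null(ffModel)) {
    canonical <- data.frame(
      muscle = c("gluteus", "psoas", "extensors", "adductors"),
      intercept = c(0.279, 0.234, 0.121, 0.199),
      ageCoef = c(0.0022, 0.0018, 0.0012, 0.0018),
      bmiCoef = c(0.0045, 0.0035, 0.0020, 0.0035),
      noiseSd = c(0.04, 0.04, 0.03, 0.04),
      subjectSd = c(0.06, 0.06, 0.05, 0.06))
    m <- match(muscles$muscle, canonical$muscle)
    ffModel <- canonical[ifelse(is.na(m), 1L, m), ]
    ffModel$muscle <- muscles$muscle
    rownames(ffModel) <- NULL
  }
  if (!identical(sort(ffModel$muscle), sort(muscles$muscle)))
    stopf("ffModel muscles must match the muscle definitions")
  spec <- list(gridShape = as.integer(gridShape), spacing = as.numeric(spacing),
               muscles = muscles, ffModel = ffModel,
               textureAmplitude = textureAmplitude,
               textureAmpSubjectSd = textureAmpSubjectSd,
               textureCorrBase = textureCorrBase,
               textureCorrAgeCoef = textureCorrAgeCoef,
               noiseSd = noiseSd, signalScale = signalScale,
               strayComponentRate = strayComponentRate, swapRate = swapRate)
  class(spec) <- "phantomSpec"
  validatePhantomSpec(spec)
  spec
}

validatePhantomSpec <- function(spec) {
  extent <- spec$gridShape * spec$spacing
  m <- spec$muscles
  for (i in seq_len(nrow(m))) {
    lo <- c(m$cx[i] - m$rx[i], m$cy[i] - m$ry[i], m$cz[i] - m$rz[i])
    hi <- c(m$cx[i] + m$rx[i], m$cy[i] + m$ry[i], m$cz[i] + m$rz[i])
    hiR <- extent[1] - (m$cx[i] - m$rx[i])
    if (any(lo < 0) || any(hi > extent) || hiR > extent[1])
      stopf("ellipsoid for muscle '%s' lies outside the grid", m$muscle[i])
  }
  rates <- c(spec$strayComponentRate, spec$swapRate)
  if (any(rates < 0 | rates > 1)) stopf("artifact rates must be in [0,1]")
  invisible(spec)
}

# Integer labels: left then right per muscle group, in muscles order.
phantomLabelMap <- function(spec) {
  m <- spec$muscles$muscle
  data.frame(label = seq_len(2 * length(m)),
             muscle = rep(m, each = 2),
             side = rep(c("left", "right"), length(m)),
             stringsAsFactors = FALSE)
}

# Voxel-centre coordinates (mm) along each axis.
axisCoords <- function(n, sp) (seq_len(n) - 0.5) * sp

#' Generate one subject's phantom volumes
#'
#' Builds the label volume from the mirrored ellipsoid definitions and
#' synthesizes water/fat intensities such that inside each muscle the
#' expected voxelwise fat proportion equals the subject's fat-fraction model
#' prediction (intercept + age and BMI terms), modulated by a Gaussian random
#' texture field whose correlation length depends on age. With all noise
#' terms zero the voxelwise fat/(water+fat) equals the model prediction
#' exactly.
#'
#' @param meta single-row data.frame as from [generateCohort()]
#' @param spec a [phantomSpec()]
#' @param seed integer seed
#' @return list with elements `volumes` (\linkS4class{DixonVolumes}),
#'   `labels` (\linkS4class{LabelVolume}) and `truth` (per-muscle data.frame
#'   of the generating fat proportion and texture correlation length)
#' @export
generatePhantom <- function(meta, spec, seed) {
  validatePhantomSpec(spec)
  dims <- spec$gridShape
  sp <- spec$spacing
  extent <- dims * sp
  xs <- axisCoords(dims[1], sp[1])
  ys <- axisCoords(dims[2], sp[2])
  zs <- axisCoords(dims[3], sp[3])
  lab <- array(0L, dims)
  lm <- phantomLabelMap(spec)
  for (i in seq_len(nrow(spec$muscles))) {
    m <- spec$muscles[i, ]
    for (side in 1:2) {
      cx <- if (side == 1) m$cx else extent[1] - m$cx
      d2 <- outer(outer(((xs - cx) / m$rx)^2, ((ys - m$cy) / m$ry)^2, "+"),
                  ((zs - m$cz) / m$rz)^2, "+")
      lab[d2 <= 1] <- 2L * (i - 1L) + side
    }
  }
  ffm <- spec$ffModel[match(spec$muscles$muscle, spec$ffModel$muscle), ]
  corrLen <- max(spec$spacing[1],
                 spec$textureCorrBase +
                   spec$textureCorrAgeCoef * (meta$age - 45))
  with_seed(seed, {
    field <- array(stats::rnorm(prod(dims)), dims)
    field <- gaussianSmooth(field, sigmaMm = corrLen, spacing = sp)
    field <- (field - mean(field)) / stats::sd(field)
    ampMult <- if (spec$textureAmpSubjectSd > 0)
      stats::rlnorm(1, 0, spec$textureAmpSubjectSd) else 1
    ff <- array(0, dims)
    truth <- data.frame(muscle = ffm$muscle, ffMean = NA_real_,
                        corrLength = corrLen,
                        textureAmp = spec$textureAmplitude * ampMult)
    for (i in seq_len(nrow(ffm))) {
      mu <- ffm$intercept[i] + ffm$ageCoef[i] * (meta$age - 45) +
        ffm$bmiCoef[i] * (meta$bmi - 26.8)
      # between-subject biological variation, shared by both sides
      if (!is.null(ffm$subjectSd) && ffm$subjectSd[i] > 0)
        mu <- mu + stats::rnorm(1, 0, ffm$subjectSd[i])
      mu <- min(max(mu, 0), 1)
      truth$ffMean[i] <- mu
      sel <- lab %in% c(2L * i - 1L, 2L * i)
      vox <- mu + ampMult * spec$textureAmplitude * field[sel]
      if (ffm$noiseSd[i] > 0)
        vox <- vox + stats::rnorm(sum(sel), 0, ffm$noiseSd[i])
      ff[sel] <- pmin(pmax(vox, 0), 1)
    }
    S <- spec$signalScale
    water <- array(0, dims)
    fat <- array(0, dims)
    inside <- lab > 0L
    water[inside] <- S * (1 - ff[inside])
    fat[inside] <- S * ff[inside]
    # surrounding tissue: fat-dominated background shell
    water[!inside] <- 0.2 * S
    fat[!inside] <- 0.55 * S
    if (spec$noiseSd > 0) {
      water <- water + array(stats::rnorm(prod(dims), 0, spec$noiseSd), dims)
      fat <- fat + array(stats::rnorm(prod(dims), 0, spec$noiseSd), dims)
    }
    water <- pmax(water, 0)
    fat <- pmax(fat, 0)
    list(volumes = DixonVolumes(water, fat, sp),
         labels = LabelVolume(lab, lm, sp),
         truth = truth)
  })
}

#' Inject simulated acquisition/segmentation artifacts
#'
#' With probability `swapRate` the water and fat grids are exchanged
#' (emulating a fat-water swap of the Dixon reconstruction); with probability
#' `strayComponentRate` a small disconnected blob (strictly below 2.5% of the
#' largest connected component of a randomly chosen label) is added to that
#' label. Every injected artifact is recorded in the returned log.
#'
#' @param volumes \linkS4class{DixonVolumes}
#' @param labels \linkS4class{LabelVolume}
#' @param spec a [phantomSpec()] carrying the rates
#' @param seed integer seed
#' @return list(volumes, labels, log) where log is a data.frame of artifacts
#' @export
injectArtifacts <- function(volumes, labels, spec, seed) {
  rates <- c(spec$swapRate, spec$strayComponentRate)
  if (any(rates < 0 | rates > 1)) stopf("artifact rates must be in [0,1]")
  log <- data.frame(artifact = character(), detail = character(),
                    stringsAsFactors = FALSE)
  with_seed(seed, {
    if (stats::runif(1) < spec$swapRate) {
      volumes <- DixonVolumes(water = fatVolume(volumes),
                              fat = waterVolume(volumes),
                              spacing = voxelSpacing(volumes))
      log <- rbind(log, data.frame(artifact = "fat_water_swap", detail = ""))
    }
    if (stats::runif(1) < spec$strayComponentRate) {
      lab <- labelArray(labels)
      dims <- dim(lab)
      present <- sort(setdiff(unique(as.integer(lab)), 0L))
      target <- present[sample.int(length(present), 1L)]
      comp <- cc_label_cpp(as.vector(lab == target), dims, 26L)
      largest <- max(tabulate(comp))
      # strictly below the 2.5% pruning threshold; capped so the blob fits
      # inside the guaranteed-background margin below
      blobMax <- min(max(1L, ceiling(0.025 * largest) - 1L), 100L)
      blobSize <- sample.int(blobMax, 1L)
      # seed voxels whose whole Manhattan-5 neighbourhood is background: a
      # blob of Euclidean radius <= 3 grown there cannot touch any label
      deep <- binary_erode_cpp(as.vector(lab == 0L), dims, 5L)
      cand <- which(array(deep, dims))
      seedVox <- cand[sample.int(length(cand), 1L)]
      sv <- as.numeric(arrayInd(seedVox, dims))
      bg <- which(lab == 0L)
      bgIdx <- arrayInd(bg, dims)
      dAll <- sqrt((bgIdx[, 1] - sv[1])^2 + (bgIdx[, 2] - sv[2])^2 +
                     (bgIdx[, 3] - sv[3])^2)
      ord <- order(dAll, bg)
      lab[bg[ord[seq_len(blobSize)]]] <- target
      labels <- LabelVolume(lab, labelMap(labels), voxelSpacing(labels))
      log <- rbind(log, data.frame(
        artifact = "stray_component",
        detail = sprintf("label=%d size=%d largest=%d", target, blobSize,
                         largest)))
    }
    list(volumes = volumes, labels = labels, log = log)
  })
}
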