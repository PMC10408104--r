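# IBSI-aligned texture feature formulas, computed from the counting matrices
# produced by the C++ kernels. Gray levels are 1..Ng bin numbers from
# fixed-bin-width discretization; co-occurrences and runs are accumulated
# (merged) over the 13 unique 3-D directions before feature computation.

log2safe <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- log2(x[pos])
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' Discretize intensities with a fixed bin width
#'
#' Bin numbers are `floor((x - min(x)) / w) + 1`, as used for all gray-level
#' matrix features.
#'
#' @param x numeric vector of ROI intensities
#' @param binWidth bin width in intensity units
#' @return list(bins = integer bin numbers starting at 1, ng = number of bins)
#' @export
discretizeFixedWidth <- function(x, binWidth) {
  b <- as.integer(floor((x - min(x)) / binWidth)) + 1L
  list(bins = b, ng = max(b))
}

firstorderFeatureNames <- function() c(
  "energy", "totalenergy", "entropy", "minimum", "10percentile",
  "90percentile", "maximum", "mean", "median", "interquartilerange",
  "range", "meanabsolutedeviation", "robustmeanabsolutedeviation",
  "rootmeansquared", "skewness", "kurtosis", "variance", "uniformity")

firstorderFeatures <- function(x, bins, ng, voxelVolume) {
  n <- length(x)
  p <- tabulate(bins, ng) / n
  q <- stats::quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  robust <- x[x >= q[1] & x <= q[4]]
  skew <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((x - mu)^4) / m2^2 else 0
  c(energy = sum(x^2), totalenergy = voxelVolume * sum(x^2),
    entropy = -sum(p * log2safe(p)), minimum = min(x),
    `10percentile` = q[1], `90percentile` = q[4], maximum = max(x),
    mean = mu, median = stats::median(x),
    interquartilerange = q[3] - q[2], range = max(x) - min(x),
    meanabsolutedeviation = mean(abs(x - mu)),
    robustmeanabsolutedeviation = mean(abs(robust - mean(robust))),
    rootmeansquared = sqrt(mean(x^2)), skewness = skew, kurtosis = kurt,
    variance = m2, uniformity = sum(p^2))
}

glcmFeatureNames <- function() c(
  "autocorrelation", "jointaverage", "clusterprominence", "clustershade",
  "clustertendency", "contrast", "correlation", "differenceaverage",
  "differenceentropy", "differencevariance", "jointenergy", "jointentropy",
  "imc1", "imc2", "idm", "idmn", "id", "idn", "inversevariance",
  "maximumprobability", "sumentropy", "sumsquares")

glcmFeatures <- function(P) {
  ng <- nrow(P)
  tot <- sum(P)
  p <- P / tot
  i <- row(p); j <- col(p)
  px <- rowSums(p)
  mux <- sum(seq_len(ng) * px)
  # symmetric accumulation: px == py, mux == muy
  sigx2 <- sum((seq_len(ng) - mux)^2 * px)
  pxy_sum <- as.vector(rowsum(as.vector(p), as.vector(i + j)))
  kd <- 0:(ng - 1)
  dif <- abs(i - j)
  pxy_diff <- numeric(ng)
  agg <- rowsum(as.vector(p), as.vector(dif))
  pxy_diff[as.integer(rownames(agg)) + 1L] <- agg
  da <- sum(kd * pxy_diff)
  hxy <- -sum(p * log2safe(p))
  ppx <- outer(px, px)
  hxy1 <- -sum(p * log2safe(ppx))
  hxy2 <- -sum(ppx * log2safe(ppx))
  hx <- -sum(px * log2safe(px))
  corr <- if (sigx2 > 0) (sum(i * j * p) - mux^2) / sigx2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  c(autocorrelation = sum(i * j * p), jointaverage = mux,
    clusterprominence = sum((i + j - 2 * mux)^4 * p),
    clustershade = sum((i + j - 2 * mux)^3 * p),
    clustertendency = sum((i + j - 2 * mux)^2 * p),
    contrast = sum((i - j)^2 * p), correlation = corr,
    differenceaverage = da,
    differenceentropy = -sum(pxy_diff * log2safe(pxy_diff)),
    differencevariance = sum((kd - da)^2 * pxy_diff),
    jointenergy = sum(p^2), jointentropy = hxy,
    imc1 = imc1, imc2 = imc2,
    idm = sum(p / (1 + dif^2)),
    idmn = sum(p / (1 + (dif / ng)^2)),
    id = sum(p / (1 + dif)),
    idn = sum(p / (1 + dif / ng)),
    inversevariance = sum(p[dif > 0] / dif[dif > 0]^2),
    maximumprobability = max(p),
    sumentropy = -sum(pxy_sum * log2safe(pxy_sum)),
    sumsquares = sum((i - mux)^2 * p))
}

glrlmFeatureNames <- function() c(
  "shortrunemphasis", "longrunemphasis", "graylevelnonuniformity",
  "graylevelnonuniformitynormalized", "runlengthnonuniformity",
  "runlengthnonuniformitynormalized", "runpercentage", "graylevelvariance",
  "runvariance", "runentropy", "lowgraylevelrunemphasis",
  "highgraylevelrunemphasis", "shortrunlowgraylevelemphasis",
  "shortrunhighgraylevelemphasis", "longrunlowgraylevelemphasis",
  "longrunhighgraylevelemphasis")

# shared run/zone/dependence feature family on a gray-by-size count matrix,
# given in triplet form (gray level gi, size sj, count w per distinct cell)
sizeMatrixFeatures <- function(gi, sj, w, nPotential, prefix) {
  nr <- sum(w)
  p <- w / nr
  pg <- rowsum(p, gi)           # per distinct gray level
  ps <- rowsum(p, sj)           # per distinct size
  glev <- as.numeric(rownames(pg))
  slev <- as.numeric(rownames(ps))
  mug <- sum(glev * pg)
  mus <- sum(slev * ps)
  out <- c(
    sum(w / sj^2) / nr, sum(w * sj^2) / nr,
    sum(pg^2) * nr, sum(pg^2),
    sum(ps^2) * nr, sum(ps^2),
    nr / nPotential,
    sum((gi - mug)^2 * p), sum((sj - mus)^2 * p),
    -sum(p * log2safe(p)),
    sum(w / gi^2) / nr, sum(w * gi^2) / nr,
    sum(w / (gi^2 * sj^2)) / nr, sum(w * gi^2 / sj^2) / nr,
    sum(w * sj^2 / gi^2) / nr, sum(w * gi^2 * sj^2) / nr)
  names(out) <- prefix
  out
}

glrlmFeatures <- function(R, nVoxels, nDirections = 13) {
  nz <- which(R > 0, arr.ind = TRUE)
  sizeMatrixFeatures(nz[, 1], nz[, 2], R[nz], nVoxels * nDirections,
                     glrlmFeatureNames())
}

glszmFeatureNames <- function() c(
  "smallareaemphasis", "largeareaemphasis", "graylevelnonuniformity",
  "graylevelnonuniformitynormalized", "sizezonenonuniformity",
  "sizezonenonuniformitynormalized", "zonepercentage", "graylevelvariance",
  "zonevariance", "zoneentropy", "lowgraylevelzoneemphasis",
  "highgraylevelzoneemphasis", "smallarealowgraylevelemphasis",
  "smallareahighgraylevelemphasis", "largearealowgraylevelemphasis",
  "largeareahighgraylevelemphasis")

glszmFeatures <- function(zoneGray, zoneSize, ng, nVoxels) {
  cell <- paste(zoneGray, zoneSize)
  w <- as.vector(table(cell))
  first <- !duplicated(cell)
  ord <- match(names(table(cell)), cell[first])
  gi <- zoneGray[first][ord]
  sj <- zoneSize[first][ord]
  sizeMatrixFeatures(gi, sj, w, nVoxels, glszmFeatureNames())
}

ngtdmFeatureNames <- function()
  c("coarseness", "contrast", "busyness", "complexity", "strength")

ngtdmFeatures <- function(counts) {
  ni <- counts[, 1]
  si <- counts[, 2]
  N <- sum(ni)
  p <- ni / N
  lv <- seq_along(ni)
  act <- which(p > 0)
  ngp <- length(act)
  coarse <- if (sum(p * si) > 0) 1 / sum(p * si) else 1e6
  if (ngp > 1) {
    pi_ <- p[act]; li <- lv[act]; siA <- si[act]
    dif2 <- outer(li, li, function(a, b) (a - b)^2)
    contrast <- sum(outer(pi_, pi_) * dif2) / (ngp * (ngp - 1)) * sum(si) / N
    ip <- li * pi_
    denomB <- sum(abs(outer(ip, ip, "-")))
    busy <- if (denomB > 0) sum(p * si) / denomB else 0
    cplx <- sum(abs(outer(li, li, "-")) *
                  (outer(pi_ * siA, pi_ * siA, "+")) /
                  outer(pi_, pi_, "+")) / N
    strength <- if (sum(si) > 0)
      sum(outer(pi_, pi_, "+") * dif2) / sum(si) else 0
  } else {
    contrast <- 0; busy <- 0; cplx <- 0; strength <- 0
  }
  c(coarseness = coarse, contrast = contrast, busyness = busy,
    complexity = cplx, strength = strength)
}

gldmFeatureNames <- function() c(
  "smalldependenceemphasis", "largedependenceemphasis",
  "graylevelnonuniformity", "dependencenonuniformity",
  "dependencenonuniformitynormalized", "graylevelvariance",
  "dependencevariance", "dependenceentropy", "lowgraylevelemphasis",
  "highgraylevelemphasis", "smalldependencelowgraylevelemphasis",
  "smalldependencehighgraylevelemphasis",
  "largedependencelowgraylevelemphasis",
  "largedependencehighgraylevelemphasis")

gldmFeatures <- function(D) {
  # columns are dependence counts 0..26; dependency size j includes the
  # centre voxel, so column c corresponds to j = c
  nz <- sum(D)
  p <- D / nz
  gi <- row(D); dj <- col(D)
  pg <- rowSums(p); pd <- colSums(p)
  mug <- sum(seq_len(nrow(D)) * pg)
  mud <- sum(seq_len(ncol(D)) * pd)
  c(smalldependenceemphasis = sum(D / dj^2) / nz,
    largedependenceemphasis = sum(D * dj^2) / nz,
    graylevelnonuniformity = sum(rowSums(D)^2) / nz,
    dependencenonuniformity = sum(colSums(D)^2) / nz,
    dependencenonuniformitynormalized = sum(colSums(D)^2) / nz^2,
    graylevelvariance = sum((gi - mug)^2 * p),
    dependencevariance = sum((dj - mud)^2 * p),
    dependenceentropy = -sum(p * log2safe(p)),
    lowgraylevelemphasis = sum(D / gi^2) / nz,
    highgraylevelemphasis = sum(D * gi^2) / nz,
    smalldependencelowgraylevelemphasis = sum(D / (gi^2 * dj^2)) / nz,
    smalldependencehighgraylevelemphasis = sum(D * gi^2 / dj^2) / nz,
    largedependencelowgraylevelemphasis = sum(D * dj^2 / gi^2) / nz,
    largedependencehighgraylevelemphasis = sum(D * gi^2 * dj^2) / nz)
}
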