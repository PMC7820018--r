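# Gray-level texture features on a discretized ROI.
#
# GLCM and GLRLM matrices are built at distance 1 for each of the 13 unique
# 3D directions; feature values are computed per direction and averaged
# ("3D average" aggregation). GLSZM zones and GLDM/NGTDM neighborhoods use
# 26-connectivity. Degenerate single-gray-level ROIs take the analytic
# limits of each formula (energies/uniformities 1, entropies/contrasts 0),
# and divisions by zero are guarded per formula with the documented limit.

entropy2 <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

#' Gray-level co-occurrence features
#'
#' 22 GLCM features from symmetric, normalized co-occurrence matrices at
#' distance 1, averaged over the 13 unique 3D directions.
#'
#' @param droi a [discretize()]d ROI.
#' @return named numeric vector of length 22.
#' @export
glcm_features <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  ng <- droi$n_levels
  counts <- cpp_glcm(droi$level_array, droi$dims, ng)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  per_dir <- vector("list", 13L)
  for (a in 1:13) {
    C <- counts[, , a]
    C <- C + t(C)  # symmetric
    tot <- sum(C)
    if (tot == 0) next  # no voxel pairs along this direction
    per_dir[[a]] <- glcm_features_one(C / tot, i, j, ng)
  }
  per_dir <- per_dir[!vapply(per_dir, is.null, logical(1))]
  if (!length(per_dir)) {
    # single-voxel ROI: treat as a point mass at (level, level)
    P <- matrix(0, ng, ng)
    P[droi$levels[1], droi$levels[1]] <- 1
    per_dir <- list(glcm_features_one(P, i, j, ng))
  }
  colMeans(do.call(rbind, per_dir))
}

glcm_features_one <- function(P, i, j, ng) {
  px <- rowSums(P)                      # == py by symmetry
  mu <- sum(seq_len(ng) * px)
  sigma2 <- sum((seq_len(ng) - mu)^2 * px)
  sigma <- sqrt(sigma2)
  k_diff <- 0:(ng - 1)
  pxmy <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  pxpy <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))
  da <- sum(k_diff * pxmy)
  hxy <- entropy2(P)
  pxpy_out <- outer(px, px)
  pos <- P > 0 & pxpy_out > 0
  hxy1 <- -sum(P[pos] * log2(pxpy_out[pos]))
  posm <- pxpy_out > 0
  hxy2 <- -sum(pxpy_out[posm] * log2(pxpy_out[posm]))
  hx <- entropy2(px)
  corr <- if (sigma2 > 0) (sum(i * j * P) - mu^2) / sigma2 else 1
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- if (hxy2 >= hxy) sqrt(1 - exp(-2 * (hxy2 - hxy))) else 0
  offd <- i != j
  c(Autocorrelation = sum(i * j * P),
    JointAverage = mu,
    ClusterProminence = sum((i + j - 2 * mu)^4 * P),
    ClusterShade = sum((i + j - 2 * mu)^3 * P),
    ClusterTendency = sum((i + j - 2 * mu)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = entropy2(pxmy),
    DifferenceVariance = sum((k_diff - da)^2 * pxmy),
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    Id = sum(P / (1 + abs(i - j))),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    InverseVariance = sum(P[offd] / (i[offd] - j[offd])^2),
    MaximumProbability = max(P),
    SumEntropy = entropy2(pxpy),
    SumSquares = sum((i - mu)^2 * P))
}

#' Gray-level run-length features
#'
#' 16 GLRLM features from run-length matrices per direction (distance-1
#' runs), averaged over the 13 unique 3D directions.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of length 16.
#' @export
glrlm_features <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  ng <- droi$n_levels
  np <- length(droi$levels)
  mats <- cpp_glrlm(droi$level_array, droi$dims, ng)
  vals <- vapply(mats, function(P) glrlm_features_one(P, np), numeric(16))
  rowMeans(vals)
}

glrlm_features_one <- function(P, np) {
  nr <- sum(P)
  gl <- seq_len(nrow(P))
  rl <- seq_len(ncol(P))
  ivec <- matrix(gl, nrow(P), ncol(P))
  jvec <- matrix(rl, nrow(P), ncol(P), byrow = TRUE)
  p <- P / nr
  mug <- sum(p * ivec)
  mur <- sum(p * jvec)
  rsum <- rowSums(P)   # per gray level
  csum <- colSums(P)   # per run length
  c(ShortRunEmphasis = sum(P / jvec^2) / nr,
    LongRunEmphasis = sum(P * jvec^2) / nr,
    GrayLevelNonUniformity = sum(rsum^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rsum^2) / nr^2,
    RunLengthNonUniformity = sum(csum^2) / nr,
    RunLengthNonUniformityNormalized = sum(csum^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = sum(p * (ivec - mug)^2),
    RunVariance = sum(p * (jvec - mur)^2),
    RunEntropy = entropy2(p),
    LowGrayLevelRunEmphasis = sum(P / ivec^2) / nr,
    HighGrayLevelRunEmphasis = sum(P * ivec^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(P / (ivec^2 * jvec^2)) / nr,
    ShortRunHighGrayLevelEmphasis = sum(P * ivec^2 / jvec^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(P * jvec^2 / ivec^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(P * ivec^2 * jvec^2) / nr)
}

#' Gray-level size-zone features
#'
#' 16 GLSZM features; zones are 26-connected components of constant gray
#' level (direction-free, so no aggregation step).
#'
#' @inheritParams glcm_features
#' @return named numeric vector of length 16.
#' @export
glszm_features <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  P <- cpp_glszm(droi$level_array, droi$dims, droi$n_levels)
  np <- length(droi$levels)
  nz <- sum(P)
  ivec <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  jvec <- matrix(seq_len(ncol(P)), nrow(P), ncol(P), byrow = TRUE)
  p <- P / nz
  mug <- sum(p * ivec)
  muz <- sum(p * jvec)
  rsum <- rowSums(P)
  csum <- colSums(P)
  c(SmallAreaEmphasis = sum(P / jvec^2) / nz,
    LargeAreaEmphasis = sum(P * jvec^2) / nz,
    GrayLevelNonUniformity = sum(rsum^2) / nz,
    GrayLevelNonUniformityNormalized = sum(rsum^2) / nz^2,
    SizeZoneNonUniformity = sum(csum^2) / nz,
    SizeZoneNonUniformityNormalized = sum(csum^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = sum(p * (ivec - mug)^2),
    ZoneVariance = sum(p * (jvec - muz)^2),
    ZoneEntropy = entropy2(p),
    LowGrayLevelZoneEmphasis = sum(P / ivec^2) / nz,
    HighGrayLevelZoneEmphasis = sum(P * ivec^2) / nz,
    SmallAreaLowGrayLevelEmphasis = sum(P / (ivec^2 * jvec^2)) / nz,
    SmallAreaHighGrayLevelEmphasis = sum(P * ivec^2 / jvec^2) / nz,
    LargeAreaLowGrayLevelEmphasis = sum(P * jvec^2 / ivec^2) / nz,
    LargeAreaHighGrayLevelEmphasis = sum(P * ivec^2 * jvec^2) / nz)
}

#' Neighboring gray-tone difference features
#'
#' 5 NGTDM features from 26-neighborhood gray-tone difference sums.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of length 5.
#' @export
ngtdm_features <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  m <- cpp_ngtdm(droi$level_array, droi$dims, droi$n_levels)
  ni <- m[, 1]
  si <- m[, 2]
  N <- sum(ni)
  pi_ <- ni / N
  gl <- seq_along(pi_)
  act <- pi_ > 0
  ngp <- sum(act)
  coarse_den <- sum(pi_ * si)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  if (ngp > 1) {
    pij <- outer(pi_[act], pi_[act])
    dij2 <- outer(gl[act], gl[act], function(a, b) (a - b)^2)
    contrast <- sum(pij * dij2) / (ngp * (ngp - 1)) * sum(si) / N
    ipi <- gl[act] * pi_[act]
    busy_den <- sum(abs(outer(ipi, ipi, "-")))
    busyness <- if (busy_den > 0) sum(pi_ * si) / busy_den else 0
    psa <- pi_[act] * si[act]
    cplx <- sum(abs(outer(gl[act], gl[act], "-")) *
                  (outer(psa, psa, "+")) /
                  outer(pi_[act], pi_[act], "+")) / N
    str_den <- sum(si)
    strength <- if (str_den > 0)
      sum(outer(pi_[act], pi_[act], "+") * dij2) / str_den else 0
  } else {
    contrast <- 0; busyness <- 0; cplx <- 0; strength <- 0
  }
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = cplx, Strength = strength)
}

#' Gray-level dependence features
#'
#' 14 GLDM features; the dependence size of a voxel is 1 plus the number of
#' its 26-neighbors whose gray level differs by at most `alpha`.
#'
#' @inheritParams glcm_features
#' @param alpha dependence tolerance on the level difference (default 0).
#' @return named numeric vector of length 14.
#' @export
gldm_features <- function(droi, alpha = 0) {
  stopifnot(inherits(droi, "discretized_roi"))
  P <- cpp_gldm(droi$level_array, droi$dims, droi$n_levels, as.integer(alpha))
  P <- P[, seq_len(max(which(colSums(P) > 0))), drop = FALSE]
  nz <- sum(P)
  ivec <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  jvec <- matrix(seq_len(ncol(P)), nrow(P), ncol(P), byrow = TRUE)
  p <- P / nz
  mug <- sum(p * ivec)
  mud <- sum(p * jvec)
  rsum <- rowSums(P)
  csum <- colSums(P)
  c(SmallDependenceEmphasis = sum(P / jvec^2) / nz,
    LargeDependenceEmphasis = sum(P * jvec^2) / nz,
    GrayLevelNonUniformity = sum(rsum^2) / nz,
    DependenceNonUniformity = sum(csum^2) / nz,
    DependenceNonUniformityNormalized = sum(csum^2) / nz^2,
    GrayLevelVariance = sum(p * (ivec - mug)^2),
    DependenceVariance = sum(p * (jvec - mud)^2),
    DependenceEntropy = entropy2(p),
    LowGrayLevelEmphasis = sum(P / ivec^2) / nz,
    HighGrayLevelEmphasis = sum(P * ivec^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (ivec^2 * jvec^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * ivec^2 / jvec^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * jvec^2 / ivec^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * ivec^2 * jvec^2) / nz)
}
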