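# Texture feature classes. Matrix accumulation happens in C++ (see
# src/texture.cpp); descriptor formulas live here so tests can verify the
# matrices against brute-force enumeration independently of the features.

EPS <- 2.220446e-16

#' Grey-level co-occurrence matrix features
#'
#' Co-occurrence is accumulated over the 13 unique 3D directions at distance
#' 1, symmetrized and normalized per direction; the 22 descriptors are
#' computed per direction and averaged. Degenerate single-level regions give
#' contrast 0, joint energy 1 and correlation 1 by convention.
#'
#' @param disc A `discretized_volume` from [discretize()].
#' @return Named numeric vector of 22 features (names `glcm_*`).
#' @export
glcm_features <- function(disc) {
  stopifnot(inherits(disc, "discretized_volume"))
  ng <- disc$ng
  counts <- cpp_glcm_counts(disc$levels, disc$dim, ng)
  feats <- NULL
  for (d in 1:13) {
    C <- matrix(counts[, , d], ng, ng)
    if (sum(C) == 0) next
    feats <- rbind(feats, glcm_from_matrix(C / sum(C)))
  }
  if (is.null(feats)) {
    # single-voxel region: no pairs in any direction; use the delta matrix
    l <- max(disc$levels)
    P <- matrix(0, ng, ng); P[l, l] <- 1
    feats <- rbind(glcm_from_matrix(P))
  }
  out <- colMeans(feats)
  names(out) <- paste0("glcm_", colnames(feats))
  out
}

# Descriptors of one symmetric normalized co-occurrence matrix.
glcm_from_matrix <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum(seq_len(ng) * px)
  sig2 <- sum((seq_len(ng) - mu)^2 * px)
  # diagonal and cross-diagonal distributions
  pxy_sum <- vapply(2:(2 * ng), function(k) sum(P[i + j == k]), 0)
  kk_sum <- 2:(2 * ng)
  pxy_diff <- vapply(0:(ng - 1), function(k) sum(P[abs(i - j) == k]), 0)
  kk_diff <- 0:(ng - 1)
  da <- sum(kk_diff * pxy_diff)
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  HXY <- -sum(P[P > 0] * log2(P[P > 0]))
  pxpy <- outer(px, px)
  HXY1 <- -sum(P * log2(pxpy + EPS))
  HXY2 <- -sum(pxpy[pxpy > 0] * log2(pxpy[pxpy > 0]))
  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 1
  c(Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - 2 * mu)^4 * P),
    ClusterShade = sum((i + j - 2 * mu)^3 * P),
    ClusterTendency = sum((i + j - 2 * mu)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pxy_diff[pxy_diff > 0] *
                               log2(pxy_diff[pxy_diff > 0])),
    DifferenceVariance = sum((kk_diff - da)^2 * pxy_diff),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    Imc1 = if (max(HX, HX) > 0) (HXY - HXY1) / HX else 0,
    Imc2 = sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0)),
    InverseVariance = if (ng > 1) sum((P / (i - j)^2)[i != j]) else 0,
    JointAverage = mu,
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    MaximumProbability = max(P),
    SumEntropy = -sum(pxy_sum[pxy_sum > 0] * log2(pxy_sum[pxy_sum > 0])),
    SumSquares = sum((i - mu)^2 * P))
}

# Shared run-length / size-zone descriptor machinery: P is a levels x sizes
# count matrix, np the ROI voxel count. Returns the 16 standard descriptors.
rl_descriptors <- function(P, np, prefix) {
  nr <- sum(P)
  i <- row(P); j <- col(P)
  p <- P / nr
  pg <- rowSums(p); pl <- colSums(p)
  mug <- sum(seq_along(pg) * pg)
  mul <- sum(seq_along(pl) * pl)
  out <- c(
    ShortEmphasis = sum(P / j^2) / nr,
    LongEmphasis = sum(P * j^2) / nr,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(P)^2) / nr^2,
    LengthNonUniformity = sum(colSums(P)^2) / nr,
    LengthNonUniformityNormalized = sum(colSums(P)^2) / nr^2,
    Percentage = nr / np,
    GrayLevelVariance = sum((seq_along(pg) - mug)^2 * pg),
    LengthVariance = sum((seq_along(pl) - mul)^2 * pl),
    Entropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelEmphasis = sum(P / i^2) / nr,
    HighGrayLevelEmphasis = sum(P * i^2) / nr,
    ShortLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nr,
    ShortHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nr,
    LongLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nr,
    LongHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nr)
  names(out) <- paste0(prefix, names(out))
  out
}

#' Grey-level run-length matrix features
#'
#' Run-length matrices over the 13 unique 3D directions; the 16 descriptors
#' are computed per direction and averaged.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features (names `glrlm_*`).
#' @export
glrlm_features <- function(disc) {
  stopifnot(inherits(disc, "discretized_volume"))
  counts <- cpp_glrlm_counts(disc$levels, disc$dim, disc$ng)
  dd <- dim(counts)
  feats <- NULL
  for (d in 1:13) {
    P <- matrix(counts[, , d], dd[1], dd[2])
    feats <- rbind(feats, rl_descriptors(P, disc$n_voxels, ""))
  }
  out <- colMeans(feats)
  nm <- colnames(feats)
  nm[nm == "Percentage"] <- "RunPercentage"
  nm[nm == "LengthVariance"] <- "RunVariance"
  nm[nm == "Entropy"] <- "RunEntropy"
  nm <- sub("^Length", "RunLength", nm)
  nm <- sub("^Short", "ShortRun", sub("^Long", "LongRun", nm))
  names(out) <- paste0("glrlm_", nm)
  out
}

#' Grey-level size-zone matrix features
#'
#' Zones are 26-connected components of equal grey level; a single matrix
#' (no directionality) yields the 16 descriptors.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features (names `glszm_*`).
#' @export
glszm_features <- function(disc) {
  stopifnot(inherits(disc, "discretized_volume"))
  zones <- cpp_glszm_zones(disc$levels, disc$dim)
  smax <- max(zones[, 2])
  P <- matrix(0, disc$ng, smax)
  for (z in seq_len(nrow(zones))) {
    P[zones[z, 1], zones[z, 2]] <- P[zones[z, 1], zones[z, 2]] + 1
  }
  out <- rl_descriptors(P, disc$n_voxels, "")
  nm <- names(out)
  nm[nm == "Percentage"] <- "ZonePercentage"
  nm[nm == "LengthVariance"] <- "ZoneVariance"
  nm[nm == "Entropy"] <- "ZoneEntropy"
  nm <- sub("^Length", "SizeZone", nm)
  nm <- sub("^Short", "SmallArea", sub("^Long", "LargeArea", nm))
  names(out) <- paste0("glszm_", nm)
  out
}

#' Neighbourhood grey-tone difference matrix features
#'
#' Grey-tone difference sums use the full 26-neighbourhood intersected with
#' the ROI. A constant region returns the documented degenerate values
#' (coarseness capped at 1e6, contrast 0).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 5 features (names `ngtdm_*`).
#' @export
ngtdm_features <- function(disc) {
  stopifnot(inherits(disc, "discretized_volume"))
  M <- cpp_ngtdm(disc$levels, disc$dim, disc$ng)
  n_i <- M[, 1]; s_i <- M[, 2]
  nvp <- sum(n_i)
  p_i <- n_i / nvp
  act <- which(p_i > 0)
  ngp <- length(act)
  lv <- seq_len(disc$ng)
  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) min(1 / coarse_den, 1e6) else 1e6
  if (ngp > 1) {
    pij <- outer(p_i[act], p_i[act])
    dij <- outer(lv[act], lv[act], `-`)
    contrast <- sum(pij * dij^2) / (ngp * (ngp - 1)) * sum(s_i) / nvp
    bus_den <- sum(abs(outer(lv[act] * p_i[act], lv[act] * p_i[act], `-`)))
    busyness <- if (bus_den > 0) sum(p_i * s_i) / bus_den else 0
    psi <- outer(p_i[act] * s_i[act], p_i[act] * s_i[act], `+`)
    psum <- outer(p_i[act], p_i[act], `+`)
    complexity <- sum(abs(dij) * psi / psum) / nvp
    strength <- if (sum(s_i) > 0) sum(psum * dij^2) / sum(s_i) else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  c(ngtdm_Coarseness = coarseness,
    ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness,
    ngtdm_Complexity = complexity,
    ngtdm_Strength = strength)
}

#' Grey-level dependence matrix features
#'
#' Dependence of a voxel is 1 plus the number of in-ROI 26-neighbours whose
#' level differs from the centre by at most `alpha` (default 0).
#'
#' @inheritParams glcm_features
#' @param alpha Dependence tolerance in grey levels.
#' @return Named numeric vector of 14 features (names `gldm_*`).
#' @export
gldm_features <- function(disc, alpha = 0) {
  stopifnot(inherits(disc, "discretized_volume"))
  P <- cpp_gldm_counts(disc$levels, disc$dim, disc$ng, alpha)
  nz <- sum(P)
  i <- row(P); j <- col(P)
  p <- P / nz
  pg <- rowSums(p); pd <- colSums(p)
  mug <- sum(seq_along(pg) * pg)
  mud <- sum(seq_along(pd) * pd)
  c(gldm_SmallDependenceEmphasis = sum(P / j^2) / nz,
    gldm_LargeDependenceEmphasis = sum(P * j^2) / nz,
    gldm_GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    gldm_DependenceNonUniformity = sum(colSums(P)^2) / nz,
    gldm_DependenceNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    gldm_GrayLevelVariance = sum((seq_along(pg) - mug)^2 * pg),
    gldm_DependenceVariance = sum((seq_along(pd) - mud)^2 * pd),
    gldm_DependenceEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    gldm_LowGrayLevelEmphasis = sum(P / i^2) / nz,
    gldm_HighGrayLevelEmphasis = sum(P * i^2) / nz,
    gldm_SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz,
    gldm_SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    gldm_LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    gldm_LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz)
}
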