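#' Gray-level co-occurrence matrix features
#'
#' Co-occurrences are counted at Chebyshev distance 1 over the 13 unique 3D
#' direction pairs and symmetrized; the 24 features are computed per
#' direction and averaged across directions with valid pairs.
#'
#' @param discretized a [discretize_fixed_bin_number()] result.
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(discretized) {
  ng <- discretized$Ng
  counts <- cpp_glcm_counts(discretized$levels, ng)
  feats <- NULL
  nvalid <- 0
  for (d in 1:13) {
    P <- counts[, , d]
    tot <- sum(P)
    if (tot == 0) next
    f <- glcm_features_one(P / tot, ng)
    feats <- if (is.null(feats)) f else feats + f
    nvalid <- nvalid + 1
  }
  if (nvalid == 0) stop("no valid co-occurrence pairs in ROI")
  feats / nvalid
}

glcm_features_one <- function(p, ng) {
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p) # == py by symmetry
  lev <- seq_len(ng)
  ux <- sum(lev * px)
  sigx2 <- sum((lev - ux)^2 * px)
  # diagonal (difference) and cross-diagonal (sum) marginals
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), numeric(1))
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(p[(i + j) == k]), numeric(1))
  da <- sum(k_diff * p_diff)
  hx <- -sum(px * log2(px + .eps))
  hxy <- -sum(p * log2(p + .eps))
  pxpy <- outer(px, px)
  hxy1 <- -sum(p * log2(pxpy + .eps))
  hxy2 <- -sum(pxpy * log2(pxpy + .eps))
  ac <- sum(i * j * p)
  corr <- if (sigx2 > .eps) (ac - ux * ux) / sigx2 else 1
  imc1 <- if (max(hx, hx) > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  c(
    Autocorrelation = ac,
    ClusterProminence = sum((i + j - 2 * ux)^4 * p),
    ClusterShade = sum((i + j - 2 * ux)^3 * p),
    ClusterTendency = sum((i + j - 2 * ux)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(p_diff * log2(p_diff + .eps)),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    Id = sum(p_diff / (1 + k_diff)),
    Idm = sum(p_diff / (1 + k_diff^2)),
    Idmn = sum(p_diff / (1 + (k_diff / ng)^2)),
    Idn = sum(p_diff / (1 + k_diff / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p_diff[-1] / k_diff[-1]^2),
    JointAverage = ux,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = glcm_mcc(p, px),
    MaximumProbability = max(p),
    SumAverage = sum(k_sum * p_sum),
    SumEntropy = -sum(p_sum * log2(p_sum + .eps)),
    SumSquares = sum((i - ux)^2 * p)
  )
}

# maximal correlation coefficient: sqrt of the second-largest eigenvalue of
# Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)), over occupied gray levels
glcm_mcc <- function(p, px) {
  keep <- px > 0
  if (sum(keep) < 2) return(1)
  psub <- p[keep, keep, drop = FALSE]
  pxs <- px[keep]
  # Q(i,j) = sum_k p(i,k)/px(i) * p(j,k)/py(k)
  Q <- (psub / pxs) %*% t(sweep(psub, 2, pxs, `/`))
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(max(0, ev[2]))
}

#' Gray-level run-length matrix features
#'
#' Runs of equal gray level along the 13 unique 3D directions; the 16
#' features are computed per direction and averaged.
#'
#' @param discretized a [discretize_fixed_bin_number()] result.
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(discretized) {
  counts <- cpp_glrlm_counts(discretized$levels, discretized$Ng)
  np <- discretized$n_voxels
  feats <- NULL
  nvalid <- 0
  for (d in 1:13) {
    P <- counts[, , d]
    if (sum(P) == 0) next
    f <- rl_type_features(P, np)
    feats <- if (is.null(feats)) f else feats + f
    nvalid <- nvalid + 1
  }
  if (is.null(feats)) stop("no runs in ROI")
  names(feats) <- c(
    "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage",
    "GrayLevelVariance", "RunVariance", "RunEntropy",
    "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
    "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
    "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  feats / nvalid
}

# shared run-length / size-zone feature kernel on a level x size matrix
rl_type_features <- function(P, np) {
  nz <- sum(P)
  i <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  j <- matrix(seq_len(ncol(P)), nrow(P), ncol(P), byrow = TRUE)
  pg <- rowSums(P)
  pr <- colSums(P)
  p <- P / nz
  pgn <- pg / nz
  prn <- pr / nz
  mu_g <- sum(seq_len(nrow(P)) * pgn)
  mu_r <- sum(seq_len(ncol(P)) * prn)
  c(
    sum(P / j^2) / nz,                 # short emphasis
    sum(P * j^2) / nz,                 # long/large emphasis
    sum(pg^2) / nz,                    # gray level non-uniformity
    sum(pg^2) / nz^2,                  # ... normalized
    sum(pr^2) / nz,                    # run-length / size-zone n.u.
    sum(pr^2) / nz^2,                  # ... normalized
    nz / np,                           # run / zone percentage
    sum((seq_len(nrow(P)) - mu_g)^2 * pgn),  # gray level variance
    sum((seq_len(ncol(P)) - mu_r)^2 * prn),  # run/zone variance
    -sum(p * log2(p + .eps)),          # entropy
    sum(P / i^2) / nz,                 # low gray level emphasis
    sum(P * i^2) / nz,                 # high gray level emphasis
    sum(P / (i^2 * j^2)) / nz,         # short + low
    sum(P * i^2 / j^2) / nz,           # short + high
    sum(P * j^2 / i^2) / nz,           # long/large + low
    sum(P * i^2 * j^2) / nz            # long/large + high
  )
}

#' Gray-level size-zone matrix features
#'
#' Zones are 26-connected components of equal gray level; a single matrix
#' (no directions) yields the 16 features.
#'
#' @param discretized a [discretize_fixed_bin_number()] result.
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(discretized) {
  zones <- cpp_glszm_zones(discretized$levels, discretized$Ng)
  if (nrow(zones) == 0) stop("no zones in ROI")
  P <- zone_matrix(zones, discretized$Ng)
  f <- rl_type_features(P, discretized$n_voxels)
  names(f) <- c(
    "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "ZonePercentage",
    "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
    "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
    "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
    "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  f
}

zone_matrix <- function(zones, ng) {
  maxs <- max(zones[, "size"])
  P <- matrix(0, ng, maxs)
  for (r in seq_len(nrow(zones)))
    P[zones[r, "level"], zones[r, "size"]] <-
      P[zones[r, "level"], zones[r, "size"]] + 1
  P
}

#' Neighbourhood gray-tone difference matrix features
#'
#' For each in-mask voxel the absolute difference between its level and the
#' mean level of its in-mask 26-neighbourhood is accumulated per level;
#' the 5 features follow. A perfectly uniform ROI has no gray-tone
#' differences: Coarseness takes its conventional cap (1e6), Contrast and
#' Busyness are 0.
#'
#' @param discretized a [discretize_fixed_bin_number()] result.
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(discretized) {
  st <- cpp_ngtdm_stats(discretized$levels, discretized$Ng)
  n_i <- st[, 1]
  s_i <- st[, 2]
  N <- sum(n_i)
  if (N == 0) stop("no voxels with a valid neighbourhood")
  p_i <- n_i / N
  lev <- seq_along(p_i)
  act <- p_i > 0
  ngp <- sum(act)
  la <- lev[act]; pa <- p_i[act]; sa <- s_i[act]
  coarse_den <- sum(pa * sa)
  ii <- matrix(la, ngp, ngp); jj <- t(ii)
  pi_m <- matrix(pa, ngp, ngp); pj_m <- t(pi_m)
  si_m <- matrix(sa, ngp, ngp); sj_m <- t(si_m)
  contrast <- if (ngp > 1)
    sum(pi_m * pj_m * (ii - jj)^2) / (ngp * (ngp - 1)) * sum(sa) / N else 0
  busy_den <- sum(abs(la * pa - rep(la * pa, each = ngp)))
  busyness <- if (ngp > 1 && busy_den > 0) coarse_den / busy_den else 0
  complexity <- sum(abs(ii - jj) * (pi_m * si_m + pj_m * sj_m) /
                      (pi_m + pj_m)) / N
  strength <- if (sum(sa) > 0)
    sum((pi_m + pj_m) * (ii - jj)^2) / sum(sa) else 0
  c(
    Coarseness = if (coarse_den > 0) min(1 / coarse_den, 1e6) else 1e6,
    Contrast = contrast,
    Busyness = busyness,
    Complexity = complexity,
    Strength = strength
  )
}

#' Gray-level dependence matrix features
#'
#' The dependence of a voxel is one plus the number of its 26-neighbours
#' (Chebyshev distance 1) whose level equals its own (dependence tolerance
#' alpha = 0). The level x dependence matrix yields the 14 features.
#'
#' @param discretized a [discretize_fixed_bin_number()] result.
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(discretized) {
  P <- cpp_gldm_counts(discretized$levels, discretized$Ng)
  nz <- sum(P)
  if (nz == 0) stop("empty discretized ROI")
  i <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  j <- matrix(seq_len(ncol(P)), nrow(P), ncol(P), byrow = TRUE)
  p <- P / nz
  pg <- rowSums(P); pd <- colSums(P)
  pgn <- pg / nz; pdn <- pd / nz
  mu_g <- sum(seq_len(nrow(P)) * pgn)
  mu_d <- sum(seq_len(ncol(P)) * pdn)
  c(
    SmallDependenceEmphasis = sum(P / j^2) / nz,
    LargeDependenceEmphasis = sum(P * j^2) / nz,
    GrayLevelNonUniformity = sum(pg^2) / nz,
    DependenceNonUniformity = sum(pd^2) / nz,
    DependenceNonUniformityNormalized = sum(pd^2) / nz^2,
    GrayLevelVariance = sum((seq_len(nrow(P)) - mu_g)^2 * pgn),
    DependenceVariance = sum((seq_len(ncol(P)) - mu_d)^2 * pdn),
    DependenceEntropy = -sum(p * log2(p + .eps)),
    LowGrayLevelEmphasis = sum(P / i^2) / nz,
    HighGrayLevelEmphasis = sum(P * i^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / nz
  )
}
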