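# Independent brute-force oracles used to verify the fast extraction paths.
# Everything here is deliberately naive: explicit loops, no shared code with
# the package implementation.

.o_eps <- .Machine$double.eps

# the 13 unique direction pairs (positive half-space, matching any
# consistent enumeration; oracles average over directions so order is
# irrelevant)
oracle_directions <- function() {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  d <- d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ]
  keep <- d$dz > 0 | (d$dz == 0 & d$dy > 0) |
    (d$dz == 0 & d$dy == 0 & d$dx > 0)
  as.matrix(d[keep, ])
}

oracle_offsets26 <- function() {
  d <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(d[!(d$dx == 0 & d$dy == 0 & d$dz == 0), ])
}

in_bounds <- function(v, dims) all(v >= 1) && all(v <= dims)

# ---- GLCM ----

oracle_glcm_matrix <- function(lv, dir, ng) {
  dims <- dim(lv)
  P <- matrix(0, ng, ng)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    a <- lv[x, y, z]
    if (a <= 0) next
    q <- c(x, y, z) + dir
    if (!in_bounds(q, dims)) next
    b <- lv[q[1], q[2], q[3]]
    if (b <= 0) next
    P[a, b] <- P[a, b] + 1
    P[b, a] <- P[b, a] + 1
  }
  P
}

oracle_glcm_features <- function(lv, ng) {
  dirs <- oracle_directions()
  acc <- NULL
  nv <- 0
  for (r in seq_len(nrow(dirs))) {
    P <- oracle_glcm_matrix(lv, dirs[r, ], ng)
    if (sum(P) == 0) next
    p <- P / sum(P)
    px <- rowSums(p); py <- colSums(p)
    ux <- 0; for (i in 1:ng) ux <- ux + i * px[i]
    uy <- 0; for (j in 1:ng) uy <- uy + j * py[j]
    sx2 <- 0; for (i in 1:ng) sx2 <- sx2 + (i - ux)^2 * px[i]
    pd <- numeric(ng); ps <- numeric(2 * ng - 1)
    for (i in 1:ng) for (j in 1:ng) {
      pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
      ps[i + j - 1] <- ps[i + j - 1] + p[i, j]
    }
    kd <- 0:(ng - 1); ks <- 2:(2 * ng)
    da <- sum(kd * pd)
    hx <- -sum(px * log2(px + .o_eps))
    hy <- -sum(py * log2(py + .o_eps))
    hxy <- -sum(p * log2(p + .o_eps))
    hxy1 <- 0; hxy2 <- 0
    for (i in 1:ng) for (j in 1:ng) {
      hxy1 <- hxy1 - p[i, j] * log2(px[i] * py[j] + .o_eps)
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j] + .o_eps)
    }
    ac <- 0; cp <- 0; cs <- 0; ct <- 0; con <- 0; je <- 0; mp <- 0; ss <- 0
    for (i in 1:ng) for (j in 1:ng) {
      ac <- ac + i * j * p[i, j]
      cp <- cp + (i + j - ux - uy)^4 * p[i, j]
      cs <- cs + (i + j - ux - uy)^3 * p[i, j]
      ct <- ct + (i + j - ux - uy)^2 * p[i, j]
      con <- con + (i - j)^2 * p[i, j]
      je <- je + p[i, j]^2
      if (p[i, j] > mp) mp <- p[i, j]
      ss <- ss + (i - ux)^2 * p[i, j]
    }
    corr <- if (sx2 > .o_eps) (ac - ux * uy) / sx2 else 1
    # MCC via the Q matrix over occupied levels
    keep <- which(px > 0)
    mcc <- if (length(keep) < 2) 1 else {
      Q <- matrix(0, length(keep), length(keep))
      for (ii in seq_along(keep)) for (jj in seq_along(keep)) {
        s <- 0
        for (kk in seq_along(keep))
          s <- s + p[keep[ii], keep[kk]] * p[keep[jj], keep[kk]] /
            (px[keep[ii]] * py[keep[kk]])
        Q[ii, jj] <- s
      }
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(0, ev[2]))
    }
    f <- c(
      Autocorrelation = ac,
      ClusterProminence = cp,
      ClusterShade = cs,
      ClusterTendency = ct,
      Contrast = con,
      Correlation = corr,
      DifferenceAverage = da,
      DifferenceEntropy = -sum(pd * log2(pd + .o_eps)),
      DifferenceVariance = sum((kd - da)^2 * pd),
      Id = sum(pd / (1 + kd)),
      Idm = sum(pd / (1 + kd^2)),
      Idmn = sum(pd / (1 + (kd / ng)^2)),
      Idn = sum(pd / (1 + kd / ng)),
      Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
      Imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
      InverseVariance = sum(pd[-1] / kd[-1]^2),
      JointAverage = ux,
      JointEnergy = je,
      JointEntropy = hxy,
      MCC = mcc,
      MaximumProbability = mp,
      SumAverage = sum(ks * ps),
      SumEntropy = -sum(ps * log2(ps + .o_eps)),
      SumSquares = ss
    )
    acc <- if (is.null(acc)) f else acc + f
    nv <- nv + 1
  }
  acc / nv
}

# ---- GLRLM ----

# enumerate maximal runs along one direction by walking to each run start
oracle_glrlm_matrix <- function(lv, dir, ng, maxlen) {
  dims <- dim(lv)
  P <- matrix(0, ng, maxlen)
  done <- array(FALSE, dim = dims)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (done[x, y, z]) next
    a <- lv[x, y, z]
    if (a <= 0) next
    # walk backwards to the start of this run
    v <- c(x, y, z)
    while (TRUE) {
      b <- v - dir
      if (!in_bounds(b, dims) || lv[b[1], b[2], b[3]] != a) break
      v <- b
    }
    len <- 0
    w <- v
    while (in_bounds(w, dims) && lv[w[1], w[2], w[3]] == a) {
      done[w[1], w[2], w[3]] <- TRUE
      len <- len + 1
      w <- w + dir
    }
    P[a, len] <- P[a, len] + 1
  }
  P
}

oracle_rl_features <- function(P, np) {
  nz <- sum(P)
  ng <- nrow(P); nr <- ncol(P)
  sre <- 0; lre <- 0; lgl <- 0; hgl <- 0; srl <- 0; srh <- 0; lrl <- 0
  lrh <- 0
  for (i in 1:ng) for (j in 1:nr) {
    sre <- sre + P[i, j] / j^2; lre <- lre + P[i, j] * j^2
    lgl <- lgl + P[i, j] / i^2; hgl <- hgl + P[i, j] * i^2
    srl <- srl + P[i, j] / (i^2 * j^2); srh <- srh + P[i, j] * i^2 / j^2
    lrl <- lrl + P[i, j] * j^2 / i^2; lrh <- lrh + P[i, j] * i^2 * j^2
  }
  pg <- rowSums(P); pr <- colSums(P)
  p <- P / nz
  mug <- sum((1:ng) * pg / nz); mur <- sum((1:nr) * pr / nz)
  c(sre / nz, lre / nz, sum(pg^2) / nz, sum(pg^2) / nz^2, sum(pr^2) / nz,
    sum(pr^2) / nz^2, nz / np,
    sum(((1:ng) - mug)^2 * pg / nz), sum(((1:nr) - mur)^2 * pr / nz),
    -sum(p * log2(p + .o_eps)),
    lgl / nz, hgl / nz, srl / nz, srh / nz, lrl / nz, lrh / nz)
}

oracle_glrlm_features <- function(lv, ng) {
  np <- sum(lv > 0)
  dirs <- oracle_directions()
  maxlen <- max(dim(lv))
  acc <- NULL; nv <- 0
  for (r in seq_len(nrow(dirs))) {
    P <- oracle_glrlm_matrix(lv, dirs[r, ], ng, maxlen)
    if (sum(P) == 0) next
    f <- oracle_rl_features(P, np)
    acc <- if (is.null(acc)) f else acc + f
    nv <- nv + 1
  }
  stats::setNames(acc / nv, c(
    "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage",
    "GrayLevelVariance", "RunVariance", "RunEntropy",
    "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
    "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
    "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis"))
}

# ---- GLSZM (components via igraph, an independent route) ----

oracle_glszm_features <- function(lv, ng) {
  dims <- dim(lv)
  np <- sum(lv > 0)
  vox <- which(lv > 0)
  coord <- arrayInd(vox, dims)
  offs <- oracle_offsets26()
  pos <- integer(prod(dims))
  pos[vox] <- seq_along(vox)
  edges <- c()
  for (i in seq_along(vox)) {
    for (r in seq_len(nrow(offs))) {
      q <- coord[i, ] + offs[r, ]
      if (!in_bounds(q, dims)) next
      if (lv[q[1], q[2], q[3]] != lv[vox[i]]) next
      j <- pos[q[1] + dims[1] * ((q[2] - 1) + dims[2] * (q[3] - 1))]
      if (j > i) edges <- c(edges, i, j)
    }
  }
  g <- igraph::make_empty_graph(n = length(vox), directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  sizes <- as.integer(comp$csize)
  levels <- vapply(seq_len(comp$no), function(k)
    lv[vox[comp$membership == k][1]], numeric(1))
  maxs <- max(sizes)
  P <- matrix(0, ng, maxs)
  for (k in seq_along(sizes)) P[levels[k], sizes[k]] <-
    P[levels[k], sizes[k]] + 1
  stats::setNames(oracle_rl_features(P, np), c(
    "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "ZonePercentage",
    "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
    "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
    "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
    "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis"))
}

# ---- NGTDM ----

oracle_ngtdm_features <- function(lv, ng) {
  dims <- dim(lv)
  offs <- oracle_offsets26()
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    a <- lv[x, y, z]
    if (a <= 0) next
    nb <- c()
    for (r in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[r, ]
      if (!in_bounds(q, dims)) next
      b <- lv[q[1], q[2], q[3]]
      if (b > 0) nb <- c(nb, b)
    }
    if (length(nb) == 0) next
    n_i[a] <- n_i[a] + 1
    s_i[a] <- s_i[a] + abs(a - mean(nb))
  }
  N <- sum(n_i)
  p_i <- n_i / N
  act <- which(p_i > 0)
  ngp <- length(act)
  den <- sum(p_i * s_i)
  contrast <- 0; busy_den <- 0; complexity <- 0; strength <- 0
  for (i in act) for (j in act) {
    contrast <- contrast + p_i[i] * p_i[j] * (i - j)^2
    busy_den <- busy_den + abs(i * p_i[i] - j * p_i[j])
    complexity <- complexity + abs(i - j) *
      (p_i[i] * s_i[i] + p_i[j] * s_i[j]) / (p_i[i] + p_i[j])
    strength <- strength + (p_i[i] + p_i[j]) * (i - j)^2
  }
  c(
    Coarseness = if (den > 0) min(1 / den, 1e6) else 1e6,
    Contrast = if (ngp > 1)
      contrast / (ngp * (ngp - 1)) * sum(s_i) / N else 0,
    Busyness = if (ngp > 1 && busy_den > 0) den / busy_den else 0,
    Complexity = complexity / N,
    Strength = if (sum(s_i) > 0) strength / sum(s_i) else 0
  )
}

# ---- GLDM ----

oracle_gldm_features <- function(lv, ng) {
  dims <- dim(lv)
  offs <- oracle_offsets26()
  deps <- c(); levs <- c()
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    a <- lv[x, y, z]
    if (a <= 0) next
    dep <- 1
    for (r in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[r, ]
      if (!in_bounds(q, dims)) next
      if (lv[q[1], q[2], q[3]] == a) dep <- dep + 1
    }
    deps <- c(deps, dep); levs <- c(levs, a)
  }
  P <- matrix(0, ng, 27)
  for (k in seq_along(deps)) P[levs[k], deps[k]] <- P[levs[k], deps[k]] + 1
  nz <- sum(P)
  sde <- 0; lde <- 0; lgl <- 0; hgl <- 0; sdl <- 0; sdh <- 0; ldl <- 0
  ldh <- 0
  for (i in 1:ng) for (j in 1:27) {
    sde <- sde + P[i, j] / j^2; lde <- lde + P[i, j] * j^2
    lgl <- lgl + P[i, j] / i^2; hgl <- hgl + P[i, j] * i^2
    sdl <- sdl + P[i, j] / (i^2 * j^2); sdh <- sdh + P[i, j] * i^2 / j^2
    ldl <- ldl + P[i, j] * j^2 / i^2; ldh <- ldh + P[i, j] * i^2 * j^2
  }
  pg <- rowSums(P); pd <- colSums(P)
  p <- P / nz
  mug <- sum((1:ng) * pg / nz); mud <- sum((1:27) * pd / nz)
  c(
    SmallDependenceEmphasis = sde / nz,
    LargeDependenceEmphasis = lde / nz,
    GrayLevelNonUniformity = sum(pg^2) / nz,
    DependenceNonUniformity = sum(pd^2) / nz,
    DependenceNonUniformityNormalized = sum(pd^2) / nz^2,
    GrayLevelVariance = sum(((1:ng) - mug)^2 * pg / nz),
    DependenceVariance = sum(((1:27) - mud)^2 * pd / nz),
    DependenceEntropy = -sum(p * log2(p + .o_eps)),
    LowGrayLevelEmphasis = lgl / nz,
    HighGrayLevelEmphasis = hgl / nz,
    SmallDependenceLowGrayLevelEmphasis = sdl / nz,
    SmallDependenceHighGrayLevelEmphasis = sdh / nz,
    LargeDependenceLowGrayLevelEmphasis = ldl / nz,
    LargeDependenceHighGrayLevelEmphasis = ldh / nz
  )
}

# ---- first-order oracle: direct recomputation from the voxel list ----

oracle_first_order <- function(x, levels, ng, voxvol) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  qs <- quantile(x, c(0.10, 0.25, 0.75, 0.90))
  cnt <- table(factor(levels[levels > 0], levels = 1:ng))
  p <- as.numeric(cnt) / sum(cnt)
  p <- p[p > 0]
  rob <- x[x >= qs[1] & x <= qs[4]]
  c(
    `10Percentile` = unname(qs[1]), `90Percentile` = unname(qs[4]),
    Energy = sum(x^2),
    Entropy = -sum(p * log2(p + .o_eps)),
    InterquartileRange = unname(qs[3] - qs[2]),
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Maximum = max(x), Mean = mu,
    MeanAbsoluteDeviation = sum(abs(x - mu)) / n,
    Median = median(x), Minimum = min(x), Range = max(x) - min(x),
    RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    RootMeanSquared = sqrt(sum(x^2) / n),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    TotalEnergy = voxvol * sum(x^2),
    Uniformity = sum(p^2),
    Variance = m2
  )
}

# ---- ICC(A,1) oracle via aov() mean squares ----

oracle_icc_a1 <- function(m) {
  df <- data.frame(
    y = as.numeric(m),
    subject = factor(rep(seq_len(nrow(m)), times = ncol(m))),
    rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  fit <- stats::aov(y ~ subject + rater, data = df)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(m); k <- ncol(m)
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# ---- Wilcoxon signed-rank oracle: exhaustive sign enumeration ----

oracle_wilcoxon_p <- function(d, alternative = "two.sided") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.numeric(signs %*% r)
  switch(alternative,
         two.sided = min(1, 2 * min(mean(ws <= w), mean(ws >= w))),
         greater = mean(ws >= w),
         less = mean(ws <= w))
}

# ---- shared fixtures ----

# random small discretized ROI (levels array with 0 = outside mask)
random_levels <- function(dims, ng, p_mask = 0.8) {
  lv <- array(sample(1:ng, prod(dims), replace = TRUE), dim = dims)
  lv[runif(prod(dims)) > p_mask] <- 0L
  if (sum(lv > 0) < 2) lv[1:2] <- 1L
  lv
}

# wrap a levels array as a discretized_roi plus matching image/mask pair
levels_as_roi <- function(lv, ng) {
  structure(list(levels = lv, Ng = as.integer(ng),
                 bin_edges = seq(0, ng), n_voxels = sum(lv > 0)),
            class = "discretized_roi")
}

make_ball_mask <- function(n, radius, spacing = c(1, 1, 1)) {
  cc <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  ball <- array(((g$x - cc)^2 + (g$y - cc)^2 + (g$z - cc)^2) <= radius^2,
                dim = c(n, n, n))
  roi_mask(ball, 1L, "ball", spacing)
}
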