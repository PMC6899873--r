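#' First-order statistical features
#'
#' The 18 first-order features computed from the raw in-mask intensities
#' (Entropy and Uniformity use the fixed-bin-number histogram of the
#' discretized ROI; Kurtosis is non-excess, i.e. a Gaussian gives 3;
#' skewness, kurtosis and variance use population moments).
#'
#' @param image a [volume_image()].
#' @param mask a [roi_mask()] on the same grid.
#' @param discretized the matching [discretize_fixed_bin_number()] result;
#'   computed on the fly when `NULL`.
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(image, mask, discretized = NULL) {
  x <- image$data[mask$mask]
  if (length(x) == 0) stop("empty mask")
  if (is.null(discretized))
    discretized <- discretize_fixed_bin_number(image, mask)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  p10 <- unname(quantile(x, 0.10))
  p90 <- unname(quantile(x, 0.90))
  p25 <- unname(quantile(x, 0.25))
  p75 <- unname(quantile(x, 0.75))
  voxvol <- prod(image$spacing)
  lv <- discretized$levels[discretized$levels > 0]
  p <- tabulate(lv, nbins = discretized$Ng) / length(lv)
  p <- p[p > 0]
  robust <- x[x >= p10 & x <= p90]
  c(
    `10Percentile` = p10,
    `90Percentile` = p90,
    Energy = sum(x^2),
    Entropy = -sum(p * log2(p + .eps)),
    InterquartileRange = p75 - p25,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Maximum = max(x),
    Mean = mu,
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    Median = median(x),
    Minimum = min(x),
    Range = max(x) - min(x),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    TotalEnergy = voxvol * sum(x^2),
    Uniformity = sum(p^2),
    Variance = m2
  )
}
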