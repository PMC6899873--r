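#' Intraclass correlation coefficient for absolute agreement, ICC(A,1)
#'
#' Two-way ANOVA without replication on an `n x k` matrix (rows: subjects,
#' here ROIs; columns: raters, here acquisition conditions):
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where MSR, MSC and MSE are the mean squares for rows, columns and
#' residual. An ICC of 1 means the conditions caused no change in the
#' measurement. When every entry of the matrix is identical the ratio is
#' 0/0; this degenerate case is defined as perfect agreement (ICC = 1).
#'
#' @param m numeric matrix, `n >= 2` rows and `k >= 2` columns, no missing
#'   values.
#' @return List of class `icc_result` with `icc`, `msr`, `msc`, `mse`,
#'   `n`, `k`.
#' @export
icc_a1 <- function(m) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) stop("ICC input must be finite")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("ICC needs at least 2 subjects and 2 raters")
  grand <- mean(m)
  rowm <- rowMeans(m)
  colm <- colMeans(m)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- max(0, sst - ssr - ssc)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  den <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- if (abs(den) < 1e-30) 1 else (msr - mse) / den
  structure(list(icc = icc, msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat("ICC(A,1) =", signif(x$icc, 5), " (n =", x$n, ", k =", x$k, ")\n")
  invisible(x)
}

#' Wilcoxon signed-rank test for paired ICC comparisons
#'
#' Two-sample paired test on `after - before`. Zero differences are
#' dropped; ranks of tied absolute differences are averaged. The exact null
#' distribution is used for up to 25 non-zero untied pairs (and exhaustive
#' sign enumeration up to 15 pairs when ties are present); otherwise a
#' normal approximation with tie and continuity corrections. Also reports
#' the median paired difference with its interquartile range, the reporting
#' format used for preprocessing effects.
#'
#' @param before,after equal-length numeric vectors of paired values.
#' @param alternative `"two.sided"`, `"greater"` (after > before) or
#'   `"less"`.
#' @return List with `statistic` (W+, sum of positive ranks), `p`,
#'   `median_diff`, `iqr_diff` (25th/75th percentiles), `n_nonzero`,
#'   `degenerate` (TRUE when all differences are zero, in which case
#'   `p = 1`), `method`.
#' @export
wilcoxon_signed_rank <- function(before, after,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  if (length(before) != length(after)) stop("paired vectors differ in length")
  d <- after - before
  med <- median(d)
  iqr <- unname(quantile(d, c(0.25, 0.75)))
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = NA_real_, p = 1, median_diff = med,
                iqr_diff = iqr, n_nonzero = 0L, degenerate = TRUE,
                method = "degenerate"))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  ties <- any(duplicated(r))
  if (!ties && n <= 25) {
    p <- switch(alternative,
      two.sided = min(1, 2 * min(stats::psignrank(w, n),
                                 1 - stats::psignrank(w - 1, n))),
      greater = 1 - stats::psignrank(w - 1, n),
      less = stats::psignrank(w, n))
    method <- "exact"
  } else if (ties && n <= 15) {
    # exhaustive enumeration of all 2^n sign assignments under H0
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- as.numeric(signs %*% r)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(mean(ws <= w), mean(ws >= w))),
      greater = mean(ws >= w),
      less = mean(ws <= w))
    method <- "enumeration"
  } else {
    mu <- n * (n + 1) / 4
    tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tab^3 - tab) / 48
    zstat <- function(x, cc) (x - mu + cc) / sqrt(sig2)
    p <- switch(alternative,
      two.sided = min(1, 2 * min(stats::pnorm(zstat(w, 0.5)),
                                 1 - stats::pnorm(zstat(w, -0.5)))),
      greater = 1 - stats::pnorm(zstat(w, -0.5)),
      less = stats::pnorm(zstat(w, 0.5)))
    method <- "normal"
  }
  list(statistic = w, p = p, median_diff = med, iqr_diff = iqr,
       n_nonzero = as.integer(n), degenerate = FALSE, method = method)
}

#' Select the stable feature set from per-analysis ICC tables
#'
#' An intensity feature (first-order or textural) is stable iff its ICC
#' strictly exceeds the threshold in all four stability analyses; a
#' shape/size feature is judged on the voxel-size analysis (analysis 2)
#' only, since TR/TE, noise and intensity non-uniformity do not affect the
#' binary mask geometry.
#'
#' @param icc_tables named list `analysis1`..`analysis4`, each a named
#'   numeric vector of per-feature ICC (preprocessed images).
#' @param threshold stability threshold (default 0.75, strict `>`).
#' @param manifest feature manifest (default [feature_manifest()]).
#' @return Character vector of stable feature names.
#' @export
select_stable <- function(icc_tables, threshold = 0.75,
                          manifest = feature_manifest()) {
  need <- paste0("analysis", 1:4)
  if (!all(need %in% names(icc_tables)))
    stop("icc_tables must contain analysis1..analysis4")
  shape <- manifest$feature[manifest$group == "SS"]
  intensity <- manifest$feature[manifest$group != "SS"]
  for (a in need) {
    have <- names(icc_tables[[a]])
    miss <- if (a == "analysis2") setdiff(manifest$feature, have)
            else setdiff(intensity, have)
    if (length(miss) > 0)
      stop("missing ICC values in ", a, ": ", paste(head(miss, 3),
                                                    collapse = ", "))
  }
  ok_shape <- shape[icc_tables$analysis2[shape] > threshold]
  ok_int <- intensity[Reduce(`&`, lapply(need, function(a)
    icc_tables[[a]][intensity] > threshold))]
  manifest$feature[manifest$feature %in% c(ok_shape, ok_int)]
}

#' Jaccard index of two feature sets
#'
#' `|A intersect B| / |A union B|`; two empty sets are defined as
#' identical (index 1, with a warning).
#'
#' @param setA,setB character vectors.
#' @return Numeric in `[0, 1]`.
#' @export
jaccard_index <- function(setA, setB) {
  u <- union(setA, setB)
  if (length(u) == 0) {
    warning("both sets empty; Jaccard index defined as 1")
    return(1)
  }
  length(intersect(setA, setB)) / length(u)
}

#' Confirm the stable set on the random-parameter analysis
#'
#' @param stable_set character vector of stable feature names.
#' @param icc_analysis5 named numeric vector of per-feature ICC from the
#'   random-parameter acquisitions.
#' @param threshold stability threshold (strict `>`).
#' @return List with `confirmed` (character vector, subset of
#'   `stable_set`), `fraction` (in percent).
#' @export
confirm_on_random <- function(stable_set, icc_analysis5, threshold = 0.75) {
  if (length(stable_set) == 0) stop("stable set is empty")
  miss <- setdiff(stable_set, names(icc_analysis5))
  if (length(miss) > 0)
    stop("analysis-5 ICC missing for: ", paste(head(miss, 3), collapse = ", "))
  confirmed <- stable_set[icc_analysis5[stable_set] > threshold]
  list(confirmed = confirmed,
       fraction = 100 * length(confirmed) / length(stable_set))
}
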