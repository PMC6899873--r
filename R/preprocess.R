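#' Preprocessing configuration
#'
#' @param zscore_region which voxels define the Z-score statistics:
#'   `"whole_image_nonzero"` (default; all strictly positive/nonzero
#'   voxels) or `"union_of_rois"`.
#' @param iso_spacing target isotropic spacing for resampling (mm).
#' @param gauss_kernel Gaussian denoising kernel size per axis (odd,
#'   default 3).
#' @param gauss_sigma Gaussian sigma (voxels, default 0.5).
#' @param bias_fwhm smoothness scale (mm) of the estimated bias field.
#' @param bias_iters rounds of log-domain field refinement.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(zscore_region = c("whole_image_nonzero",
                                                "union_of_rois"),
                              iso_spacing = 1, gauss_kernel = 3,
                              gauss_sigma = 0.5, bias_fwhm = 40,
                              bias_iters = 4) {
  zscore_region <- match.arg(zscore_region)
  if (iso_spacing <= 0) stop("iso_spacing must be positive")
  if (gauss_kernel %% 2 == 0) stop("gauss_kernel must be odd")
  if (gauss_sigma <= 0) stop("gauss_sigma must be positive")
  structure(list(zscore_region = zscore_region, iso_spacing = iso_spacing,
                 gauss_kernel = as.integer(gauss_kernel),
                 gauss_sigma = gauss_sigma, bias_fwhm = bias_fwhm,
                 bias_iters = as.integer(bias_iters)),
            class = "preprocess_config")
}

#' Z-score intensity normalization
#'
#' Standardizes intensities to zero mean and unit standard deviation over a
#' region: `out = (image - mean(region)) / sd(region)`. Invariant to affine
#' intensity transforms `a * x + b` (a > 0) of the input, and idempotent.
#'
#' @param image a [volume_image()].
#' @param region logical 3D array selecting the normalization region;
#'   `NULL` uses all nonzero voxels.
#' @return A standardized [volume_image()].
#' @export
zscore_normalize <- function(image, region = NULL) {
  if (is.null(region)) region <- image$data != 0
  vals <- image$data[region]
  if (length(vals) < 2) stop("normalization region must have >= 2 voxels")
  s <- sd(vals)
  if (s == 0) stop("zero variance in normalization region")
  volume_image((image$data - mean(vals)) / s, image$spacing,
               provenance = c(image$provenance, list(zscore = TRUE)))
}

#' Gaussian denoising with a small truncated kernel
#'
#' Separable discrete Gaussian truncated to a `kernel^3` stencil and
#' renormalized to sum 1 (so constant images are unchanged and the interior
#' mean is preserved).
#'
#' @param image a [volume_image()].
#' @param kernel kernel size per axis (odd, default 3 as in a 3x3x3
#'   stencil).
#' @param sigma Gaussian sigma in voxels (default 0.5).
#' @return A smoothed [volume_image()].
#' @export
gaussian_denoise <- function(image, kernel = 3, sigma = 0.5) {
  if (kernel %% 2 == 0) stop("kernel size must be odd")
  if (sigma <= 0) stop("sigma must be positive")
  r <- (kernel - 1) %/% 2
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  out <- image$data
  for (ax in 1:3) out <- conv_axis(out, k, ax)
  volume_image(out, image$spacing,
               provenance = c(image$provenance, list(denoised = TRUE)))
}

#' Estimate and remove a smooth multiplicative bias field
#'
#' Iterative log-domain estimator: the logarithm of the foreground image is
#' repeatedly decomposed into a smooth component (wide Gaussian smoothing
#' with foreground-weighted normalized convolution, smoothness set by
#' `bias_fwhm`) that is accumulated into the field estimate, and a residual
#' that carries tissue structure. The estimated field is smooth, strictly
#' positive and normalized to mean 1 over the foreground; the corrected
#' image is `image / field`.
#'
#' @param image a [volume_image()] with non-negative intensities.
#' @param config a [preprocess_config()].
#' @return List with elements `corrected` (a [volume_image()]) and `field`
#'   (3D array).
#' @export
correct_bias_field <- function(image, config = preprocess_config()) {
  a <- image$data
  fg <- a > 0
  if (!any(fg)) stop("no positive foreground intensities to correct")
  floorv <- stats::quantile(a[fg], 0.01)
  L <- log(pmax(a, floorv))
  sigma_vox <- (config$bias_fwhm / 2.355) / image$spacing
  w <- array(as.numeric(fg), dim = dim(a))
  f <- array(0, dim = dim(a))
  den <- pmax(gaussian_smooth3(w, sigma_vox), 1e-8)
  for (it in seq_len(config$bias_iters)) {
    r <- L - f
    s <- gaussian_smooth3(r * w, sigma_vox) / den
    s <- s - mean(s[fg])
    f <- f + s
  }
  field <- exp(f)
  field <- field / mean(field[fg])
  corrected <- a / field
  list(corrected = volume_image(corrected, image$spacing,
                                provenance = c(image$provenance,
                                               list(bias_corrected = TRUE))),
       field = field)
}

#' Apply an ordered preprocessing pipeline
#'
#' Applies a subset of the four preprocessing operators in the given order;
#' whenever the image grid changes (resampling), the ROI masks are carried
#' along with nearest-neighbour interpolation.
#'
#' @param image a [volume_image()].
#' @param masks list of [roi_mask()] on the same grid as `image`.
#' @param steps ordered character subset of
#'   `c("bias", "denoise", "resample", "zscore")`.
#' @param config a [preprocess_config()].
#' @return List with `image` (processed volume) and `masks` (on the final
#'   grid).
#' @export
apply_pipeline <- function(image, masks, steps,
                           config = preprocess_config()) {
  if (length(steps) == 0) stop("steps must be non-empty")
  steps <- match.arg(steps, c("bias", "denoise", "resample", "zscore"),
                     several.ok = TRUE)
  for (s in steps) {
    if (s == "bias") {
      image <- correct_bias_field(image, config)$corrected
    } else if (s == "denoise") {
      image <- gaussian_denoise(image, config$gauss_kernel,
                                config$gauss_sigma)
    } else if (s == "resample") {
      target <- rep(config$iso_spacing, 3)
      if (!isTRUE(all.equal(image$spacing, target, tolerance = 1e-12))) {
        image <- resample_volume(image, target, "linear")
        masks <- lapply(masks, function(m) {
          v <- volume_image(array(as.numeric(m$mask), dim = dim(m$mask)),
                            m$spacing)
          r <- resample_volume(v, target, "nearest")
          md <- r$data > 0.5
          if (!any(md)) md[which.max(r$data)] <- TRUE # guard tiny ROIs
          roi_mask(md, m$tissue_id, m$name, target)
        })
      }
    } else if (s == "zscore") {
      region <- if (config$zscore_region == "union_of_rois") {
        if (length(masks) == 0)
          stop("zscore with union_of_rois requires masks on the current grid")
        Reduce(`|`, lapply(masks, function(m) {
          if (!all(dim(m$mask) == dim(image$data)))
            stop("zscore requires masks on the current image grid")
          m$mask
        }))
      } else NULL
      image <- zscore_normalize(image, region)
    }
  }
  list(image = image, masks = masks)
}
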