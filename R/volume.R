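#' Construct a 3D scalar volume with voxel-spacing metadata
#'
#' The basic unit of acquisition and preprocessing: a 3D numeric array plus
#' the physical size (mm) of a voxel along each axis. The third axis is the
#' axial (slice) direction. Voxel centres sit at `(i - 0.5) * spacing`
#' in world coordinates, so all grids over the same field of view share one
#' physical space.
#'
#' @param data 3D numeric array of finite values.
#' @param spacing numeric length-3, voxel size in mm (x, y, z); all > 0.
#' @param provenance free-form list recording how the volume was produced.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), provenance = list()) {
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  if (!all(is.finite(data))) stop("volume values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive values (mm)")
  structure(list(data = data, spacing = spacing, provenance = provenance),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$data), collapse = " x "),
      " voxels @ ", paste(signif(x$spacing, 4), collapse = " x "), " mm\n",
      sep = "")
  cat("  intensity range: [", signif(min(x$data), 5), ", ",
      signif(max(x$data), 5), "]\n", sep = "")
  invisible(x)
}

#' Construct an ROI mask aligned to a volume grid
#'
#' @param mask 3D logical array with at least one `TRUE` voxel.
#' @param tissue_id integer tissue label the mask was derived from.
#' @param name tissue name.
#' @param spacing voxel size (mm) of the grid the mask lives on.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, tissue_id, name, spacing = c(1, 1, 1)) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!any(mask)) stop("mask must contain at least one voxel")
  structure(list(mask = mask, tissue_id = as.integer(tissue_id),
                 name = as.character(name), spacing = as.numeric(spacing)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("<roi_mask> '", x$name, "' (tissue ", x$tissue_id, "): ",
      sum(x$mask), " voxels\n", sep = "")
  invisible(x)
}

# physical extent (mm) covered by a grid
grid_extent <- function(dims, spacing) dims * spacing

#' Resample a volume to a new voxel spacing
#'
#' Cell-centred resampling that preserves the physical extent of the volume
#' (to within one voxel): the output grid spans the same field of view and
#' world-coordinate alignment is preserved. Intensities use trilinear
#' interpolation; masks must use nearest-neighbour.
#'
#' @param image a [volume_image()].
#' @param target_spacing numeric length-3 (or scalar, recycled), mm.
#' @param interpolation `"linear"` (intensities) or `"nearest"` (labels).
#' @return A resampled [volume_image()].
#' @export
resample_volume <- function(image, target_spacing,
                            interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  target_spacing <- rep(as.numeric(target_spacing), length.out = 3L)
  if (any(target_spacing <= 0)) stop("target spacing must be positive")
  sp <- image$spacing
  if (isTRUE(all.equal(sp, target_spacing, tolerance = 1e-12)))
    return(image)
  dims <- dim(image$data)
  extent <- grid_extent(dims, sp)
  ndims <- pmax(1L, as.integer(round(extent / target_spacing)))
  # continuous (1-based, cell-centred) source coordinates of target centres
  coord <- function(ax) ((seq_len(ndims[ax]) - 0.5) * target_spacing[ax]) /
    sp[ax] + 0.5
  cx <- coord(1); cy <- coord(2); cz <- coord(3)
  out <- interp3(image$data, cx, cy, cz, interpolation)
  volume_image(out, target_spacing,
               provenance = c(image$provenance,
                              list(resampled_to = target_spacing)))
}

# separable trilinear / nearest interpolation at the outer grid cx x cy x cz
# of continuous 1-based array coordinates
interp3 <- function(a, cx, cy, cz, interpolation) {
  d <- dim(a)
  if (interpolation == "nearest") {
    ix <- pmin(pmax(round(cx), 1L), d[1])
    iy <- pmin(pmax(round(cy), 1L), d[2])
    iz <- pmin(pmax(round(cz), 1L), d[3])
    return(a[ix, iy, iz, drop = FALSE])
  }
  lo <- function(c, n) pmin(pmax(floor(c), 1L), n)
  fx0 <- lo(cx, d[1] - 1L); fy0 <- lo(cy, d[2] - 1L); fz0 <- lo(cz, d[3] - 1L)
  if (d[1] == 1L) fx0 <- rep(1L, length(cx))
  if (d[2] == 1L) fy0 <- rep(1L, length(cy))
  if (d[3] == 1L) fz0 <- rep(1L, length(cz))
  wx <- pmin(pmax(cx - fx0, 0), 1); wy <- pmin(pmax(cy - fy0, 0), 1)
  wz <- pmin(pmax(cz - fz0, 0), 1)
  up <- function(f, n) pmin(f + 1L, n)
  out <- array(0, dim = c(length(cx), length(cy), length(cz)))
  for (bx in 0:1) for (by in 0:1) for (bz in 0:1) {
    ix <- if (bx == 0) fx0 else up(fx0, d[1])
    iy <- if (by == 0) fy0 else up(fy0, d[2])
    iz <- if (bz == 0) fz0 else up(fz0, d[3])
    ux <- if (bx == 0) 1 - wx else wx
    uy <- if (by == 0) 1 - wy else wy
    uz <- if (bz == 0) 1 - wz else wz
    w <- outer(outer(ux, uy), uz)
    out <- out + a[ix, iy, iz, drop = FALSE] * w
  }
  out
}

# 1D convolution along one axis of a 3D array with a symmetric kernel,
# renormalizing at the borders (constant volumes are preserved exactly)
conv_axis <- function(a, kernel, axis) {
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(a * kernel)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  b <- aperm(a, perm)
  d <- dim(b)
  n <- d[1]
  conv <- cpp_conv_cols(matrix(b, nrow = n), kernel)
  norm <- as.numeric(cpp_conv_cols(matrix(1, n, 1), kernel))
  out <- array(conv / norm, dim = d)
  aperm(out, order(perm))
}

# separable Gaussian smoothing; sigma in voxels per axis
gaussian_smooth3 <- function(a, sigma, radius = NULL) {
  sigma <- rep(sigma, length.out = 3L)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    r <- if (is.null(radius)) max(1L, ceiling(3 * sigma[ax])) else radius
    k <- exp(-((-r:r)^2) / (2 * sigma[ax]^2))
    k <- k / sum(k)
    a <- conv_axis(a, k, ax)
  }
  a
}

# boxcar average along z of an (odd or even) window in voxels; truncated,
# renormalized at the borders
boxcar_z <- function(a, width) {
  width <- as.integer(width)
  if (width <= 1L) return(a)
  k <- rep(1 / width, width)
  if (width %% 2L == 0L) k <- c(k, 0) # centre even windows on the grid
  conv_axis(a, k / sum(k), 3L)
}
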