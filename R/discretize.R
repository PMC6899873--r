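#' Fixed-bin-number gray-level discretization
#'
#' Partitions the in-mask intensity range `[min, max]` into `Ng` equal-width
#' bins; each voxel is assigned a level in `1..Ng` (the maximum maps to
#' level `Ng`; bins are half-open with the last bin closed). A constant ROI
#' maps every voxel to level 1 by convention. Min-max binning makes the
#' level volume invariant to affine intensity transforms with positive
#' slope.
#'
#' @param image a [volume_image()].
#' @param mask a [roi_mask()] on the same grid.
#' @param Ng number of gray levels (default 32).
#' @return An object of class `discretized_roi` with fields `levels` (3D
#'   integer array over the mask bounding box, 0 outside the mask), `Ng`,
#'   `bin_edges`, `n_voxels`.
#' @export
discretize_fixed_bin_number <- function(image, mask, Ng = 32) {
  if (!all(dim(mask$mask) == dim(image$data)))
    stop("mask and image grids differ")
  bb <- mask_bbox(mask$mask)
  m <- mask$mask[bb$x, bb$y, bb$z, drop = FALSE]
  a <- image$data[bb$x, bb$y, bb$z, drop = FALSE]
  vals <- a[m]
  lo <- min(vals); hi <- max(vals)
  levels <- array(0L, dim = dim(m))
  if (hi == lo) {
    levels[m] <- 1L
    edges <- lo + seq(0, 1, length.out = Ng + 1) # degenerate-range convention
  } else {
    width <- (hi - lo) / Ng
    lv <- pmin(floor((vals - lo) / width) + 1, Ng)
    levels[m] <- as.integer(lv)
    edges <- lo + width * (0:Ng)
  }
  structure(list(levels = levels, Ng = as.integer(Ng), bin_edges = edges,
                 n_voxels = length(vals)),
            class = "discretized_roi")
}

mask_bbox <- function(mask) {
  ix <- which(apply(mask, 1, any))
  iy <- which(apply(mask, 2, any))
  iz <- which(apply(mask, 3, any))
  list(x = min(ix):max(ix), y = min(iy):max(iy), z = min(iz):max(iz))
}
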