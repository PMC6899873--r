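#' Shape and size features
#'
#' The 14 three-dimensional shape descriptors of an ROI, all in physical
#' units. Surface area and mesh volume come from a triangulated isosurface
#' of the binary mask (marching tetrahedra on the Kuhn cube decomposition,
#' vertices at edge midpoints); axis lengths derive from the principal
#' components of the physical voxel-centre coordinates
#' (`4 * sqrt(eigenvalue)`); diameters are maximum pairwise distances
#' between surface voxel centres, in 3D and within planes fixing the slice,
#' column and row axes.
#'
#' @param mask a [roi_mask()].
#' @param spacing voxel size (mm); defaults to the mask's own spacing.
#' @return Named numeric vector of 14 features (mm, mm^2, mm^3 as
#'   appropriate).
#' @export
shape_features <- function(mask, spacing = mask$spacing) {
  m <- mask$mask
  if (!any(m)) stop("empty mask")
  bb <- mask_bbox(m)
  m <- m[bb$x, bb$y, bb$z, drop = FALSE]
  n <- sum(m)
  mv <- mesh_area_volume(m, spacing)
  surface <- unname(mv["surface_area"])
  meshvol <- unname(mv["mesh_volume"])
  idx <- which(m, arr.ind = TRUE)
  coords <- sweep(idx - 0.5, 2, spacing, `*`)
  # principal axes from the covariance of physical voxel centres
  if (n > 1) {
    ev <- sort(eigen(stats::cov(coords), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2]); least <- 4 * sqrt(ev[3])
  elong <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1
  flat <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  dm <- max_diameters(idx, coords)
  c(
    Elongation = elong,
    Flatness = flat,
    LeastAxisLength = least,
    MajorAxisLength = major,
    Maximum2DDiameterColumn = unname(dm["column"]),
    Maximum2DDiameterRow = unname(dm["row"]),
    Maximum2DDiameterSlice = unname(dm["slice"]),
    Maximum3DDiameter = unname(dm["d3"]),
    MeshVolume = meshvol,
    MinorAxisLength = minor,
    Sphericity = if (surface > 0)
      (36 * pi * meshvol^2)^(1 / 3) / surface else 1,
    SurfaceArea = surface,
    SurfaceVolumeRatio = if (meshvol > 0) surface / meshvol else NA_real_,
    VoxelVolume = n * prod(spacing)
  )
}

# Isosurface area/volume of a binary mask. The indicator is lightly
# smoothed (Gaussian, sigma 1 voxel) before meshing so the 0.5 isosurface
# is antialiased rather than a voxel staircase; a thin structure whose
# smoothed indicator drops below 0.5 everywhere falls back to the raw
# binary surface.
mesh_area_volume <- function(m, spacing) {
  d <- dim(m)
  pad <- 4L
  f <- array(0, dim = d + 2L * pad)
  f[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(m)
  fs <- gaussian_smooth3(f, sigma = 1)
  mv <- cpp_mesh_area_volume(fs, as.numeric(spacing), 0.5)
  if (mv["mesh_volume"] < 0.25 * sum(m) * prod(spacing))
    mv <- cpp_mesh_area_volume(f, as.numeric(spacing), 0.5)
  mv
}

# per-group axis extremes: indices of rows attaining min/max of `val`
# within each group (exact superset of the convex-hull vertices along that
# axis, so maximum pairwise distances computed on them are exact)
axis_extremes <- function(val, grp) {
  o <- order(grp, val)
  g <- grp[o]
  c(o[!duplicated(g)], o[!duplicated(g, fromLast = TRUE)])
}

# exact maximum pairwise distances: 3D, and 2D within planes fixing the
# slice (z), column (x) and row (y) axes; candidate points are reduced to
# per-column extremes before the quadratic search
max_diameters <- function(idx, coords) {
  ix <- idx[, 1]; iy <- idx[, 2]; iz <- idx[, 3]
  key <- function(a, b) a + (max(a) + 1) * b
  cand3 <- unique(c(axis_extremes(ix, key(iy, iz)),
                    axis_extremes(iy, key(ix, iz)),
                    axis_extremes(iz, key(ix, iy))))
  d3 <- cpp_max_dist(coords[cand3, , drop = FALSE],
                     rep(0L, length(cand3)))
  plane_max <- function(fix, a, b, cols) {
    cand <- unique(c(axis_extremes(a, key(b, fix)),
                     axis_extremes(b, key(a, fix))))
    cpp_max_dist(coords[cand, cols, drop = FALSE], as.integer(fix[cand]))
  }
  c(d3 = d3,
    slice = plane_max(iz, ix, iy, c(1, 2)),
    column = plane_max(ix, iy, iz, c(2, 3)),
    row = plane_max(iy, ix, iz, c(1, 3)))
}
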