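#' Default tissue relaxometry table
#'
#' Per-tissue longitudinal relaxation time T1 (ms), transverse relaxation
#' time T2 (ms) and proton density PD (relative, 0-1) representative of
#' head tissues at 1.5 T. These are editable inputs of the simulation, not
#' asserted physical constants; users may supply their own table (e.g. read
#' from JSON with [read_tissues()]) to [build_default_phantom()]. A copy of
#' this table ships as
#' `system.file("extdata", "tissues_1p5T.json", package = "radstab")`.
#' The `texture_sd` and `texture_scale` columns set the relative amplitude
#' and spatial correlation length (voxels) of each tissue's within-region
#' intensity texture.
#'
#' @return data.frame with columns `id`, `name`, `T1`, `T2`, `PD`.
#' @export
default_tissues <- function() {
  data.frame(
    id   = 1:10,
    name = c("csf", "gray_matter", "white_matter", "fat", "muscle",
             "skin", "skull", "glial_matter", "connective_tissue", "marrow"),
    T1   = c(2569, 833, 500, 350, 900, 570, 380, 790, 600, 420),
    T2   = c(329, 83, 70, 70, 47, 30, 20, 90, 55, 45),
    PD   = c(1.00, 0.86, 0.77, 1.00, 1.00, 0.85, 0.15, 0.88, 0.70, 0.90),
    # within-tissue texture: relative amplitude and spatial correlation
    # scale (voxels) of the intensity variation each tissue exhibits
    texture_sd    = c(0.04, 0.10, 0.06, 0.12, 0.09, 0.08, 0.14, 0.11,
                      0.13, 0.07),
    texture_scale = c(2.2, 1.0, 1.6, 0.7, 1.3, 0.9, 0.6, 1.9, 1.1, 2.5),
    stringsAsFactors = FALSE
  )
}

validate_tissues <- function(tissues) {
  stopifnot(all(c("id", "name", "T1", "T2", "PD") %in% names(tissues)))
  if (any(tissues$T2 <= 0) || any(tissues$T1 <= tissues$T2))
    stop("tissue table must satisfy T1 > T2 > 0")
  if (any(tissues$PD <= 0) || any(tissues$PD > 1))
    stop("tissue PD must lie in (0, 1]")
  invisible(tissues)
}

#' Build the default digital head phantom
#'
#' Constructs a brain-like nested-ellipsoid label volume at 1 mm isotropic
#' spacing: concentric shells (skin, fat, skull, CSF, gray matter) around a
#' white-matter core, with seeded ellipsoidal inclusions of four further
#' tissues (glial matter, connective tissue, muscle, marrow) embedded in the
#' core. A smooth, fine-grained multiplicative texture field (unit mean) is
#' attached; it modulates the per-voxel proton density and, more weakly, T1
#' and T2, so that each tissue shows realistic within-region intensity
#' variation rather than a flat plateau.
#'
#' @param size voxels per axis (cubic volume), at least 32.
#' @param seed integer; fixes inclusion placement, ellipsoid axis ratios
#'   and the texture field. Deterministic: equal seeds give identical
#'   phantoms.
#' @param tissues tissue property table, see [default_tissues()].
#' @param texture_sd relative standard deviation of the within-tissue
#'   texture field (default 0.08).
#' @return An object of class `tissue_phantom` with fields `labels`
#'   (3D integer array, 0 = background), `spacing`, `tissues`, `texture`.
#' @export
build_default_phantom <- function(size = 64, seed = 1,
                                  tissues = default_tissues(),
                                  texture_sd = 0.08) {
  size <- as.integer(size)
  if (size < 32) stop("phantom too small: size must be at least 32 voxels")
  validate_tissues(tissues)
  with_seed(seed, {
    ax <- (seq_len(size) - (size + 1) / 2) / (size / 2)
    X <- array(rep(ax, times = size * size), dim = rep(size, 3))
    Y <- aperm(X, c(2, 1, 3))
    Z <- aperm(X, c(3, 2, 1))
    # head ellipsoid: clearly anisotropic semi-axes (A-P > L-R > S-I),
    # mildly randomized, so in-plane shape descriptors carry real signal
    semi <- 0.95 * c(1, 0.86, 0.76) * (1 + runif(3, -0.03, 0.03))
    rho <- sqrt((X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2)
    labels <- array(0L, dim = rep(size, 3))
    shells <- rbind( # tissue id, inner rho, outer rho
      c(6L, 0.93, 1.00),  # skin
      c(4L, 0.87, 0.93),  # fat
      c(7L, 0.78, 0.87),  # skull
      c(1L, 0.72, 0.78),  # csf
      c(2L, 0.55, 0.72),  # gray matter
      c(3L, 0.00, 0.55))  # white matter core
    for (i in seq_len(nrow(shells)))
      labels[rho > shells[i, 2] & rho <= shells[i, 3]] <- as.integer(shells[i, 1])
    # ellipsoidal inclusions inside the white-matter core, non-overlapping
    incl <- c(8L, 9L, 5L, 10L) # glial, connective, muscle, marrow
    centres <- matrix(NA_real_, 0, 3)
    for (id in incl) {
      repeat {
        ctr <- runif(3, -0.28, 0.28)
        if (nrow(centres) == 0 ||
            min(sqrt(rowSums(sweep(centres, 2, ctr)^2))) > 0.26) break
      }
      centres <- rbind(centres, ctr)
      rad <- 0.17 * (1 + runif(3, -0.35, 0.35)) # anisotropic inclusions
      d <- sqrt(((X - ctr[1]) / rad[1])^2 + ((Y - ctr[2]) / rad[2])^2 +
                  ((Z - ctr[3]) / rad[3])^2)
      labels[d <= 1 & labels == 3L] <- id
    }
    # within-tissue texture: each tissue gets its own smoothed-noise field
    # with a tissue-specific amplitude and correlation length, so regions
    # differ in spatial structure (as real tissues do), not only in mean
    # signal
    texture <- array(1, dim = rep(size, 3))
    has_cfg <- all(c("texture_sd", "texture_scale") %in% names(tissues))
    for (ti in seq_len(nrow(tissues))) {
      sel <- labels == tissues$id[ti]
      if (!any(sel)) next
      g <- array(rnorm(size^3), dim = rep(size, 3))
      scale <- if (has_cfg) tissues$texture_scale[ti] else 1
      amp <- if (has_cfg) texture_sd * tissues$texture_sd[ti] / 0.08
             else texture_sd
      g <- gaussian_smooth3(g, sigma = scale)
      g <- (g - mean(g)) / sd(g)
      texture[sel] <- 1 + amp * pmin(pmax(g[sel], -3), 3)
    }
    phantom <- structure(list(labels = labels, spacing = c(1, 1, 1),
                              tissues = tissues, texture = texture,
                              seed = as.integer(seed)),
                         class = "tissue_phantom")
    validate_phantom(phantom)
    phantom
  })
}

validate_phantom <- function(phantom) {
  counts <- table(phantom$labels[phantom$labels > 0])
  if (sum(counts >= 200) < 5)
    stop("phantom too small: fewer than 5 tissue classes with >= 200 voxels")
  ids <- as.integer(names(counts))
  if (!all(ids %in% phantom$tissues$id))
    stop("every nonzero label must have a tissue table entry")
  invisible(phantom)
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat("<tissue_phantom> ", paste(dim(x$labels), collapse = " x "),
      " voxels @ ", paste(x$spacing, collapse = " x "), " mm, ",
      length(unique(x$labels[x$labels > 0])), " tissue classes\n", sep = "")
  invisible(x)
}

#' Extract per-tissue ROI masks restricted to central axial slices
#'
#' One mask per tissue class present in the phantom, each restricted to the
#' `n_slices` axial slices centred on that tissue's own axial extent (large
#' regions are trimmed to keep texture-matrix extraction tractable, small
#' regions are unaffected). Masks are defined on the native phantom grid
#' and can be transferred to any acquisition grid with
#' [resample_volume()] using nearest-neighbour interpolation.
#'
#' @param phantom a [build_default_phantom()] result.
#' @param n_slices number of central axial slices to keep (default 11).
#' @return List of [roi_mask()] objects, one per tissue with a non-empty
#'   restricted mask (empty ones are dropped with a warning).
#' @export
extract_rois <- function(phantom, n_slices = 11) {
  ids <- sort(unique(phantom$labels[phantom$labels > 0]))
  half <- (n_slices - 1) %/% 2
  out <- list()
  for (id in ids) {
    m <- phantom$labels == id
    zs <- which(apply(m, 3, any))
    if (length(zs) == 0) next
    centre <- floor((min(zs) + max(zs)) / 2)
    keep <- intersect(seq(centre - half, centre + (n_slices - 1) - half), zs)
    mm <- array(FALSE, dim = dim(m))
    mm[, , keep] <- m[, , keep]
    if (!any(mm)) {
      warning("tissue ", id, " has an empty mask after slice restriction; ",
              "excluded")
      next
    }
    nm <- phantom$tissues$name[match(id, phantom$tissues$id)]
    out[[nm]] <- roi_mask(mm, id, nm, phantom$spacing)
  }
  out
}
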