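#' Steady-state spin-echo signal
#'
#' Closed-form spin-echo magnitude signal
#' \deqn{S = PD \cdot (1 - e^{-TR/T1}) \cdot e^{-TE/T2}.}
#' The signal saturates to PD for long TR, increases strictly with TR and
#' decreases strictly with TE.
#'
#' @param T1,T2 relaxation times (ms), positive; vectors allowed.
#' @param PD proton density in (0, 1].
#' @param TR repetition time (ms), positive.
#' @param TE echo time (ms), non-negative.
#' @return Dimensionless signal in `[0, PD]`.
#' @export
spin_echo_signal <- function(T1, T2, PD, TR, TE) {
  if (any(T1 <= 0) || any(T2 <= 0) || any(TR <= 0))
    stop("T1, T2 and TR must be positive")
  if (any(TE < 0)) stop("TE must be non-negative")
  PD * (1 - exp(-TR / T1)) * exp(-TE / T2)
}

#' Acquisition parameters for one simulated scan
#'
#' @param modality `"T1w"` or `"T2w"`.
#' @param TR,TE repetition/echo time (ms), `0 < TE < TR`.
#' @param pixel_spacing in-plane voxel size (mm, isotropic), at least the
#'   native spacing.
#' @param slice_thickness axial voxel size (mm), at least the native spacing.
#' @param noise_pct Rician noise level, percent of the brightest-tissue
#'   signal per quadrature channel, in `[0, 100]`.
#' @param inu_pct intensity-non-uniformity amplitude in percent (40 means a
#'   multiplicative field spanning `[0.8, 1.2]`), in `[0, 100]`.
#' @param inu_field_id which of the three fixed inhomogeneity patterns to
#'   apply (1, 2 or 3).
#' @param seed integer seed for the stochastic degradations.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(modality, TR, TE, pixel_spacing = 1,
                               slice_thickness = 1, noise_pct = 0,
                               inu_pct = 0, inu_field_id = 1, seed = 1) {
  modality <- match.arg(modality, c("T1w", "T2w"))
  if (!(TE > 0 && TE < TR)) stop("requires 0 < TE < TR")
  if (pixel_spacing <= 0 || slice_thickness <= 0)
    stop("voxel sizes must be positive")
  if (noise_pct < 0 || noise_pct > 100) stop("noise_pct must be in [0, 100]")
  if (inu_pct < 0 || inu_pct > 100) stop("inu_pct must be in [0, 100]")
  if (!inu_field_id %in% 1:3) stop("inu_field_id must be 1, 2 or 3")
  structure(list(modality = modality, TR = TR, TE = TE,
                 pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness, noise_pct = noise_pct,
                 inu_pct = inu_pct, inu_field_id = as.integer(inu_field_id),
                 seed = as.integer(seed)),
            class = "acquisition_params")
}

#' Generate a smooth multiplicative intensity-non-uniformity field
#'
#' Three fixed low-order spatial patterns are available: (1) a linear ramp,
#' (2) a quadratic bowl and (3) a diagonal saddle, each lightly smoothed.
#' The pattern is centred (zero mean) and scaled so the field lies within
#' `[1 - inu_pct/200, 1 + inu_pct/200]` (40% gives `[0.8, 1.2]`) with a
#' volume mean of 1 within 0.01.
#'
#' @param shape integer length-3 voxel dimensions.
#' @param inu_pct non-uniformity amplitude in percent; 0 gives an all-ones
#'   field.
#' @param field_id pattern selector in `{1, 2, 3}`.
#' @param seed seed for the small smoothed-noise component that makes the
#'   patterns non-degenerate.
#' @return 3D array of multiplicative field values.
#' @export
make_inu_field <- function(shape, inu_pct, field_id = 1, seed = 1) {
  if (inu_pct < 0) stop("inu_pct must be non-negative")
  if (!field_id %in% 1:3) stop("inu_field_id must be 1, 2 or 3")
  shape <- as.integer(rep(shape, length.out = 3L))
  if (inu_pct == 0) return(array(1, dim = shape))
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  u <- function(n) if (n == 1) 0 else (seq_len(n) - (n + 1) / 2) / ((n - 1) / 2)
  X <- array(rep(u(nx), times = ny * nz), dim = shape)
  Y <- aperm(array(rep(u(ny), times = nx * nz), dim = c(ny, nx, nz)),
             c(2, 1, 3))
  Z <- aperm(array(rep(u(nz), times = nx * ny), dim = c(nz, nx, ny)),
             c(2, 3, 1))
  pattern <- switch(field_id,
                    X + 0.25 * Y,                       # ramp
                    (X^2 + Y^2 + Z^2) / 3,              # bowl
                    X * Y + 0.5 * Z)                    # saddle
  wob <- with_seed(seed + 1000L * field_id, {
    g <- array(rnorm(prod(shape)), dim = shape)
    g <- gaussian_smooth3(g, sigma = max(2, min(shape) / 8))
    g / max(abs(g), .eps)
  })
  pattern <- pattern + 0.05 * wob
  pattern <- gaussian_smooth3(pattern, sigma = 1.5)
  pattern <- pattern - mean(pattern)
  pattern <- pattern / max(abs(pattern))
  1 + (inu_pct / 200) * pattern
}

#' Add Rician noise to a magnitude image
#'
#' Models MRI magnitude noise: independent zero-mean Gaussian noise of
#' standard deviation `sigma = noise_pct/100 * reference` is added to the
#' real (signal) and imaginary quadrature channels, and the magnitude is
#' taken: `out = sqrt((S + n1)^2 + n2^2)`. On zero-signal background this
#' yields a Rayleigh distribution with mean `sigma * sqrt(pi/2)`.
#'
#' @param image a [volume_image()].
#' @param noise_pct percent noise level; 0 returns the input unchanged.
#' @param reference reference signal level the percentage applies to
#'   (conventionally the brightest tissue's mean signal).
#' @param seed integer seed; equal seeds give identical noise.
#' @return A [volume_image()] with Rician-distributed intensities.
#' @export
add_rician_noise <- function(image, noise_pct, reference, seed = 1) {
  if (noise_pct < 0) stop("noise_pct must be non-negative")
  if (noise_pct == 0) return(image)
  if (reference <= 0) stop("reference signal level must be positive")
  sigma <- (noise_pct / 100) * reference
  n <- length(image$data)
  with_seed(seed, {
    n1 <- rnorm(n, 0, sigma)
    n2 <- rnorm(n, 0, sigma)
    out <- sqrt((as.numeric(image$data) + n1)^2 + n2^2)
    volume_image(array(out, dim = dim(image$data)), image$spacing,
                 provenance = c(image$provenance,
                                list(noise_pct = noise_pct, seed = seed)))
  })
}

#' Simulate one spin-echo acquisition of the phantom
#'
#' Fixed pipeline order: (1) map every voxel's tissue to its spin-echo
#' signal (modulated by the phantom's within-tissue texture field);
#' (2) multiply by the INU field if `inu_pct > 0`; (3) add Rician noise if
#' `noise_pct > 0` (reference = brightest tissue's signal); (4) degrade to
#' the requested voxel size: partial-volume (boxcar) averaging along the
#' slice axis over the slice thickness, then trilinear resampling to
#' `(pixel_spacing, pixel_spacing, slice_thickness)`. Deterministic for a
#' fixed seed.
#'
#' @param phantom a [build_default_phantom()] result.
#' @param params an [acquisition_params()] object.
#' @return A [volume_image()] on the acquisition grid.
#' @export
simulate_acquisition <- function(phantom, params) {
  stopifnot(inherits(params, "acquisition_params"))
  if (params$pixel_spacing < phantom$spacing[1] ||
      params$slice_thickness < phantom$spacing[3])
    stop("acquisition voxel size must not be finer than the native grid")
  lab <- phantom$labels
  tis <- phantom$tissues
  idx <- match(lab, tis$id) # NA for background
  tex <- phantom$texture
  mod <- 1 + 0.3 * (tex - 1) # weaker modulation of relaxation times
  T1v <- tis$T1[idx] * mod
  T2v <- tis$T2[idx] * mod
  PDv <- tis$PD[idx] * tex
  sig <- ifelse(is.na(idx), 0,
                spin_echo_signal(ifelse(is.na(T1v), 1, T1v),
                                 ifelse(is.na(T2v), 1, T2v),
                                 ifelse(is.na(PDv), 1, PDv),
                                 params$TR, params$TE))
  vol <- volume_image(array(sig, dim = dim(lab)), phantom$spacing,
                      provenance = list(params = unclass(params)))
  if (params$inu_pct > 0) {
    field <- make_inu_field(dim(lab), params$inu_pct, params$inu_field_id,
                            seed = phantom$seed)
    vol$data <- vol$data * field
  }
  if (params$noise_pct > 0) {
    ref <- max(spin_echo_signal(tis$T1, tis$T2, tis$PD, params$TR, params$TE))
    vol <- add_rician_noise(vol, params$noise_pct, ref, seed = params$seed)
  }
  target <- c(params$pixel_spacing, params$pixel_spacing,
              params$slice_thickness)
  if (!isTRUE(all.equal(target, phantom$spacing, tolerance = 1e-12))) {
    w <- round(params$slice_thickness / phantom$spacing[3])
    if (w > 1) vol$data <- boxcar_z(vol$data, w)
    vol <- resample_volume(vol, target, "linear")
  }
  vol$provenance <- list(params = unclass(params))
  vol
}

# Table-1 style fixed TR/TE used by the voxel-size, noise and INU analyses
fixed_tr_te <- function(modality) {
  if (modality == "T1w") c(TR = 500, TE = 9) else c(TR = 6000, TE = 100)
}

tr_te_grid <- function(modality) {
  if (modality == "T1w")
    expand.grid(TR = seq(350, 650, by = 50), TE = seq(5, 15, by = 2))
  else
    expand.grid(TR = seq(2000, 9000, by = 1000), TE = seq(80, 130, by = 10))
}

#' Build the scenario set for one stability analysis
#'
#' The five designs:
#' * Analysis 1 (TR/TE): the full TR x TE grid at native 1 mm voxels,
#'   no noise, no INU (42 T1w images, 48 T2w images).
#' * Analysis 2 (voxel size): slice thickness 1-7 mm x pixel spacing
#'   1-4 mm at fixed TR/TE (28 images).
#' * Analysis 3 (noise): 10 replicate acquisitions at 9% noise differing
#'   only by noise seed.
#' * Analysis 4 (INU): the three inhomogeneity fields at 40% plus one
#'   reference image without INU (4 images).
#' * Analysis 5 (random): 50 draws with TR, TE, noise and INU uniform over
#'   their analysis 1-4 ranges (continuous), pixel spacing and slice
#'   thickness on the integer-mm grid, and a random field pattern.
#'
#' @param analysis_id integer 1-5.
#' @param modality `"T1w"` or `"T2w"`.
#' @param seed base seed; per-scenario seeds are derived deterministically
#'   from it.
#' @return An object of class `scenario_set` with fields `analysis_id`,
#'   `modality`, `params` (ordered list of [acquisition_params()]).
#' @export
make_scenarios <- function(analysis_id, modality = c("T1w", "T2w"),
                           seed = 1) {
  modality <- match.arg(modality)
  if (!analysis_id %in% 1:5) stop("unknown analysis_id (must be 1-5)")
  ft <- fixed_tr_te(modality)
  mk <- function(i, ...) acquisition_params(
    modality, ..., seed = derive_seed(seed, analysis_id, i))
  params <- switch(analysis_id,
    { g <- tr_te_grid(modality)
      lapply(seq_len(nrow(g)), function(i) mk(i, TR = g$TR[i], TE = g$TE[i])) },
    { g <- expand.grid(ST = 1:7, PS = 1:4)
      lapply(seq_len(nrow(g)), function(i)
        mk(i, TR = ft["TR"], TE = ft["TE"], pixel_spacing = g$PS[i],
           slice_thickness = g$ST[i])) },
    lapply(1:10, function(i)
      mk(i, TR = ft["TR"], TE = ft["TE"], noise_pct = 9)),
    c(list(mk(1, TR = ft["TR"], TE = ft["TE"], inu_pct = 0)),
      lapply(1:3, function(f)
        mk(f + 1, TR = ft["TR"], TE = ft["TE"], inu_pct = 40,
           inu_field_id = f))),
    with_seed(derive_seed(seed, 5L, 0L), {
      rng <- tr_te_grid(modality)
      lapply(1:50, function(i) mk(
        i,
        TR = runif(1, min(rng$TR), max(rng$TR)),
        TE = runif(1, min(rng$TE), max(rng$TE)),
        pixel_spacing = sample(1:4, 1),
        slice_thickness = sample(1:7, 1),
        noise_pct = runif(1, 0, 9),
        inu_pct = runif(1, 0, 40),
        inu_field_id = sample(1:3, 1)))
    })
  )
  structure(list(analysis_id = as.integer(analysis_id), modality = modality,
                 params = params),
            class = "scenario_set")
}

#' @export
print.scenario_set <- function(x, ...) {
  cat("<scenario_set> analysis ", x$analysis_id, " (", x$modality, "): ",
      length(x$params), " acquisitions\n", sep = "")
  invisible(x)
}
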