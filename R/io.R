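#' Write a volume or mask as NIfTI-1
#'
#' Voxel spacing is stored in the NIfTI header (pixdim).
#'
#' @param x a [volume_image()] or [roi_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "roi_mask")) {
    data <- array(as.integer(x$mask), dim = dim(x$mask))
    spacing <- x$spacing
  } else {
    data <- x$data
    spacing <- x$spacing
  }
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path a `.nii` / `.nii.gz` file.
#' @param as_mask logical; return a [roi_mask()] (voxels > 0.5) instead of
#'   a [volume_image()].
#' @param tissue_id,name mask metadata when `as_mask = TRUE`.
#' @return A [volume_image()] or [roi_mask()].
#' @export
read_volume <- function(path, as_mask = FALSE, tissue_id = 1L,
                        name = "roi") {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  data <- array(as.numeric(img), dim = dim(img))
  if (as_mask)
    roi_mask(data > 0.5, tissue_id, name, spacing)
  else
    volume_image(data, spacing)
}

#' Serialize a scenario set to JSON
#'
#' @param scen a [make_scenarios()] result.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_scenarios <- function(scen, path) {
  jsonlite::write_json(
    list(analysis_id = scen$analysis_id, modality = scen$modality,
         params = lapply(scen$params, unclass)),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Write the tissue property table as JSON
#'
#' @param tissues data.frame as from [default_tissues()].
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
write_tissues <- function(tissues, path) {
  jsonlite::write_json(tissues, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a tissue property table from JSON
#'
#' @param path JSON file with fields id, name, T1, T2, PD.
#' @return data.frame suitable for [build_default_phantom()].
#' @export
read_tissues <- function(path) {
  validate_tissues(jsonlite::fromJSON(path))
}
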