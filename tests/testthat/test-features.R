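test_that("the extractor returns exactly 107 class-labelled features", {
  man <- feature_manifest()
  expect_equal(nrow(man), 107)
  expect_equal(as.integer(table(man$class)[c("SS", "FOS", "GLCM", "GLRLM",
                                             "GLSZM", "NGTDM", "GLDM")]),
               c(14L, 18L, 24L, 16L, 16L, 5L, 14L))
  expect_equal(sum(man$group == "textural"), 75)
  ph <- build_default_phantom(48, 2)
  rois <- extract_rois(ph)
  img <- simulate_acquisition(ph, acquisition_params("T1w", 500, 9))
  f <- extract_all(img, rois[["gray_matter"]])
  expect_length(f, 107)
  expect_identical(names(f), man$feature)
  expect_true(all(is.finite(f)))
})

test_that("extraction is deterministic", {
  ph <- build_default_phantom(48, 2)
  rois <- extract_rois(ph)
  img <- simulate_acquisition(ph, acquisition_params("T2w", 6000, 100))
  expect_identical(extract_all(img, rois[["white_matter"]]),
                   extract_all(img, rois[["white_matter"]]))
})

test_that("affine intensity transforms leave shape and texture untouched", {
  ph <- build_default_phantom(48, 2)
  rois <- extract_rois(ph)
  img <- simulate_acquisition(ph, acquisition_params("T1w", 500, 9))
  img2 <- volume_image(4 * img$data + 3, img$spacing)
  f1 <- extract_all(img, rois[["fat"]])
  f2 <- extract_all(img2, rois[["fat"]])
  affine_invariant <- grep("^(shape_|glcm_|glrlm_|glszm_|ngtdm_|gldm_)",
                           names(f1), value = TRUE)
  expect_equal(f1[affine_invariant], f2[affine_invariant],
               tolerance = 1e-9)
  # but first-order location/scale features move
  expect_equal(unname(f2["firstorder_Mean"]),
               4 * unname(f1["firstorder_Mean"]) + 3, tolerance = 1e-9)
})

test_that("manifest labels cover the published feature vocabulary", {
  lab <- feature_manifest()$label
  published <- c(
    "Elongation", "Flatness", "Least axis length", "Major axis length",
    "Maximum 2D diameter (column)", "Maximum 2D diameter (row)",
    "Maximum 2D diameter (slice)", "Maximum 3D diameter", "Mesh volume",
    "Minor axis length", "Sphericity", "Surface area",
    "Surface to volume ratio", "Voxel volume",
    "10th percentile", "90th percentile", "Energy", "Entropy", "Kurtosis",
    "Maximum", "Mean", "Median", "Minimum", "Skewness",
    "Root mean squared", "Total energy", "Uniformity",
    "Inter-quartile range", "Mean absolute deviation", "Range",
    "Robust mean absolute deviation",
    "Autocorrelation", "Cluster shade", "Inverse difference",
    "Inverse difference moment", "Inverse difference normalized",
    "Joint average", "Joint energy", "Joint entropy",
    "Maximum probability", "Sum average", "Sum entropy", "Sum squares",
    "Gray level non-uniformity (GLRLM)",
    "Gray level non-uniformity normalized",
    "High gray level run emphasis", "Run length non-uniformity",
    "Run length non-uniformity normalized", "Run percentage",
    "Short run emphasis", "Short run high gray level emphasis",
    "Long run low gray level emphasis", "Low gray level run emphasis",
    "Short run low gray level emphasis", "High gray level zone emphasis",
    "Large area emphasis", "Zone percentage", "Zone variance",
    "Large area high gray level emphasis", "Coarseness", "Strength",
    "Dependence non-uniformity", "Dependence non-uniformity normalized",
    "Dependence variance", "Gray level non-uniformity (GLDM)",
    "High gray level emphasis (GLDM)", "Large dependence emphasis",
    "Large dependence low gray level emphasis",
    "Large dependence high gray level emphasis",
    "Low gray level emphasis (GLDM)", "Small dependence emphasis",
    "Small dependence high gray level emphasis")
  norm <- function(x) gsub("[^a-z0-9]", "", tolower(x))
  missing <- setdiff(norm(published), norm(lab))
  expect_length(missing, 0)
})
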