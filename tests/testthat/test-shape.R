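test_that("single voxel has unit voxel volume at 1 mm spacing", {
  m <- array(FALSE, c(3, 3, 3)); m[2, 2, 2] <- TRUE
  f <- shape_features(roi_mask(m, 1, "pt"), c(1, 1, 1))
  expect_equal(unname(f["VoxelVolume"]), 1)
  expect_equal(unname(f["Maximum3DDiameter"]), 0)
})

test_that("digital ball matches analytic sphere formulas", {
  f <- shape_features(make_ball_mask(40, 15), c(1, 1, 1))
  expect_gte(unname(f["Sphericity"]), 0.95)
  expect_lte(unname(f["Sphericity"]), 1.0)
  expect_lt(abs(unname(f["SurfaceArea"]) / (4 * pi * 15^2) - 1), 0.05)
  expect_lt(abs(unname(f["MeshVolume"]) / (4 / 3 * pi * 15^3) - 1), 0.05)
  expect_lt(abs(unname(f["Maximum3DDiameter"]) - 30), 1.5)
  # a ball has no preferred axis
  expect_gt(unname(f["Elongation"]), 0.97)
  expect_gt(unname(f["Flatness"]), 0.97)
})

test_that("cube diameters equal corner-to-corner distances", {
  cube <- array(FALSE, c(14, 14, 14)); cube[3:12, 3:12, 3:12] <- TRUE
  f <- shape_features(roi_mask(cube, 1, "cube"), c(1, 1, 1))
  expect_equal(unname(f["Maximum3DDiameter"]), sqrt(3) * 9, tolerance = 1e-9)
  expect_equal(unname(f["Maximum2DDiameterSlice"]), sqrt(2) * 9,
               tolerance = 1e-9)
  expect_equal(unname(f["VoxelVolume"]), 1000)
})

test_that("candidate-reduced diameters equal the all-pairs brute force", {
  set.seed(31)
  for (trial in 1:10) {
    dims <- c(sample(4:8, 1), sample(4:8, 1), sample(4:8, 1))
    mask <- array(runif(prod(dims)) < 0.4, dim = dims)
    mask[1] <- TRUE
    sp <- runif(3, 0.5, 2.5)
    f <- shape_features(roi_mask(mask, 1, "rnd"), sp)
    idx <- which(mask, arr.ind = TRUE)
    co <- sweep(idx - 0.5, 2, sp, `*`)
    n <- nrow(idx)
    d3 <- 0; ds <- 0; dc <- 0; dr <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      dd <- co[j, ] - co[i, ]
      d3 <- max(d3, sum(dd^2))
      if (idx[i, 3] == idx[j, 3]) ds <- max(ds, dd[1]^2 + dd[2]^2)
      if (idx[i, 1] == idx[j, 1]) dc <- max(dc, dd[2]^2 + dd[3]^2)
      if (idx[i, 2] == idx[j, 2]) dr <- max(dr, dd[1]^2 + dd[3]^2)
    }
    expect_equal(unname(f["Maximum3DDiameter"]), sqrt(d3), tolerance = 1e-9)
    expect_equal(unname(f["Maximum2DDiameterSlice"]), sqrt(ds),
                 tolerance = 1e-9)
    expect_equal(unname(f["Maximum2DDiameterColumn"]), sqrt(dc),
                 tolerance = 1e-9)
    expect_equal(unname(f["Maximum2DDiameterRow"]), sqrt(dr),
                 tolerance = 1e-9)
  }
})

test_that("axis lengths track an elongated box", {
  box <- array(FALSE, c(30, 12, 8)); box[3:28, 3:10, 3:6] <- TRUE
  f <- shape_features(roi_mask(box, 1, "box"), c(1, 1, 1))
  expect_gt(unname(f["MajorAxisLength"]), unname(f["MinorAxisLength"]))
  expect_gt(unname(f["MinorAxisLength"]), unname(f["LeastAxisLength"]))
  expect_lt(unname(f["Elongation"]), 1)
  expect_lt(unname(f["Flatness"]), unname(f["Elongation"]))
  # uniform box: 4*sqrt(variance of a discrete uniform over 26 positions)
  expect_equal(unname(f["MajorAxisLength"]), 4 * sqrt((26^2 - 1) / 12),
               tolerance = 2e-3)
})

test_that("shape features ignore image intensities", {
  ph <- build_default_phantom(48, 2)
  rois <- extract_rois(ph)
  i1 <- simulate_acquisition(ph, acquisition_params("T1w", 500, 9))
  i2 <- simulate_acquisition(ph, acquisition_params("T1w", 650, 15))
  f1 <- extract_all(i1, rois[[2]])
  f2 <- extract_all(i2, rois[[2]])
  sf <- grep("^shape_", names(f1), value = TRUE)
  expect_identical(f1[sf], f2[sf])
})
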