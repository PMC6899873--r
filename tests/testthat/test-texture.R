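# Hand-enumerated degenerate cases and small brute-force cross-checks for
# the five texture-matrix families; the 100-trial oracle sweep lives in
# test-acceptance.R.

uniform_roi <- function(n = 4) {
  lv <- array(1L, dim = c(n, n, n))
  levels_as_roi(lv, 4)
}

test_that("uniform ROI collapses the GLCM to a single cell", {
  f <- glcm_features(uniform_roi())
  expect_equal(unname(f["JointEnergy"]), 1, tolerance = 1e-12)
  expect_equal(unname(f["JointEntropy"]), 0, tolerance = 1e-9)
  expect_equal(unname(f["MaximumProbability"]), 1)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["Correlation"]), 1) # degenerate convention
})

test_that("2x2x1 slab matches hand-enumerated co-occurrences", {
  lv <- array(c(1L, 1L, 2L, 2L), dim = c(2, 2, 1))
  d <- levels_as_roi(lv, 2)
  got <- glcm_features(d)
  want <- oracle_glcm_features(lv, 2)
  expect_equal(got[names(want)], want, tolerance = 1e-12)
  # direction (1,0,0): pairs (1,1) and (2,2); direction (0,1,0): two (1,2)
  # pairs; so Contrast is 0 for the first and 1 for the second
  expect_equal(unname(oracle_glcm_features(lv, 2)["JointAverage"]),
               unname(got["JointAverage"]))
})

test_that("uniform 4x4x4 ROI gives closed-form run and zone structure", {
  d <- uniform_roi(4)
  rl <- glrlm_features(d)
  # along each axis direction: 16 runs of length 4 -> RunPercentage 16/64;
  # oracle handles the diagonal directions
  want <- oracle_glrlm_features(d$levels, 4)
  expect_equal(rl[names(want)], want, tolerance = 1e-12)
  sz <- glszm_features(d)
  # one 26-connected zone of size 64
  expect_equal(unname(sz["ZonePercentage"]), 1 / 64)
  expect_equal(unname(sz["LargeAreaEmphasis"]), 64^2)
  expect_equal(unname(sz["GrayLevelNonUniformity"]), 1)
})

test_that("uniform ROI caps NGTDM coarseness and zeroes contrast", {
  f <- ngtdm_features(uniform_roi())
  expect_equal(unname(f["Coarseness"]), 1e6)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["Busyness"]), 0)
})

test_that("uniform cube GLDM dependences count equal neighbours plus centre", {
  f <- gldm_features(uniform_roi(4))
  w <- oracle_gldm_features(uniform_roi(4)$levels, 4)
  expect_equal(f[names(w)], w, tolerance = 1e-12)
  # 4^3 cube: 8 corners dep 8, 24 edge voxels dep 12, 24 face voxels dep 18,
  # 8 interior voxels dep 27
  expect_equal(unname(f["LargeDependenceEmphasis"]),
               (8 * 64 + 24 * 144 + 24 * 324 + 8 * 729) / 64)
})

test_that("each family matches its brute-force oracle on random small ROIs", {
  set.seed(99)
  for (trial in 1:12) {
    dims <- c(sample(3:5, 1), sample(3:5, 1), sample(3:5, 1))
    lv <- random_levels(dims, ng = 4)
    d <- levels_as_roi(lv, 4)
    expect_equal(glcm_features(d), oracle_glcm_features(lv, 4),
                 tolerance = 1e-9)
    expect_equal(glrlm_features(d), oracle_glrlm_features(lv, 4),
                 tolerance = 1e-9)
    expect_equal(glszm_features(d), oracle_glszm_features(lv, 4),
                 tolerance = 1e-9)
    expect_equal(ngtdm_features(d), oracle_ngtdm_features(lv, 4),
                 tolerance = 1e-9)
    expect_equal(gldm_features(d), oracle_gldm_features(lv, 4),
                 tolerance = 1e-9)
  }
})

test_that("probability-form matrices are properly normalized", {
  set.seed(17)
  lv <- random_levels(c(5, 5, 5), ng = 6)
  counts <- radstab:::cpp_glcm_counts(lv, 6)
  for (dd in 1:13) {
    P <- counts[, , dd]
    if (sum(P) == 0) next
    expect_lt(abs(sum(P / sum(P)) - 1), 1e-9)
    expect_identical(P, t(P)) # symmetrized
  }
})
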