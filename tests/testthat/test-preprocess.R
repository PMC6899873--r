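test_that("Z-score normalization standardizes, is affine-invariant and idempotent", {
  set.seed(1)
  a <- array(abs(rnorm(16^3, 10, 3)) + 0.1, dim = c(16, 16, 16))
  v <- volume_image(a)
  z <- zscore_normalize(v)
  expect_lt(abs(mean(z$data)), 1e-9)
  expect_lt(abs(sd(z$data) - 1), 1e-9)
  # affine invariance: a*x + b gives the same standardized image
  v2 <- volume_image(2.5 * a + 7)
  z2 <- zscore_normalize(v2)
  expect_equal(z$data, z2$data, tolerance = 1e-9)
  # idempotence (the image has no zero background, so the region is stable)
  z3 <- zscore_normalize(z)
  expect_equal(z$data, z3$data, tolerance = 1e-9)
  expect_error(zscore_normalize(volume_image(array(5, c(4, 4, 4)))),
               "variance")
})

test_that("Gaussian denoising preserves constants and contracts variance", {
  const <- volume_image(array(2.2, dim = c(10, 10, 10)))
  expect_equal(gaussian_denoise(const)$data, const$data, tolerance = 1e-12)
  set.seed(2)
  noisy <- volume_image(array(rnorm(20^3), dim = c(20, 20, 20)))
  sm <- gaussian_denoise(noisy)
  expect_lt(var(as.numeric(sm$data)), var(as.numeric(noisy$data)))
  # interior mean preserved
  expect_lt(abs(mean(sm$data[5:16, 5:16, 5:16]) -
                  mean(noisy$data[5:16, 5:16, 5:16])), 0.01)
  expect_error(gaussian_denoise(noisy, kernel = 4), "odd")
})

test_that("impulse response equals the hand-computed truncated kernel weight", {
  imp <- array(0, dim = c(9, 9, 9))
  imp[5, 5, 5] <- 1
  sm <- gaussian_denoise(volume_image(imp), kernel = 3, sigma = 0.5)
  # 1D truncated kernel: (w, 1, w)/ (1 + 2w) with w = exp(-1/(2*0.25))
  w <- exp(-2)
  centre <- (1 / (1 + 2 * w))^3
  expect_equal(sm$data[5, 5, 5], centre, tolerance = 1e-12)
  side <- (1 / (1 + 2 * w))^2 * (w / (1 + 2 * w))
  expect_equal(sm$data[4, 5, 5], side, tolerance = 1e-12)
})

test_that("bias correction recovers a known multiplicative field", {
  # uniform-tissue ellipsoid times a 40% ramp field
  n <- 40
  m <- make_ball_mask(n, 15)$mask
  field <- make_inu_field(c(n, n, n), 40, 1, seed = 4)
  img <- array(0, dim = c(n, n, n))
  img[m] <- 10
  biased <- volume_image(img * field)
  # smoothness scale chosen commensurate with the 40 mm field of view
  res <- correct_bias_field(biased, preprocess_config(bias_fwhm = 25))
  cov_before <- sd(biased$data[m]) / mean(biased$data[m])
  cov_after <- sd(res$corrected$data[m]) / mean(res$corrected$data[m])
  expect_lt(cov_after, 0.5 * cov_before)
  expect_gt(cor(as.numeric(res$field[m]), as.numeric(field[m])), 0.9)
  expect_true(all(res$field > 0))
  expect_lt(abs(mean(res$field[biased$data > 0]) - 1), 0.02)
})

test_that("bias correction leaves an unbiased image nearly untouched", {
  n <- 40
  m <- make_ball_mask(n, 15)$mask
  img <- array(0, dim = c(n, n, n))
  set.seed(9)
  img[m] <- 10 * (1 + 0.02 * rnorm(sum(m)))
  res <- correct_bias_field(volume_image(img))
  expect_lt(max(abs(res$field[m] - 1)), 0.05)
})

test_that("pipelines apply steps in order and carry masks across grids", {
  ph <- build_default_phantom(48, 5)
  rois <- extract_rois(ph)
  p <- acquisition_params("T1w", 500, 9, pixel_spacing = 2,
                          slice_thickness = 3)
  img <- simulate_acquisition(ph, p)
  masks <- radstab:::transfer_masks(rois, img)
  mid <- apply_pipeline(img, masks, c("bias", "denoise", "resample"))
  out <- apply_pipeline(mid$image, mid$masks, "zscore")
  expect_equal(out$image$spacing, c(1, 1, 1))
  fg <- mid$image$data != 0 # the region the z-score statistics came from
  expect_lt(abs(mean(out$image$data[fg])), 1e-9)
  expect_lt(abs(sd(out$image$data[fg]) - 1), 1e-9)
  expect_true(all(vapply(out$masks, function(m)
    all(dim(m$mask) == dim(out$image$data)), logical(1))))
  # identity resample step is a no-op on an already isotropic grid
  img1 <- simulate_acquisition(ph, acquisition_params("T1w", 500, 9))
  out1 <- apply_pipeline(img1, rois, "resample")
  expect_identical(out1$image$data, img1$data)
  expect_error(apply_pipeline(img1, rois, character(0)), "non-empty")
})

test_that("mask transfer keeps physical volume for convex ROIs", {
  m <- make_ball_mask(48, 15)
  img2 <- volume_image(array(1, dim = c(24, 24, 24)), c(2, 2, 2))
  tr <- radstab:::transfer_masks(list(ball = m), img2)[[1]]
  expect_lt(abs(sum(tr$mask) * 8 / (4 / 3 * pi * 15^3) - 1), 0.10)
})
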