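test_that("spin-echo signal matches the closed form and its limits", {
  # saturation: very long TR, no echo decay
  expect_equal(spin_echo_signal(500, 80, 1, 1e9, 0), 1, tolerance = 1e-12)
  # direct evaluations of the closed form
  expect_equal(spin_echo_signal(500, 80, 1, 500, 0), 1 - exp(-1),
               tolerance = 1e-12)
  expect_equal(spin_echo_signal(500, 80, 0.8, 500, 80),
               0.8 * (1 - exp(-1)) * exp(-1), tolerance = 1e-12)
  expect_error(spin_echo_signal(-500, 80, 1, 500, 10), "positive")
  expect_error(spin_echo_signal(500, 80, 1, -500, 10), "positive")
})

test_that("signal is strictly monotone in TR and TE", {
  trs <- seq(200, 5000, by = 100)
  s_tr <- spin_echo_signal(900, 80, 1, trs, 15)
  expect_true(all(diff(s_tr) > 0))
  tes <- seq(0, 200, by = 5)
  s_te <- spin_echo_signal(900, 80, 1, 2000, tes)
  expect_true(all(diff(s_te) < 0))
  expect_true(all(s_tr >= 0 & s_tr <= 1))
})

test_that("INU fields respect range, mean and distinctness contracts", {
  f0 <- make_inu_field(c(48, 48, 48), 0, 1)
  expect_true(all(f0 == 1))
  for (id in 1:3) {
    f <- make_inu_field(c(48, 48, 48), 40, id, seed = 2)
    expect_gte(min(f), 0.8 - 1e-9)
    expect_lte(max(f), 1.2 + 1e-9)
    expect_lt(abs(mean(f) - 1), 0.01)
  }
  # the ramp pattern attains both extremes
  f1 <- make_inu_field(c(48, 48, 48), 40, 1, seed = 2)
  expect_lt(abs(min(f1) - 0.8), 0.8 * 0.01)
  expect_lt(abs(max(f1) - 1.2), 1.2 * 0.01)
  f2 <- make_inu_field(c(48, 48, 48), 40, 2, seed = 2)
  expect_lt(cor(as.numeric(f1), as.numeric(f2)), 0.99)
  expect_error(make_inu_field(c(48, 48, 48), 40, 4), "field_id")
})

test_that("Rician noise has Rayleigh background and Gaussian high-signal limits", {
  n <- 48
  img <- volume_image(array(0, dim = c(n, n, n)))
  noisy <- add_rician_noise(img, 9, reference = 1, seed = 11)
  sigma <- 0.09
  # background magnitude is Rayleigh: mean sigma * sqrt(pi/2)
  expect_lt(abs(mean(noisy$data) / (sigma * sqrt(pi / 2)) - 1), 0.02)
  # high-signal region: sd approaches the Gaussian sigma
  bright <- volume_image(array(100, dim = c(n, n, n)))
  bn <- add_rician_noise(bright, 9, reference = 1, seed = 12)
  expect_lt(abs(sd(bn$data) / sigma - 1), 0.05)
  # zero-noise identity and determinism
  expect_identical(add_rician_noise(img, 0, 1, 1), img)
  n2 <- add_rician_noise(img, 9, reference = 1, seed = 11)
  expect_identical(noisy$data, n2$data)
  expect_error(add_rician_noise(img, -1, 1, 1), "non-negative")
})

test_that("acquisition with all degradations disabled is the pure signal map", {
  ph <- build_default_phantom(48, 5)
  p <- acquisition_params("T1w", TR = 500, TE = 9)
  img <- simulate_acquisition(ph, p)
  # recompute expected signal directly from the closed form
  idx <- match(ph$labels, ph$tissues$id)
  mod <- 1 + 0.3 * (ph$texture - 1)
  expected <- ifelse(is.na(idx), 0,
                     ph$tissues$PD[idx] * ph$texture *
                       (1 - exp(-500 / (ph$tissues$T1[idx] * mod))) *
                       exp(-9 / (ph$tissues$T2[idx] * mod)))
  expect_equal(as.numeric(img$data), as.numeric(expected), tolerance = 1e-12)
  # determinism with noise enabled
  pn <- acquisition_params("T1w", TR = 500, TE = 9, noise_pct = 9, seed = 3)
  a <- simulate_acquisition(ph, pn)
  b <- simulate_acquisition(ph, pn)
  expect_identical(a$data, b$data)
})

test_that("TR/TE changes move the white/gray matter contrast", {
  ph <- build_default_phantom(48, 5)
  r1 <- simulate_acquisition(ph, acquisition_params("T1w", 500, 9))
  r2 <- simulate_acquisition(ph, acquisition_params("T1w", 650, 15))
  wm <- ph$labels == 3; gm <- ph$labels == 2
  ratio1 <- mean(r1$data[wm]) / mean(r1$data[gm])
  ratio2 <- mean(r2$data[wm]) / mean(r2$data[gm])
  # closed-form prediction of the ratio change (texture factors out)
  t <- ph$tissues
  f <- function(TR, TE, i) t$PD[i] * (1 - exp(-TR / t$T1[i])) *
    exp(-TE / t$T2[i])
  pred1 <- f(500, 9, 3) / f(500, 9, 2)
  pred2 <- f(650, 15, 3) / f(650, 15, 2)
  expect_false(isTRUE(all.equal(ratio1, ratio2)))
  expect_equal(sign(ratio2 - ratio1), sign(pred2 - pred1))
  expect_lt(abs(ratio1 / pred1 - 1), 0.02)
})

test_that("scenario designs reproduce the study image counts", {
  expect_length(make_scenarios(1, "T1w")$params, 42)
  expect_length(make_scenarios(1, "T2w")$params, 48)
  expect_length(make_scenarios(2, "T1w")$params, 28)
  expect_length(make_scenarios(2, "T2w")$params, 28)
  expect_length(make_scenarios(3, "T1w")$params, 10)
  expect_length(make_scenarios(4, "T1w")$params, 4)
  expect_length(make_scenarios(5, "T2w")$params, 50)
  expect_error(make_scenarios(6, "T1w"), "analysis_id")
})

test_that("random-parameter scenarios stay within ranges and reproduce", {
  s1 <- make_scenarios(5, "T2w", seed = 3)
  s2 <- make_scenarios(5, "T2w", seed = 3)
  expect_identical(s1, s2)
  for (p in s1$params) {
    expect_true(p$TR >= 2000 && p$TR <= 9000)
    expect_true(p$TE >= 80 && p$TE <= 130)
    expect_true(p$pixel_spacing %in% 1:4)
    expect_true(p$slice_thickness %in% 1:7)
    expect_true(p$noise_pct >= 0 && p$noise_pct <= 9)
    expect_true(p$inu_pct >= 0 && p$inu_pct <= 40)
    expect_true(p$inu_field_id %in% 1:3)
  }
  # replicates differ (noise analysis seeds vary within the set)
  s3 <- make_scenarios(3, "T1w", seed = 1)
  expect_gt(length(unique(vapply(s3$params, `[[`, 1L, "seed"))), 1)
})
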