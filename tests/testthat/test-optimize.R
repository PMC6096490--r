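test_that("sharpening scan uses the documented defaults and calibrated endpoints", {
  fx <- default_fixture()
  tr <- scan_sharpening(fx$map, 3)
  info <- trace_info(tr)
  expect_equal(info$d_cut, 3)          # d_cut defaults to the map resolution
  expect_equal(info$b_blur, 200)
  expect_equal(info$k, 10)
  expect_equal(info$fraction, 0.2)
  expect_equal(tr$b_candidate, seq(-100, 300, by = 20))
  # endpoint adjusted surface areas equal after calibration
  expect_equal(tr$sa_adjusted[1], tr$sa_adjusted[nrow(tr)], tolerance = 1e-9)
  # fitted B of each candidate map tracks the target
  expect_lt(max(abs(tr$b_fitted - tr$b_candidate)), 35)
  # objective has a strictly interior maximum on this noisy fixture
  i <- which.max(tr$sa_adjusted)
  expect_gt(i, 1)
  expect_lt(i, nrow(tr))
})

test_that("surface-area auto-sharpening picks the objective maximum and is scale-invariant", {
  fx <- default_fixture()
  res <- auto_sharpen_sa(fx$map, 3)
  info <- trace_info(res$trace)
  expect_true(info$applicable)
  best <- max(res$trace$b_candidate[res$trace$sa_adjusted >=
                                      max(res$trace$sa_adjusted) - 1e-9])
  expect_equal(info$chosen_b, best)
  # the returned map has roughly the chosen overall B
  expect_equal(fit_isotropic_b(map_to_coeffs(res$map, d_min = 3)),
               info$chosen_b, tolerance = 35)
  # doubling all map values leaves the choice unchanged
  fx2 <- fx$map; fx2$values <- fx$map$values * 2
  res2 <- auto_sharpen_sa(fx2, 3)
  expect_equal(trace_info(res2$trace)$chosen_b, info$chosen_b)
})

test_that("a noise-free blob declines surface-area sharpening gracefully", {
  # a single zero-B atom: its resolution-limited peak is one contiguous
  # region at every candidate B, so the region counts cannot calibrate
  # C_scale and the method must fall through
  mdl <- atomic_model("C", 20, 20, 20)
  m <- model_to_map(mdl, c(40, 40, 40), c(40, 40, 40), b_values = 0, d_min = 3)
  expect_message(res <- auto_sharpen_sa(m, 3), "declined")
  expect_false(trace_info(res$trace)$applicable)
  expect_identical(res$map$values, m$values)   # input returned unchanged
})

test_that("kurtosis sharpening is consistent with direct kurtosis evaluation", {
  fx <- default_fixture()
  res <- auto_sharpen_kurtosis(fx$map, 3, aniso_correct = FALSE)
  tr <- res$trace
  info <- trace_info(tr)
  # recompute kurtosis of independently sharpened maps at three candidates
  coeffs <- map_to_coeffs(fx$map, d_min = 3)
  for (i in c(3, 11, 19)) {
    p <- sharpen_params(info$b0 - tr$b_candidate[i], d_cut = 3)
    k <- map_kurtosis(coeffs_to_map(apply_sharpening(coeffs, p)))
    expect_equal(tr$kurtosis[i], k, tolerance = 1e-9)
  }
  expect_equal(info$chosen_b,
               max(tr$b_candidate[tr$kurtosis >= max(tr$kurtosis) - 1e-12]))
  # the optimum is an interior feature of the scan on this fixture
  i <- which.max(tr$kurtosis)
  expect_gt(i, 1)
  expect_lt(i, nrow(tr))
  # a constant map cannot be scanned
  cst <- volume_grid(array(1, dim = c(8, 8, 8)), cell = c(8, 8, 8))
  expect_error(suppressWarnings(auto_sharpen_kurtosis(cst, 3)))
})

test_that("half-map FSC converts to CC* by the closed form", {
  expect_equal(cc_star_from_halfmap_fsc(1), 1)
  expect_equal(cc_star_from_halfmap_fsc(0), 0)
  expect_equal(cc_star_from_halfmap_fsc(0.5), sqrt(2 * 0.5 / 1.5))
  expect_equal(cc_star_from_halfmap_fsc(0.5), 0.8164966, tolerance = 1e-6)
  # negative correlations carry no signal
  expect_equal(cc_star_from_halfmap_fsc(-0.4), 0)
  expect_error(cc_star_from_halfmap_fsc(-1), "> -1")
  expect_true(all(diff(cc_star_from_halfmap_fsc(seq(0, 1, 0.05))) >= 0))
})

test_that("half-map sharpening normalizes to the zero-B model falloff", {
  fx <- default_fixture(seed = 11, true_b = 0, noise_sigma = 0.3)
  fc_full <- map_to_coeffs(fx$map, d_min = 3)
  # identical halves: CC* = 1 in every shell, output shell means match the
  # zero-B model map
  out <- halfmap_sharpen(fc_full, fx$map, fx$map, fx$model, 3)
  sh <- attr(out, "shells")
  expect_equal(sh$cc_star, rep(1, nrow(sh)))
  mm <- model_to_map(fx$model, fx$map$cell, dim(fx$map$values), b_values = 0,
                     d_min = 3)
  tab_out <- resolution_shells(map_to_coeffs(coeffs_to_map(out), d_min = 3))
  tab_mod <- resolution_shells(map_to_coeffs(mm, d_min = 3))
  expect_equal(tab_out$mean_amp, tab_mod$mean_amp, tolerance = 1e-6)
  # phases untouched, per-shell scales non-negative
  live <- Mod(out$terms) > 0
  expect_equal(Arg(out$terms[live]), Arg(fc_full$terms[live]), tolerance = 1e-9)
  expect_true(all(sh$cc_star * sh$ratio_r >= 0))
  # strong high-resolution noise pushes the high-res scale below R
  halves <- make_half_maps(fx$truth, noise_sigma = 3 * sd(fx$truth$values), seed = 5)
  out2 <- halfmap_sharpen(fc_full, halves$half1, halves$half2, fx$model, 3)
  sh2 <- attr(out2, "shells")
  hi <- which.min(sh2$d_mid)
  expect_lt(sh2$cc_star[hi], 1)
  expect_lt(sh2$cc_star[hi] * sh2$ratio_r[hi], sh2$ratio_r[hi])
})

test_that("model-based sharpening corrects the FSC for assumed model error", {
  # rmse = 0: no error correction, CC* = CC (clipped)
  ep0 <- model_error_params(0)
  expect_equal(ep0$b_eff, 0)
  # default rmse is resolution/4; B_eff by direct evaluation of the relation
  ep <- model_error_params(3.5 / 4)
  expect_equal(ep$rmse, 0.875)
  expect_equal(ep$b_eff, 8 * pi^2 * 0.875^2 / 3, tolerance = 1e-12)
  # a map generated from the model with a known falloff is restored to the
  # zero-B model falloff
  fx <- default_fixture(seed = 11, true_b = 0, noise_sigma = 0.3)
  blurred <- model_to_map(fx$model, fx$map$cell, dim(fx$map$values),
                          b_values = 100, d_min = 3)
  out <- model_sharpen(map_to_coeffs(blurred, d_min = 3), fx$model, 3, err = ep0)
  ref <- fit_isotropic_b(map_to_coeffs(
    model_to_map(fx$model, fx$map$cell, dim(fx$map$values), b_values = 0, d_min = 3),
    d_min = 3))
  expect_equal(fit_isotropic_b(out), ref, tolerance = 2)
  # phases untouched
  fcb <- map_to_coeffs(blurred, d_min = 3)
  live <- Mod(out$terms) > 0
  expect_equal(Arg(out$terms[live]), Arg(fcb$terms[live]), tolerance = 1e-9)
})

test_that("zero-B map-model correlation behaves as a map-quality metric", {
  fx <- default_fixture(seed = 11, true_b = 0, noise_sigma = 0.3)
  mm <- model_to_map(fx$model, fx$map$cell, dim(fx$map$values), b_values = 0,
                     d_min = 3)
  expect_equal(map_model_cc_zero_b(mm, fx$model, 3), 1, tolerance = 1e-9)
  neg <- mm; neg$values <- -mm$values
  expect_equal(map_model_cc_zero_b(neg, fx$model, 3), -1, tolerance = 1e-9)
  # correlation strictly between 0 and 1 for blurred maps, increasing as the
  # blur is removed
  ccs <- vapply(c(200, 100, 50, 0), function(b) {
    bl <- model_to_map(fx$model, fx$map$cell, dim(fx$map$values), b_values = b,
                       d_min = 3)
    map_model_cc_zero_b(bl, fx$model, 3)
  }, numeric(1))
  expect_true(all(ccs > 0 & ccs <= 1))
  expect_true(all(diff(ccs) > 0))
  far <- atomic_model("C", 900, 900, 900)
  expect_error(map_model_cc_zero_b(fx$map, far, 3), "mask_radius")
})

test_that("model-targeted sharpening recovers the zero-B optimum on a clean fixture", {
  # truth: zero-B map, blurred to B = 100; the cc optimum should sit within
  # one scan step of the target restoring the zero-B falloff
  fx <- default_fixture(seed = 11, true_b = 0, noise_sigma = 0.3)
  blurred <- model_to_map(fx$model, fx$map$cell, dim(fx$map$values),
                          b_values = 100, d_min = 3)
  res <- suppressWarnings(auto_sharpen_model(blurred, fx$model, 3,
                                             aniso_correct = FALSE))
  tr <- res$trace
  info <- trace_info(tr)
  ref <- fit_isotropic_b(map_to_coeffs(
    model_to_map(fx$model, fx$map$cell, dim(fx$map$values), b_values = 0, d_min = 3),
    d_min = 3))
  expect_lte(abs(info$chosen_b - ref), 20)
  # cc column is unimodal on this noise-free fixture
  i <- which.max(tr$cc)
  expect_true(all(diff(tr$cc[seq_len(i)]) > 0))
  expect_true(all(diff(tr$cc[i:nrow(tr)]) < 0))
  # agrees with direct per-candidate evaluation
  p <- sharpen_params(info$b0 - tr$b_candidate[5], d_cut = 3)
  m5 <- coeffs_to_map(apply_sharpening(map_to_coeffs(blurred, d_min = 3), p))
  expect_equal(tr$cc[5], map_model_cc_zero_b(m5, fx$model, 3), tolerance = 1e-6)
})
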