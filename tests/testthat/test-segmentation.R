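test_that("molecule mask tracks a Gaussian-atom octant", {
  set.seed(5)
  g <- c(60, 60, 60)
  pos <- matrix(runif(250 * 3, min = 2, max = 28), ncol = 3)
  mdl <- atomic_model("C", pos[, 1], pos[, 2], pos[, 3])
  m <- model_to_map(mdl, c(60, 60, 60), g, b_values = 20, d_min = 3)
  m$values <- m$values + array(rnorm(prod(g), sd = 0.05 * sd(m$values)), g)
  mk <- find_molecule_mask(m, 3)
  expect_s3_class(mk, "molecule_mask")
  expect_equal(mk$smoothing_radius, 4.5)          # 1.5x the resolution
  oct <- array(FALSE, g); oct[1:30, 1:30, 1:30] <- TRUE
  jac <- sum(mk$mask & oct) / sum(mk$mask | oct)
  expect_gte(jac, 0.8)
  # mask is invariant under adding a constant to the map
  m2 <- m; m2$values <- m$values + 7.3
  mk2 <- find_molecule_mask(m2, 3)
  expect_identical(mk2$mask, mk$mask)
})

test_that("a map with uniform variance keeps the guessed fraction", {
  set.seed(12)
  nz <- volume_grid(array(rnorm(40^3), dim = c(40, 40, 40)), cell = c(40, 40, 40))
  mk <- suppressWarnings(find_molecule_mask(nz, 3, initial_fraction_guesses = 0.3))
  expect_equal(mk$volume_fraction, 0.3, tolerance = 0.02)
  expect_error(find_molecule_mask(volume_grid(array(1, dim = c(4, 4, 4)),
                                              cell = c(4, 4, 4)), 3),
               "constant")
})

test_that("volume threshold selects the requested top fraction", {
  # 1000 masked points with values 1..1000: fraction 0.2 keeps the top 200
  vals <- array(0, dim = c(10, 10, 10))
  vals[] <- sample(1:1000)
  m <- volume_grid(vals, cell = c(10, 10, 10))
  mask <- array(TRUE, dim = c(10, 10, 10))
  thr <- threshold_for_volume(m, mask, 0.2)
  expect_identical(sum(vals >= thr), 200L)
  expect_identical(thr, 801)
  # fraction -> 1 gives a threshold at or below the minimum masked value
  expect_lte(threshold_for_volume(m, mask, 0.999), min(vals[mask]) + 1)
  # monotonicity: larger fraction, lower-or-equal threshold
  thrs <- vapply(c(0.1, 0.2, 0.4, 0.8), function(f)
    threshold_for_volume(m, mask, f), numeric(1))
  expect_true(all(diff(thrs) <= 0))
  expect_error(threshold_for_volume(m, mask, 1.2), "fraction")
  cst <- m; cst$values[] <- 1
  expect_error(threshold_for_volume(cst, mask, 0.2), "constant")
})

test_that("contour statistics follow the face-adjacency conventions", {
  g <- array(0, dim = c(5, 5, 5))
  g[3, 3, 3] <- 1
  m <- volume_grid(g, cell = c(5, 5, 5))
  st <- contour_stats(m, 0.5)
  expect_identical(st$n_regions, 1L)
  expect_identical(st$surface_area, 6L)
  # voxels touching only at an edge are two regions under 6-connectivity
  g2 <- array(0, dim = c(5, 5, 5))
  g2[2, 2, 2] <- 1; g2[3, 3, 2] <- 1
  st2 <- contour_stats(volume_grid(g2, cell = c(5, 5, 5)), 0.5)
  expect_identical(st2$n_regions, 2L)
  # and corner-touching voxels likewise
  g3 <- array(0, dim = c(5, 5, 5))
  g3[2, 2, 2] <- 1; g3[3, 3, 3] <- 1
  expect_identical(contour_stats(volume_grid(g3, cell = c(5, 5, 5)), 0.5)$n_regions, 2L)
  # empty contour gives zeros
  st0 <- contour_stats(m, 2)
  expect_identical(st0$n_regions, 0L)
  expect_identical(st0$surface_area, 0L)
  # threshold is inclusive (>=)
  expect_identical(contour_stats(m, 1)$n_regions, 1L)
})

test_that("random binary grids match the flood-fill/neighbour-scan oracle", {
  set.seed(13)
  for (rep in 1:100) {
    dm <- c(6, 6, 6)
    inside <- array(runif(prod(dm)) < runif(1, 0.1, 0.6), dim = dm)
    m <- volume_grid(array(as.numeric(inside), dm), cell = dm)
    st <- contour_stats(m, 0.5)
    expect_identical(st$n_regions, oracle_regions(inside))
    expect_identical(st$surface_area, oracle_surface(inside))
  }
})

test_that("adjusted surface area and C_scale calibration solve the endpoint equation", {
  st <- list(surface_area = 120, n_regions = 40)
  expect_equal(adjusted_surface_area(st, 0), 120)
  expect_equal(adjusted_surface_area(st, 3), 0)
  # linearity in c_scale
  cs <- seq(0, 5, by = 0.5)
  sa <- vapply(cs, function(c) adjusted_surface_area(st, c), numeric(1))
  expect_equal(diff(sa), rep(-0.5 * 40, length(cs) - 1))
  # endpoint calibration: (SA 200, N 50) and (SA 80, N 10) -> c = 3, both ends 50
  tr <- data.frame(b_candidate = c(-100, 0, 100, 200, 300),
                   surface_area = c(200, 170, 130, 100, 80),
                   n_regions = c(50, 30, 18, 12, 10))
  cscale <- calibrate_c_scale(tr)
  expect_equal(cscale, 3)
  saj <- tr$surface_area - cscale * tr$n_regions
  expect_equal(saj[1], saj[5])
  expect_equal(saj[1], 50)
  # identical extreme region counts are an error
  tr2 <- tr; tr2$n_regions[5] <- 50
  expect_error(calibrate_c_scale(tr2), "not applicable")
  expect_error(calibrate_c_scale(tr[1:2, ]), ">= 3")
})

test_that("applicability test reproduces a hand-computed signal and noise", {
  # collinear trace: every interior point interpolates its neighbours
  # exactly, so the noise is zero
  lin <- data.frame(b_candidate = c(-100, 0, 100, 200, 300),
                    sa_adjusted = c(10, 40, 70, 100, 130))
  app <- applicability_check(lin)
  expect_equal(app$noise, 0)
  expect_equal(app$signal, 120)
  expect_true(app$applicable)
  # a tent trace is linear except at its apex, which contributes the only
  # non-zero residual: noise = sqrt(mean(c(0, 45, 0)^2)) = sqrt(675)
  tent <- data.frame(b_candidate = c(-100, 0, 100, 200, 300),
                     sa_adjusted = c(10, 55, 100, 55, 10))
  app_t <- applicability_check(tent)
  expect_equal(app_t$noise, sqrt(675), tolerance = 1e-12)
  expect_equal(app_t$signal, 90)
  expect_true(app_t$applicable)   # 90 / 25.98 > 3
  # hand-computed 5-point trace:
  # sa = (20, 70, 100, 40, 20); endpoint 20, max 100 -> signal 80
  # residuals at interior points: 70-(20+100)/2 = 10; 100-(70+40)/2 = 45;
  # 40-(100+20)/2 = -20  -> noise = sqrt((100+2025+400)/3) = sqrt(2525/3)
  tr <- data.frame(b_candidate = c(-100, 0, 100, 200, 300),
                   sa_adjusted = c(20, 70, 100, 40, 20))
  app2 <- applicability_check(tr)
  expect_equal(app2$signal, 80)
  expect_equal(app2$noise, sqrt(2525 / 3), tolerance = 1e-12)
  expect_equal(app2$applicable, 80 / sqrt(2525 / 3) >= 3)
  # a trace dipping below the endpoints near B = 50 is not applicable
  dip <- data.frame(b_candidate = seq(-100, 300, by = 50),
                    sa_adjusted = c(50, 80, 90, 30, 90, 80, 70, 60, 50))
  expect_false(applicability_check(dip)$applicable)
  expect_error(applicability_check(tr[1:3, ]), ">= 4")
})

test_that("surface area falls and regions spike as sharpening increases on noisy maps", {
  fx <- default_fixture()
  tr <- scan_sharpening(fx$map, 3)
  # SA non-increasing with B (a few grid-effect violations tolerated)
  viol <- mean(diff(tr$surface_area) > 0)
  expect_lte(viol, 0.05)
  # strong region growth at the most negative B
  expect_gt(tr$n_regions[1], 5 * stats::median(tr$n_regions))
})
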