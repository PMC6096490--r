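# Fixtures are generated in code; the heavier ones are built once per test
# run and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# standard noisy chain fixture (matches the generator defaults)
default_fixture <- function(seed = 7, true_b = 120, noise_sigma = 1) {
  cached(sprintf("fx_%d_%g_%g", seed, true_b, noise_sigma),
         make_synthetic_map(synthetic_spec(true_b = true_b,
                                           noise_sigma = noise_sigma,
                                           seed = seed)))
}

# phase-degraded fixture for the model-error robustness property (the
# degradation route the paper's own simulation used): blur to b_true, then
# randomize phases with rms error (d_min/d) radians
phase_degraded_fixture <- function(seed, b_true, d_min = 3) {
  spn <- synthetic_spec(true_b = b_true, noise_sigma = 0, seed = seed,
                        d_min = d_min)
  model <- make_model(spn)
  truth <- model_to_map(model, spn$cell, spn$grid_shape, b_values = b_true,
                        d_min = d_min)
  dg <- degrade_map(map_to_coeffs(truth, d_min = d_min),
                    function(d) pmin(pi, d_min / d), seed = seed + 1000L)
  list(model = model, truth = truth, map = coeffs_to_map(dg))
}

# recovery fixture: zero-B chain map blurred to b_true, plus shell-scaled
# Hermitian Fourier noise. Per shell the complex noise sigma is
# alpha(d) x mean shell amplitude with alpha(d) = sqrt(3) (d_min/d)^2, so the
# shell correlation to the noise-free map is ~1 at low resolution and falls
# to ~0.5 at the nominal resolution (1/sqrt(1 + 3) = 0.5).
recovery_fixture <- function(seed, b_true, d_min = 3) {
  spn <- synthetic_spec(true_b = b_true, noise_sigma = 0, seed = seed,
                        d_min = d_min)
  model <- make_model(spn)
  truth <- model_to_map(model, spn$cell, spn$grid_shape, b_values = b_true,
                        d_min = d_min)
  fc <- map_to_coeffs(truth, d_min = d_min)
  sb <- sharpmax:::shell_bins(fc, 20)
  d <- coeff_resolution(fc)
  sigma <- array(0, dim = dim(d))
  live <- sb$bins > 0L
  sigma[live] <- sqrt(3) * (d_min / d[live])^2 * sb$table$mean_amp[sb$bins[live]]
  set.seed(seed + 1000L)
  n_white <- stats::fft(array(stats::rnorm(length(d)), dim = dim(d)))
  fc$terms <- fc$terms + n_white * sigma / sqrt(length(d))
  list(model = model, truth = truth, map = coeffs_to_map(fc))
}

# pure-R flood-fill oracle for 6-connected regions (independent of the
# package's labelling code)
oracle_regions <- function(inside) {
  dm <- dim(inside)
  seen <- array(FALSE, dm)
  nbrs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  n_regions <- 0L
  for (i0 in seq_len(dm[1])) for (j0 in seq_len(dm[2])) for (k0 in seq_len(dm[3])) {
    if (!inside[i0, j0, k0] || seen[i0, j0, k0]) next
    n_regions <- n_regions + 1L
    queue <- matrix(c(i0, j0, k0), 1, 3)
    seen[i0, j0, k0] <- TRUE
    while (nrow(queue) > 0) {
      p <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (q in seq_len(6)) {
        np <- p + nbrs[q, ]
        if (any(np < 1) || any(np > dm)) next
        if (inside[np[1], np[2], np[3]] && !seen[np[1], np[2], np[3]]) {
          seen[np[1], np[2], np[3]] <- TRUE
          queue <- rbind(queue, np)
        }
      }
    }
  }
  n_regions
}

# pure-R neighbour-scan oracle for the surface area
oracle_surface <- function(inside) {
  dm <- dim(inside)
  nbrs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  count <- 0L
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (inside[i, j, k]) next
    for (q in seq_len(6)) {
      np <- c(i, j, k) + nbrs[q, ]
      if (any(np < 1) || any(np > dm)) next
      if (inside[np[1], np[2], np[3]]) { count <- count + 1L; break }
    }
  }
  count
}

# coefficients with an exact isotropic exponential falloff exp(-B s^2 / 4)
falloff_coeffs <- function(b, dims = c(24, 24, 24), cell = c(24, 24, 24),
                           seed = 1) {
  set.seed(seed)
  base <- stats::fft(array(stats::rnorm(prod(dims)), dim = dims))
  fc <- fourier_coeffs(base, cell = cell)
  d <- coeff_resolution(fc)
  ssq <- ifelse(is.infinite(d), 0, 1 / d^2)
  fc$terms <- array(complex(modulus = exp(-b * ssq / 4), argument = Arg(base)),
                    dim = dims)
  fc
}
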