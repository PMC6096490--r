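#' Specification for a synthetic test map
#'
#' Describes a reproducible Gaussian-atom fixture with known ground truth:
#' a pseudo-chain model, the overall B falloff applied to the map, the
#' additive noise level and the layout. The same spec and seed always
#' reproduce identical outputs.
#'
#' @param n_atoms number of atoms in the pseudo-chain (default 200).
#' @param cell cell edge lengths in Angstrom (default 60 x 60 x 60).
#' @param grid_shape grid dimensions (default 60 x 60 x 60, i.e. 1.0 A
#'   spacing).
#' @param true_b overall B falloff applied to the noise-free map, Angstrom^2
#'   (default 0).
#' @param noise_sigma additive white-noise standard deviation; either an
#'   absolute value in map units, or (default) interpreted relative to the
#'   standard deviation of the noise-free map when `noise_relative = TRUE`.
#' @param noise_relative if `TRUE` (default) `noise_sigma` multiplies the
#'   noise-free map's standard deviation.
#' @param d_min high-resolution limit of the generated signal in Angstrom
#'   (default 3).
#' @param seed integer RNG seed.
#' @param layout `"chain"` (single pseudo-chain), `"blob"` (compact cluster)
#'   or `"two_domain"` (two chains, one per cell half, with per-domain B from
#'   `domain_b`).
#' @param domain_b per-domain overall B values for the `two_domain` layout
#'   (default `c(60, 160)`).
#' @param margin solvent margin kept free of atoms, Angstrom (default 10).
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_atoms = 200, cell = c(60, 60, 60),
                           grid_shape = c(60, 60, 60), true_b = 0,
                           noise_sigma = 0, noise_relative = TRUE,
                           d_min = 3, seed = 1,
                           layout = c("chain", "blob", "two_domain"),
                           domain_b = c(60, 160), margin = 10) {
  layout <- match.arg(layout)
  structure(list(n_atoms = as.integer(n_atoms), cell = as.numeric(cell),
                 grid_shape = as.integer(grid_shape), true_b = true_b,
                 noise_sigma = noise_sigma, noise_relative = noise_relative,
                 d_min = d_min, seed = as.integer(seed), layout = layout,
                 domain_b = domain_b, margin = margin),
            class = "synthetic_spec")
}

# one self-avoiding pseudo-chain inside [lo, hi]^3, Calpha-like 3.8 A steps
random_chain <- function(n_atoms, lo, hi, step = 3.8, min_dist = 1.0) {
  pos <- matrix(NA_real_, n_atoms, 3)
  pos[1, ] <- lo + stats::runif(3) * (hi - lo)
  for (i in seq_len(n_atoms - 1)) {
    placed <- FALSE
    for (try in 1:200) {
      u <- stats::rnorm(3)
      cand <- pos[i, ] + step * u / sqrt(sum(u^2))
      if (any(cand < lo | cand > hi)) next
      d2 <- rowSums((pos[seq_len(i), , drop = FALSE] -
                       matrix(cand, i, 3, byrow = TRUE))^2)
      if (min(d2) >= min_dist^2) { placed <- TRUE; break }
    }
    if (!placed) stop("could not place chain inside the cell", call. = FALSE)
    pos[i + 1, ] <- cand
  }
  pos
}

#' Generate a pseudo-chain atomic model
#'
#' Atoms are placed as a self-avoiding random chain with Calpha-like 3.8 A
#' steps, at least `margin` Angstrom from every cell face, with a minimum
#' interatomic distance of 1 Angstrom. Deterministic for a given spec/seed.
#'
#' @param spec a [synthetic_spec()].
#' @return an [atomic_model()] (atom B values 0; for the `two_domain` layout
#'   each atom carries its domain's B from `spec$domain_b`).
#' @export
make_model <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  lo <- rep(spec$margin, 3)
  hi <- spec$cell - spec$margin
  if (any(hi <= lo)) stop("cell too small for the solvent margin", call. = FALSE)
  if (spec$layout == "two_domain") {
    mid <- spec$cell[1] / 2
    n1 <- spec$n_atoms %/% 2L
    p1 <- random_chain(n1, lo, c(mid - 2, hi[2], hi[3]))
    p2 <- random_chain(spec$n_atoms - n1, c(mid + 2, lo[2], lo[3]), hi)
    pos <- rbind(p1, p2)
    b <- rep(spec$domain_b[1:2], c(n1, spec$n_atoms - n1))
  } else {
    if (spec$layout == "blob") {
      ctr <- spec$cell / 2
      r <- min(spec$cell) / 2 - spec$margin
      lo <- pmax(lo, ctr - r / 1.5)
      hi <- pmin(hi, ctr + r / 1.5)
    }
    pos <- random_chain(spec$n_atoms, lo, hi)
    b <- rep(0, spec$n_atoms)
  }
  atomic_model("C", pos[, 1], pos[, 2], pos[, 3], b = b, occ = 1)
}

#' Compute a Gaussian-atom density map from a model
#'
#' Structure factors are accumulated analytically,
#' `F(hkl) = sum_i occ_i exp(-B_i s^2/4) exp(-2 pi i s . r_i)`,
#' truncated at `d_min`, and inverted to a real map. With `b_values = 0` each
#' atom is the resolution-limited point response after truncation (the
#' "zero-B model map" convention); a single-Gaussian form factor is used for
#' every element.
#'
#' @param model an [atomic_model()].
#' @param cell cell edge lengths in Angstrom.
#' @param grid_shape grid dimensions.
#' @param b_values per-atom B override in Angstrom^2 (scalar or vector);
#'   `NULL` uses the model's own B column.
#' @param d_min high-resolution truncation in Angstrom (must respect the grid
#'   Nyquist limit).
#' @param origin grid-index origin shift of the target box (atoms are placed
#'   in the same Cartesian frame as a [volume_grid()] with this origin).
#' @return a [volume_grid()].
#' @export
model_to_map <- function(model, cell, grid_shape, b_values = NULL, d_min = NA_real_,
                         origin = c(0L, 0L, 0L)) {
  stopifnot(inherits(model, "atomic_model"))
  cell <- as.numeric(cell)
  grid_shape <- as.integer(grid_shape)
  sp <- cell / grid_shape
  if (is.finite(d_min) && d_min < 2 * max(sp) - 1e-9)
    stop(sprintf("d_min = %.3f A is below the Nyquist limit %.3f A of this grid",
                 d_min, 2 * max(sp)), call. = FALSE)
  b <- if (is.null(b_values)) model$b else rep_len(as.numeric(b_values), nrow(model))
  h1 <- fft_freq(grid_shape[1]); h2 <- fft_freq(grid_shape[2]); h3 <- fft_freq(grid_shape[3])
  # fractional coordinates relative to the box corner
  fx <- (model$x / sp[1] - origin[1]) / grid_shape[1]
  fy <- (model$y / sp[2] - origin[2]) / grid_shape[2]
  fz <- (model$z / sp[3] - origin[3]) / grid_shape[3]
  # at an even-length axis the Nyquist index represents +n/2 and -n/2 at
  # once; keeping only the real part of that phase factor keeps the
  # coefficient set exactly Hermitian (real map)
  real_at_nyquist <- function(p, h, n) {
    if (n %% 2L == 0L) p[h == n %/% 2L] <- Re(p[h == n %/% 2L]) + 0i
    p
  }
  terms <- array(0 + 0i, dim = grid_shape)
  for (bu in unique(b)) {
    sel <- which(b == bu)
    acc <- array(0 + 0i, dim = grid_shape)
    for (i in sel) {
      px <- real_at_nyquist(exp(-2i * pi * h1 * fx[i]), h1, grid_shape[1]) * model$occ[i]
      py <- real_at_nyquist(exp(-2i * pi * h2 * fy[i]), h2, grid_shape[2])
      pz <- real_at_nyquist(exp(-2i * pi * h3 * fz[i]), h3, grid_shape[3])
      acc <- acc + outer(outer(px, py), pz)
    }
    if (bu != 0) {
      s1 <- h1 / cell[1]; s2 <- h2 / cell[2]; s3 <- h3 / cell[3]
      ssq <- outer(outer(s1^2, s2^2, "+"), s3^2, "+")
      acc <- acc * exp(-bu * ssq / 4)
    }
    terms <- terms + acc
  }
  fc <- truncate_coeffs(fourier_coeffs(terms, cell = cell, d_min = d_min), d_min)
  coeffs_to_map(fc, origin = origin)
}

#' Build the full synthetic fixture
#'
#' Generates the model, the noise-free map with the spec's overall B falloff,
#' and the observed map (noise-free map plus white Gaussian noise).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `model` ([atomic_model()]), `truth` (noise-free
#'   [volume_grid()]), `map` (noisy [volume_grid()]), `noise_sd` (the
#'   absolute noise level used).
#' @export
make_synthetic_map <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  model <- make_model(spec)
  bvals <- if (spec$layout == "two_domain") model$b + spec$true_b else spec$true_b
  truth <- model_to_map(model, spec$cell, spec$grid_shape,
                        b_values = bvals, d_min = spec$d_min)
  sig <- if (spec$noise_relative) spec$noise_sigma * stats::sd(truth$values)
         else spec$noise_sigma
  map <- truth
  if (sig > 0) {
    set.seed(spec$seed + 1L)
    map$values <- truth$values + array(stats::rnorm(length(truth$values), sd = sig),
                                       dim = dim(truth$values))
  }
  list(model = model, truth = truth, map = map, noise_sd = sig)
}

#' Randomize phases with resolution-dependent errors
#'
#' Rotates every Fourier term by a zero-mean Gaussian phase error whose
#' standard deviation is a function of the term's resolution, preserving all
#' amplitudes and Hermitian symmetry exactly; this emulates a reconstruction
#' of degraded quality.
#'
#' @param coeffs a [fourier_coeffs()].
#' @param rms_phase_error_fn function of resolution d (Angstrom) returning
#'   the phase-error standard deviation in radians.
#' @param seed integer RNG seed.
#' @return a phase-degraded [fourier_coeffs()].
#' @export
degrade_map <- function(coeffs, rms_phase_error_fn, seed = 1) {
  stopifnot(inherits(coeffs, "fourier_coeffs"), is.function(rms_phase_error_fn))
  d <- coeff_resolution(coeffs)
  sigma <- array(rms_phase_error_fn(as.numeric(d)), dim = dim(d))
  sigma[is.infinite(d)] <- 0
  set.seed(seed)
  theta <- array(stats::rnorm(length(d)), dim = dim(d))
  # antisymmetrize so that theta(-h) = -theta(h): the perturbed set stays
  # Hermitian; (a - b)/sqrt(2) keeps unit variance, and self-conjugate terms
  # (h = -h mod n) get exactly zero
  rev_idx <- function(n) c(1L, n:2L)
  dm <- dim(d)
  theta <- (theta - theta[rev_idx(dm[1]), rev_idx(dm[2]), rev_idx(dm[3])]) / sqrt(2)
  coeffs$terms <- coeffs$terms * exp(1i * sigma * theta)
  coeffs
}

#' Simulate a pair of half-maps
#'
#' Adds independent white Gaussian noise to two copies of the true map, as in
#' reconstructions from independent halves of the particle data.
#'
#' @param true_map a [volume_grid()].
#' @param noise_sigma absolute noise standard deviation in map units.
#' @param seed integer RNG seed.
#' @return list of two [volume_grid()]s, `half1` and `half2`.
#' @export
make_half_maps <- function(true_map, noise_sigma, seed = 1) {
  stopifnot(inherits(true_map, "volume_grid"))
  dm <- dim(true_map$values)
  set.seed(seed)
  h1 <- h2 <- true_map
  if (noise_sigma > 0) {
    h1$values <- true_map$values + array(stats::rnorm(prod(dm), sd = noise_sigma), dm)
    h2$values <- true_map$values + array(stats::rnorm(prod(dm), sd = noise_sigma), dm)
  }
  list(half1 = h1, half2 = h2)
}

#' Perturb model coordinates by a target r.m.s. displacement
#'
#' Adds isotropic Gaussian displacements so that the expected r.m.s. total
#' displacement per atom equals `rmse`. B values and occupancies are
#' unchanged.
#'
#' @param model an [atomic_model()].
#' @param rmse target r.m.s. coordinate displacement in Angstrom.
#' @param seed integer RNG seed.
#' @return a jittered [atomic_model()].
#' @export
jitter_model <- function(model, rmse, seed = 1) {
  stopifnot(inherits(model, "atomic_model"), rmse >= 0)
  if (rmse == 0) return(model)
  set.seed(seed)
  n <- nrow(model)
  sd_axis <- rmse / sqrt(3)
  model$x <- model$x + stats::rnorm(n, sd = sd_axis)
  model$y <- model$y + stats::rnorm(n, sd = sd_axis)
  model$z <- model$z + stats::rnorm(n, sd = sd_axis)
  model
}
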