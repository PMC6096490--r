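#' Four-parameter sharpening model
#'
#' The map is rescaled in reciprocal space with an overall scale factor
#' \deqn{A(d) = w_s(d)\,A_{sharpen}(d) + w_b(d)\,A_{blur}(d)}
#' where \eqn{A_{sharpen}(d) = \exp[+B_{sharpen}/(4d^2)]} applies at lower
#' resolution, \eqn{A_{blur}(d) = \exp[-B_{blur}/(4d^2)]} acts as a soft
#' resolution limit at high resolution, and the weights
#' \deqn{w_s(d) = \frac{e^{k(d-d_{cut})}}{e^{k(d-d_{cut})} + e^{-k(d-d_{cut})}},
#'       \quad w_b(d) = 1 - w_s(d)}
#' cross over at the transition resolution `d_cut` (weights equal there) with
#' steepness `k`. A positive `b_sharpen` sharpens the map; a negative value
#' blurs it, in which case no high-resolution blur is applied
#' (`A(d) = A_sharpen(d)` everywhere).
#'
#' @param b_sharpen sharpening B factor in Angstrom^2 (positive = sharpen,
#'   negative = blur).
#' @param d_cut transition resolution in Angstrom (typically the nominal map
#'   resolution).
#' @param b_blur high-resolution blurring B factor in Angstrom^2 (default 200).
#' @param k transition steepness in 1/Angstrom (default 10; the transition is
#'   more than 90 percent complete over `d_cut` +/- 0.2 Angstrom).
#' @return an object of class `sharpen_params`.
#' @export
sharpen_params <- function(b_sharpen, d_cut, b_blur = 200, k = 10) {
  if (!is.finite(b_sharpen)) stop("b_sharpen must be finite", call. = FALSE)
  if (!is.finite(d_cut) || d_cut <= 0) stop("d_cut must be > 0", call. = FALSE)
  if (!is.finite(b_blur) || b_blur < 0) stop("b_blur must be >= 0", call. = FALSE)
  if (!is.finite(k) || k <= 0) stop("k must be > 0", call. = FALSE)
  structure(list(b_sharpen = b_sharpen, d_cut = d_cut, b_blur = b_blur, k = k),
            class = "sharpen_params")
}

#' @export
print.sharpen_params <- function(x, ...) {
  cat(sprintf("<sharpen_params> b_sharpen = %.1f A^2, d_cut = %.2f A, b_blur = %.0f A^2, k = %.0f /A\n",
              x$b_sharpen, x$d_cut, x$b_blur, x$k))
  invisible(x)
}

#' Sharpen/blur crossover weights
#'
#' Evaluates the resolution-dependent weights on the sharpening and blurring
#' scale factors. The weights always sum to one; they are equal at
#' `d = d_cut`, the sharpening weight tends to 1 at low resolution
#' (`d >> d_cut`) and to 0 at high resolution.
#'
#' @param d resolution(s) in Angstrom (vectorized).
#' @param params a [sharpen_params()].
#' @return data frame with columns `d`, `w_sharpen`, `w_blur`.
#' @export
sharpen_weights <- function(d, params) {
  stopifnot(inherits(params, "sharpen_params"))
  # e^{k(d-dc)} / (e^{k(d-dc)} + e^{-k(d-dc)}) computed stably as a logistic
  w_s <- stats::plogis(2 * params$k * (d - params$d_cut))
  w_s[is.infinite(d)] <- 1
  data.frame(d = d, w_sharpen = w_s, w_blur = 1 - w_s)
}

#' Per-resolution sharpening scale factors
#'
#' Evaluates the sharpening factor, blurring factor, crossover weights and
#' combined scale `A(d)` at arbitrary resolutions. When `b_sharpen <= 0`
#' (overall blurring) the high-resolution blur is disabled and
#' `a_total = a_sharpen`.
#'
#' @param d resolution(s) in Angstrom (vectorized; `Inf` is the zero
#'   frequency and always gets scale 1 for the exponential factors).
#' @param params a [sharpen_params()].
#' @return data frame with columns `d`, `a_sharpen`, `a_blur`, `w_sharpen`,
#'   `w_blur`, `a_total`.
#' @export
sharpen_scale <- function(d, params) {
  stopifnot(inherits(params, "sharpen_params"))
  inv4d2 <- ifelse(is.infinite(d), 0, 1 / (4 * d^2))
  a_sharpen <- exp(params$b_sharpen * inv4d2)
  a_blur <- exp(-params$b_blur * inv4d2)
  w <- sharpen_weights(d, params)
  if (params$b_sharpen > 0) {
    a_total <- w$w_sharpen * a_sharpen + w$w_blur * a_blur
  } else {
    # a blurred map gets no additional high-resolution blurring
    w$w_sharpen <- rep(1, length(d))
    w$w_blur <- rep(0, length(d))
    a_total <- a_sharpen
  }
  data.frame(d = d, a_sharpen = a_sharpen, a_blur = a_blur,
             w_sharpen = w$w_sharpen, w_blur = w$w_blur, a_total = a_total)
}

#' Scale profile for a coefficient set
#'
#' Evaluates [sharpen_scale()] at the resolution of every retained Fourier
#' term.
#'
#' @param coeffs a [fourier_coeffs()].
#' @param params a [sharpen_params()].
#' @return data frame (class `scale_profile`) with one row per retained term:
#'   `d`, `a_sharpen`, `a_blur`, `w_sharpen`, `w_blur`, `a_total`.
#' @export
scale_profile <- function(coeffs, params) {
  stopifnot(inherits(coeffs, "fourier_coeffs"))
  d <- coeff_resolution(coeffs)
  keep <- retained_terms(coeffs, d)
  out <- sharpen_scale(as.numeric(d[keep]), params)
  class(out) <- c("scale_profile", "data.frame")
  out
}

#' Apply a sharpening scale function to Fourier coefficients
#'
#' Multiplies every retained amplitude by the combined scale `A(d)`; phases
#' are untouched. With all factors positive the operation is invertible.
#'
#' @param coeffs a [fourier_coeffs()].
#' @param params a [sharpen_params()].
#' @return a rescaled [fourier_coeffs()].
#' @export
apply_sharpening <- function(coeffs, params) {
  stopifnot(inherits(coeffs, "fourier_coeffs"))
  d <- coeff_resolution(coeffs)
  sc <- array(sharpen_scale(as.numeric(d), params)$a_total, dim = dim(d))
  keep <- retained_terms(coeffs, d)
  coeffs$terms[keep] <- coeffs$terms[keep] * sc[keep]
  coeffs
}

#' Fit the overall isotropic B factor of a map
#'
#' Wilson-style fit of the resolution falloff of mean shell amplitudes,
#' `F(d) = F0 exp(-B_iso / (4 d^2))`: the per-shell mean log amplitude is
#' regressed on the per-shell mean of `1/(4 d^2)`, weighted by shell
#' amplitude, and `B_iso` is minus the slope. When four or more shells are
#' available the lowest-resolution shell is excluded (its few strong
#' low-order terms distort the fit).
#'
#' @param coeffs a [fourier_coeffs()].
#' @param shells optional [resolution_shells()] table; computed with
#'   `n_shells` shells if missing.
#' @param n_shells shells to use when `shells` is not supplied (default 20,
#'   reduced automatically for small coefficient sets).
#' @return fitted `B_iso` in Angstrom^2.
#' @export
fit_isotropic_b <- function(coeffs, shells = NULL, n_shells = 20) {
  stopifnot(inherits(coeffs, "fourier_coeffs"))
  if (is.null(shells)) {
    n_terms <- sum(retained_terms(coeffs)) - 1L
    shells <- resolution_shells(coeffs, max(2L, min(n_shells, n_terms %/% 2L)))
  }
  sh <- shells[is.finite(shells$log_amp) & shells$mean_amp > 0, , drop = FALSE]
  if (nrow(sh) < 2L) stop("need >= 2 shells with positive mean amplitude", call. = FALSE)
  if (nrow(sh) >= 4L) sh <- sh[-which.max(sh$d_mid), , drop = FALSE]
  fit <- stats::lm.wfit(cbind(1, sh$x_mid), sh$log_amp, w = sh$mean_amp)
  -unname(fit$coefficients[2])
}

#' Remove amplitude anisotropy from a coefficient set
#'
#' Fits a symmetric anisotropic B tensor to the log amplitudes,
#' `ln|F| = c - s' B s / 4` with `s = (h/a, k/b, l/c)`, by linear least
#' squares, then rescales the amplitudes so the residual falloff is isotropic
#' with `B_iso = trace(B)/3`. Phases are unchanged.
#'
#' @param coeffs a [fourier_coeffs()].
#' @return list with elements `coeffs` (corrected [fourier_coeffs()]) and
#'   `tensor` (class `aniso_tensor`: 3x3 matrix `tensor` and scalar `b_iso`).
#' @export
remove_anisotropy <- function(coeffs) {
  stopifnot(inherits(coeffs, "fourier_coeffs"))
  dm <- dim(coeffs$terms)
  s1 <- array(fft_freq(dm[1]) / coeffs$cell[1], dim = dm)
  s2 <- aperm(array(fft_freq(dm[2]) / coeffs$cell[2], dim = dm[c(2, 1, 3)]), c(2, 1, 3))
  s3 <- aperm(array(fft_freq(dm[3]) / coeffs$cell[3], dim = dm[c(3, 2, 1)]), c(3, 2, 1))
  amp <- Mod(coeffs$terms)
  d <- coeff_resolution(coeffs)
  use <- retained_terms(coeffs, d) & is.finite(d) & amp > 0
  if (sum(use) < 20L)
    stop("too few non-zero terms to fit an anisotropic B tensor", call. = FALSE)
  X <- cbind(1,
             -s1[use]^2 / 4, -s2[use]^2 / 4, -s3[use]^2 / 4,
             -2 * s1[use] * s2[use] / 4,
             -2 * s1[use] * s3[use] / 4,
             -2 * s2[use] * s3[use] / 4)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("singular anisotropy fit; applying identity correction")
    tensor <- diag(0, 3)
    b_iso <- 0
    corr <- NULL
  } else {
    beta <- qr.coef(qrX, log(amp[use]))
    tensor <- matrix(c(beta[2], beta[5], beta[6],
                       beta[5], beta[3], beta[7],
                       beta[6], beta[7], beta[4]), 3, 3)
    b_iso <- sum(diag(tensor)) / 3
    quad <- tensor[1, 1] * s1^2 + tensor[2, 2] * s2^2 + tensor[3, 3] * s3^2 +
      2 * (tensor[1, 2] * s1 * s2 + tensor[1, 3] * s1 * s3 + tensor[2, 3] * s2 * s3)
    ssq <- s1^2 + s2^2 + s3^2
    corr <- exp(quad / 4 - b_iso * ssq / 4)  # strip anisotropic, keep isotropic part
    # on Nyquist planes (h = n/2 is its own conjugate partner) the cross terms
    # of the quadratic form are sign-ambiguous; average with the mirrored
    # factor so the corrected set stays exactly Hermitian
    rev_idx <- function(n) c(1L, n:2L)
    corr <- (corr + corr[rev_idx(dm[1]), rev_idx(dm[2]), rev_idx(dm[3])]) / 2
  }
  if (!is.null(corr)) {
    keep <- retained_terms(coeffs, d)
    coeffs$terms[keep] <- coeffs$terms[keep] * corr[keep]
  }
  list(coeffs = coeffs,
       tensor = structure(list(tensor = tensor, b_iso = b_iso),
                          class = "aniso_tensor"))
}

#' Kurtosis of map density values
#'
#' Raw (Pearson) kurtosis, the fourth central moment over the squared
#' variance; a Gaussian map has kurtosis 3. Invariant under affine rescaling
#' of the density. Well sharpened maps are peaky and have high kurtosis.
#'
#' @param map a [volume_grid()].
#' @return the kurtosis (dimensionless).
#' @export
map_kurtosis <- function(map) {
  stopifnot(inherits(map, "volume_grid"))
  v <- as.numeric(map$values)
  z <- v - mean(v)
  m2 <- mean(z^2)
  if (m2 <= 0) stop("map is constant: kurtosis undefined", call. = FALSE)
  mean(z^4) / m2^2
}

#' Empirical resolution-based overall B
#'
#' The crystallographic fallback rule used by automated map-interpretation
#' pipelines when no optimization is attempted: sharpen to an overall B equal
#' to ten times the resolution in Angstrom (e.g. 40 A^2 at 4 A).
#'
#' @param resolution nominal resolution in Angstrom.
#' @return target overall B in Angstrom^2.
#' @export
empirical_b <- function(resolution) {
  stopifnot(is.finite(resolution), resolution > 0)
  10 * resolution
}
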