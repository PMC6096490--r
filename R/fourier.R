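#' Fourier coefficients of a density map
#'
#' A `fourier_coeffs` object stores the complex discrete Fourier transform of
#' a [volume_grid()] in standard FFT layout (frequency index
#' `h = 0, 1, ..., floor(n/2), -(ceiling(n/2)-1), ..., -1` along each axis),
#' together with the cell so that each term's resolution
#' `d = 1 / |s|`, `s = (h/a, k/b, l/c)`, is defined. Terms with `d < d_min`
#' are removed (set to zero and excluded from all shell statistics).
#'
#' @param terms complex 3D array in FFT layout (unnormalized forward
#'   transform, as returned by [stats::fft()]).
#' @param cell numeric(3) cell edge lengths in Angstrom.
#' @param d_min high-resolution truncation limit in Angstrom, or `NA` for an
#'   untruncated (full-resolution) set.
#' @return an object of class `fourier_coeffs`.
#' @export
fourier_coeffs <- function(terms, cell, d_min = NA_real_) {
  if (!is.array(terms) || length(dim(terms)) != 3L)
    stop("`terms` must be a complex 3D array", call. = FALSE)
  storage.mode(terms) <- "complex"
  cell <- as.numeric(cell)
  if (length(cell) != 3L || any(cell <= 0))
    stop("`cell` must be 3 positive edge lengths", call. = FALSE)
  structure(list(terms = terms, cell = cell, d_min = as.numeric(d_min)),
            class = "fourier_coeffs")
}

#' @export
print.fourier_coeffs <- function(x, ...) {
  cat("<fourier_coeffs> ", paste(dim(x$terms), collapse = " x "),
      " terms, cell ", paste(format(x$cell, digits = 4), collapse = " x "), " A",
      if (is.finite(x$d_min)) paste0(", d_min ", format(x$d_min, digits = 3), " A"),
      "\n", sep = "")
  invisible(x)
}

# integer frequency indices along one axis in FFT layout
fft_freq <- function(n) {
  h <- 0:(n - 1)
  h[h > n / 2] <- h[h > n / 2] - n
  h
}

#' Per-term resolution of a coefficient set
#'
#' @param coeffs a [fourier_coeffs()].
#' @return numeric array of `d = 1/|s|` in Angstrom (the zero-frequency term
#'   has `d = Inf`).
#' @export
coeff_resolution <- function(coeffs) {
  stopifnot(inherits(coeffs, "fourier_coeffs"))
  d <- dim(coeffs$terms)
  s1 <- fft_freq(d[1]) / coeffs$cell[1]
  s2 <- fft_freq(d[2]) / coeffs$cell[2]
  s3 <- fft_freq(d[3]) / coeffs$cell[3]
  ssq <- outer(outer(s1^2, s2^2, "+"), s3^2, "+")
  1 / sqrt(ssq)
}

# logical array: TRUE for terms kept after d_min truncation
retained_terms <- function(coeffs, d = coeff_resolution(coeffs)) {
  if (!is.finite(coeffs$d_min)) return(array(TRUE, dim = dim(coeffs$terms)))
  d >= coeffs$d_min - 1e-9
}

#' Forward transform: density map to Fourier coefficients
#'
#' Computes the (unnormalized) forward DFT of the map and removes all terms
#' at resolutions finer than `d_min`.
#'
#' @param map a [volume_grid()].
#' @param d_min high-resolution limit in Angstrom; must be at least twice
#'   the largest grid spacing (the Nyquist limit). `NA` keeps everything.
#' @return a [fourier_coeffs()].
#' @export
map_to_coeffs <- function(map, d_min = NA_real_) {
  stopifnot(inherits(map, "volume_grid"))
  if (is.finite(d_min)) {
    nyq <- 2 * max(grid_spacing(map))
    if (d_min < nyq - 1e-9)
      stop(sprintf("d_min = %.3f A is below the Nyquist limit %.3f A of this grid",
                   d_min, nyq), call. = FALSE)
  }
  fc <- fourier_coeffs(stats::fft(map$values), cell = map$cell, d_min = d_min)
  truncate_coeffs(fc, d_min)
}

#' Truncate a coefficient set at a high-resolution limit
#'
#' Idempotent: truncating twice at the same `d_min` changes nothing.
#' @param coeffs a [fourier_coeffs()].
#' @param d_min resolution limit in Angstrom (`NA` = no truncation).
#' @return a [fourier_coeffs()] with terms at `d < d_min` zeroed.
#' @export
truncate_coeffs <- function(coeffs, d_min) {
  stopifnot(inherits(coeffs, "fourier_coeffs"))
  if (!is.finite(d_min)) return(coeffs)
  d <- coeff_resolution(coeffs)
  coeffs$terms[d < d_min - 1e-9] <- 0 + 0i
  coeffs$d_min <- d_min
  coeffs
}

#' Inverse transform: Fourier coefficients to a density map
#'
#' @param coeffs a [fourier_coeffs()] with Hermitian symmetry (as produced
#'   from any real map); non-Hermitian input is an error.
#' @param origin grid-index origin shift for the output map.
#' @return a [volume_grid()].
#' @export
coeffs_to_map <- function(coeffs, origin = c(0L, 0L, 0L)) {
  stopifnot(inherits(coeffs, "fourier_coeffs"))
  if (!is_hermitian(coeffs$terms))
    stop("coefficients are not Hermitian-symmetric; inverse map would be complex",
         call. = FALSE)
  vals <- Re(stats::fft(coeffs$terms, inverse = TRUE)) / length(coeffs$terms)
  volume_grid(vals, cell = coeffs$cell, origin = origin)
}

# check F(-h,-k,-l) == Conj(F(h,k,l)) up to roundoff
is_hermitian <- function(terms, tol = 1e-6) {
  d <- dim(terms)
  rev_idx <- function(n) c(1L, n:2L)
  mirrored <- terms[rev_idx(d[1]), rev_idx(d[2]), rev_idx(d[3])]
  scale <- max(Mod(terms))
  if (scale == 0) return(TRUE)
  max(Mod(terms - Conj(mirrored))) <= tol * scale
}

#' Bin Fourier terms into resolution shells
#'
#' Shells hold (approximately) equal numbers of terms, ordered from low to
#' high resolution; terms tied in `d` at a shell boundary all go to the
#' lower-resolution shell. The zero-frequency term (the map mean) is
#' excluded from shell statistics.
#'
#' @param coeffs a [fourier_coeffs()].
#' @param n_shells number of shells (>= 2), default 20.
#' @return a `shell_table` data frame with per-shell columns `shell`,
#'   `d_max`, `d_min`, `d_mid`, `n_terms`, `mean_amp` (mean amplitude F(d)),
#'   `x_mid` (mean of 1/(4 d^2), the Wilson-plot abscissa) and `log_amp`
#'   (mean log amplitude over non-zero terms).
#' @export
resolution_shells <- function(coeffs, n_shells = 20) {
  shell_bins(coeffs, n_shells)$table
}

# equal-count shell assignment: returns the shell table plus an integer array
# (same shape as the terms) giving each term's shell, 0 for excluded terms
# (zero frequency, truncated).
shell_bins <- function(coeffs, n_shells = 20) {
  stopifnot(inherits(coeffs, "fourier_coeffs"))
  n_shells <- as.integer(n_shells)
  if (n_shells < 2L) stop("n_shells must be >= 2", call. = FALSE)
  d <- coeff_resolution(coeffs)
  keep <- retained_terms(coeffs, d) & is.finite(d)
  kidx <- which(keep)
  dv <- d[kidx]
  n <- length(dv)
  if (n < n_shells) stop("fewer Fourier terms than shells", call. = FALSE)
  ord <- order(dv, decreasing = TRUE)     # low resolution first
  dv_s <- dv[ord]
  # nominal equal-count boundaries, then push ties into the earlier shell
  bnd <- floor(seq_len(n_shells - 1) * n / n_shells)
  for (j in seq_along(bnd)) {
    b <- bnd[j]
    while (b < n && dv_s[b + 1] == dv_s[b]) b <- b + 1L
    bnd[j] <- b
  }
  bnd <- unique(bnd[bnd < n])   # boundaries inside one tie block collapse
  starts <- c(1L, bnd + 1L)
  ends <- c(bnd, n)
  shell_sorted <- rep.int(seq_along(starts), ends - starts + 1L)
  bins <- array(0L, dim = dim(d))
  bins[kidx[ord]] <- shell_sorted
  amp_s <- Mod(coeffs$terms)[kidx][ord]
  rows <- lapply(seq_along(starts), function(j) {
    i <- starts[j]:ends[j]
    a <- amp_s[i]
    x <- 1 / (4 * dv_s[i]^2)
    data.frame(
      shell = j,
      d_max = dv_s[i[1]],
      d_min = dv_s[i[length(i)]],
      d_mid = 1 / (2 * sqrt(mean(x))),
      n_terms = length(i),
      mean_amp = mean(a),
      x_mid = mean(x),
      log_amp = if (any(a > 0)) mean(log(a[a > 0])) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("shell_table", "data.frame")
  list(table = out, bins = bins)
}
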