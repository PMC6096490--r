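#' Scan sharpening B values and record detail/connectivity diagnostics
#'
#' For each candidate target overall B, the map's Fourier amplitudes are
#' rescaled with the four-parameter function so that the overall B moves from
#' its fitted value `b0` to the target (`b_sharpen = b0 - target`), the
#' iso-contour threshold enclosing `fraction` of the molecular volume is
#' recomputed, and the surface area, region count, kurtosis and fitted
#' overall B of the rescaled map are recorded. The region-count scale
#' `C_scale` is then calibrated so the adjusted surface area is equal at the
#' scan extremes, and the signal-to-noise applicability test is evaluated.
#'
#' @param map a [volume_grid()] (already anisotropy-corrected; the
#'   `auto_sharpen_*` drivers do this by default).
#' @param resolution nominal map resolution in Angstrom; also the default
#'   transition resolution `d_cut` and the Fourier truncation limit.
#' @param b_targets candidate target overall B values in Angstrom^2
#'   (default `seq(-100, 300, by = 20)`).
#' @param d_cut,b_blur,k four-parameter model settings (defaults: `d_cut =
#'   resolution`, `b_blur = 200`, `k = 10`).
#' @param fraction molecular volume fraction inside the contour (default 0.2).
#' @param mask optional precomputed [find_molecule_mask()]; computed from
#'   `map` if missing.
#' @param model optional [atomic_model()]; when given, the zero-B map-model
#'   correlation of every candidate map is recorded in a `cc` column.
#' @param mask_radius radius (Angstrom) of the near-atom mask for the `cc`
#'   column (default 3).
#' @param b_probe,min_snr applicability-test settings (see
#'   [applicability_check()]).
#' @param n_shells shells for the overall-B fits (default 20).
#' @return an `optimization_trace`: a data frame with columns `b_candidate`,
#'   `b_fitted`, `surface_area`, `n_regions`, `sa_adjusted`, `kurtosis` (and
#'   `cc` when a model is given), with attribute `info` holding `c_scale`,
#'   `signal`, `noise`, `applicable`, `chosen_b` and `b0`.
#' @export
scan_sharpening <- function(map, resolution,
                            b_targets = seq(-100, 300, by = 20),
                            d_cut = resolution, b_blur = 200, k = 10,
                            fraction = 0.2, mask = NULL, model = NULL,
                            mask_radius = 3, b_probe = 50, min_snr = 3,
                            n_shells = 20) {
  stopifnot(inherits(map, "volume_grid"))
  b_targets <- sort(as.numeric(b_targets))
  coeffs <- map_to_coeffs(map, d_min = resolution)
  b0 <- fit_isotropic_b(coeffs, n_shells = n_shells)
  if (is.null(mask)) mask <- find_molecule_mask(map, resolution)
  model_vals <- cc_mask <- NULL
  if (!is.null(model)) {
    mm <- model_to_map(model, map$cell, dim(map$values), b_values = 0,
                       d_min = resolution, origin = map$origin)
    cc_mask <- points_near_atoms(map, model, mask_radius)
    if (!any(cc_mask)) stop("no grid points near model atoms", call. = FALSE)
    model_vals <- mm$values[cc_mask]
  }
  rows <- lapply(b_targets, function(beta) {
    params <- sharpen_params(b_sharpen = b0 - beta, d_cut = d_cut,
                             b_blur = b_blur, k = k)
    sc <- apply_sharpening(coeffs, params)
    m <- coeffs_to_map(sc, origin = map$origin)
    thr <- threshold_for_volume(m, mask, fraction)
    st <- contour_stats(m, thr, mask)
    out <- data.frame(b_candidate = beta,
                      b_fitted = fit_isotropic_b(sc, n_shells = n_shells),
                      surface_area = st$surface_area,
                      n_regions = st$n_regions,
                      kurtosis = map_kurtosis(m))
    if (!is.null(model_vals)) out$cc <- stats::cor(m$values[cc_mask], model_vals)
    out
  })
  trace <- do.call(rbind, rows)
  info <- list(b0 = b0, c_scale = NA_real_, signal = NA_real_,
               noise = NA_real_, applicable = FALSE, chosen_b = NA_real_,
               d_cut = d_cut, b_blur = b_blur, k = k, fraction = fraction,
               resolution = resolution, declined_reason = NULL)
  cs <- tryCatch(calibrate_c_scale(trace), error = function(e) e)
  if (inherits(cs, "error")) {
    trace$sa_adjusted <- NA_real_
    info$declined_reason <- conditionMessage(cs)
  } else {
    info$c_scale <- cs
    trace$sa_adjusted <- trace$surface_area - cs * trace$n_regions
    app <- applicability_check(trace, b_probe = b_probe, min_snr = min_snr)
    info$signal <- app$signal
    info$noise <- app$noise
    info$applicable <- app$applicable
    if (!app$applicable)
      info$declined_reason <- "adjusted-surface-area signal-to-noise test failed"
  }
  structure(trace, info = info, mask = mask,
            class = c("optimization_trace", "data.frame"))
}

#' @export
print.optimization_trace <- function(x, ...) {
  info <- attr(x, "info")
  cat(sprintf("<optimization_trace> %d candidates, b0 = %.1f A^2\n", nrow(x), info$b0))
  if (is.finite(info$c_scale))
    cat(sprintf("  C_scale = %.3f, signal = %.1f, noise = %.2f, applicable: %s\n",
                info$c_scale, info$signal, info$noise, info$applicable))
  if (is.finite(info$chosen_b))
    cat(sprintf("  chosen overall B = %.1f A^2\n", info$chosen_b))
  print.data.frame(as.data.frame(x), ...)
  invisible(x)
}

#' @export
plot.optimization_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$b_candidate, x$surface_area, type = "b", xlab = "overall B (A^2)",
                 ylab = "surface area", main = "detail", ...)
  graphics::plot(x$b_candidate, x$n_regions, type = "b", xlab = "overall B (A^2)",
                 ylab = "regions", main = "fragmentation", ...)
  graphics::plot(x$b_candidate, x$sa_adjusted, type = "b", xlab = "overall B (A^2)",
                 ylab = "adjusted surface area", main = "objective", ...)
  info <- attr(x, "info")
  if (is.finite(info$chosen_b)) graphics::abline(v = info$chosen_b, lty = 2)
  invisible(x)
}

#' Summary information of an optimization trace
#'
#' @param trace an `optimization_trace` from [scan_sharpening()] or an
#'   `auto_sharpen_*` function.
#' @return the `info` list: `b0`, `c_scale`, `signal`, `noise`, `applicable`,
#'   `chosen_b`, scan settings, and `declined_reason` when the method was not
#'   applied.
#' @export
trace_info <- function(trace) attr(trace, "info")

#' Write an optimization trace as CSV
#'
#' @param trace an `optimization_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

# argmax with ties broken toward the larger B (less sharpening)
argmax_high_b <- function(b, value) {
  mx <- max(value)
  max(b[value >= mx - 1e-12 * max(1, abs(mx))])
}

# shared driver: aniso-correct, scan, pick the optimum of `column`
auto_sharpen_driver <- function(map, resolution, column, model = NULL,
                                aniso_correct = TRUE, require_applicable = FALSE,
                                ...) {
  stopifnot(inherits(map, "volume_grid"))
  input <- map
  if (aniso_correct) {
    ac <- remove_anisotropy(map_to_coeffs(map))
    map <- coeffs_to_map(ac$coeffs, origin = map$origin)
  }
  trace <- scan_sharpening(map, resolution, model = model, ...)
  info <- attr(trace, "info")
  if (require_applicable && !isTRUE(info$applicable)) {
    message("sharpening declined: ",
            info$declined_reason %||% "applicability test failed")
    return(list(map = input, trace = trace))
  }
  vals <- trace[[column]]
  if (which.max(vals) %in% c(1L, nrow(trace)))
    warning("optimum of ", column, " lies at the scan boundary")
  chosen <- argmax_high_b(trace$b_candidate, vals)
  info$chosen_b <- chosen
  attr(trace, "info") <- info
  params <- sharpen_params(b_sharpen = info$b0 - chosen, d_cut = info$d_cut,
                           b_blur = info$b_blur, k = info$k)
  sharp <- coeffs_to_map(apply_sharpening(map_to_coeffs(map, d_min = resolution),
                                          params), origin = map$origin)
  list(map = sharp, trace = trace)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Auto-sharpen a map by maximizing the adjusted surface area
#'
#' The primary algorithm: scans candidate overall B values, calibrates
#' `C_scale`, and returns the map rescaled to the candidate maximizing the
#' adjusted surface area (ties broken toward higher B, i.e. less
#' sharpening). If the applicability test fails the input map is returned
#' unchanged with the diagnostic trace (method declined).
#'
#' @param map a [volume_grid()].
#' @param resolution nominal resolution in Angstrom.
#' @param aniso_correct correct amplitude anisotropy first (default `TRUE`).
#' @param ... scan options passed to [scan_sharpening()].
#' @return list with `map` (sharpened, or the input when declined) and
#'   `trace` (the diagnostic `optimization_trace`; see [trace_info()]).
#' @export
auto_sharpen_sa <- function(map, resolution, aniso_correct = TRUE, ...) {
  auto_sharpen_driver(map, resolution, column = "sa_adjusted",
                      aniso_correct = aniso_correct, require_applicable = TRUE, ...)
}

#' Auto-sharpen a map by maximizing kurtosis
#'
#' Same scan as [auto_sharpen_sa()], but the chosen overall B maximizes the
#' kurtosis of the candidate maps. A boundary optimum raises a warning.
#'
#' @inheritParams auto_sharpen_sa
#' @return list with `map` and `trace`.
#' @export
auto_sharpen_kurtosis <- function(map, resolution, aniso_correct = TRUE, ...) {
  auto_sharpen_driver(map, resolution, column = "kurtosis",
                      aniso_correct = aniso_correct, ...)
}

#' Auto-sharpen a map by maximizing zero-B map-model correlation
#'
#' Scans candidate overall B values and picks the one maximizing
#' [map_model_cc_zero_b()] against the supplied model.
#'
#' @inheritParams auto_sharpen_sa
#' @param model an [atomic_model()].
#' @param mask_radius near-atom mask radius for the correlation, Angstrom.
#' @return list with `map` and `trace` (with a `cc` column).
#' @export
auto_sharpen_model <- function(map, model, resolution, aniso_correct = TRUE,
                               mask_radius = 3, ...) {
  auto_sharpen_driver(map, resolution, column = "cc", model = model,
                      mask_radius = mask_radius, aniso_correct = aniso_correct, ...)
}

#' Convert a half-map FSC to an estimate of the true map correlation
#'
#' `CC* = sqrt(2 CC / (1 + CC))`: the estimated correlation between the full
#' map and a perfect (noise-free) map, given the Fourier shell correlation
#' `CC` between two half-maps. Non-positive FSC values carry no usable
#' signal and map to 0; the result is clipped to `[0, 1]`.
#'
#' @param cc Fourier shell correlation(s) in (-1, 1] (vectorized).
#' @return CC* value(s) in `[0, 1]`.
#' @export
cc_star_from_halfmap_fsc <- function(cc) {
  if (any(cc <= -1)) stop("FSC must be > -1", call. = FALSE)
  out <- sqrt(pmax(0, 2 * cc / (1 + cc)))
  pmin(1, pmax(0, out))
}

#' Fourier shell correlation between two coefficient sets
#'
#' @param coeffs1,coeffs2 [fourier_coeffs()] on the same grid and cell.
#' @param n_shells number of resolution shells (default 20).
#' @return a `shell_table` for `coeffs1` with an added `fsc` column.
#' @export
fsc_shells <- function(coeffs1, coeffs2, n_shells = 20) {
  stopifnot(inherits(coeffs1, "fourier_coeffs"), inherits(coeffs2, "fourier_coeffs"))
  if (!identical(dim(coeffs1$terms), dim(coeffs2$terms)))
    stop("coefficient sets are on different grids", call. = FALSE)
  sb <- shell_bins(coeffs1, n_shells)
  bins <- as.integer(sb$bins)
  f1 <- as.complex(coeffs1$terms)
  f2 <- as.complex(coeffs2$terms)
  use <- bins > 0L
  num <- tapply(Re(f1[use] * Conj(f2[use])), bins[use], sum)
  p1 <- tapply(Mod(f1[use])^2, bins[use], sum)
  p2 <- tapply(Mod(f2[use])^2, bins[use], sum)
  fsc <- as.numeric(num) / sqrt(as.numeric(p1) * as.numeric(p2))
  fsc[!is.finite(fsc)] <- 0
  tab <- sb$table
  tab$fsc <- fsc
  tab
}

# shared scale-by-shell machinery for half-map and model-based sharpening:
# amplitudes in each shell are scaled by R * CC*, where R is the ratio of the
# zero-B model-map mean amplitude to the full-map mean amplitude
scale_by_shell_ccstar <- function(full, model, resolution, cc_star, sb) {
  tab <- sb$table
  mm <- model_to_map(model, full$cell, dim(full$terms), b_values = 0,
                     d_min = resolution)
  mc <- map_to_coeffs(mm, d_min = resolution)
  amp_model <- Mod(mc$terms)
  bins <- as.integer(sb$bins)
  use <- bins > 0L
  mean_model <- as.numeric(tapply(amp_model[use], bins[use], mean))
  r_ratio <- rep(0, nrow(tab))
  pos <- tab$mean_amp > 0
  r_ratio[pos] <- mean_model[pos] / tab$mean_amp[pos]
  if (any(!pos)) warning("shell(s) with zero map amplitude scaled to 0")
  scale_shell <- r_ratio * cc_star
  sc <- array(1, dim = dim(full$terms))
  sc[use] <- scale_shell[bins[use]]
  full$terms[use] <- full$terms[use] * sc[use]
  tab$cc_star <- cc_star
  tab$ratio_r <- r_ratio
  attr(full, "shells") <- tab
  full
}

#' Half-map (FSC-weighted) sharpening
#'
#' Per resolution shell, the FSC between the two half-maps is converted to
#' CC* and the full map's amplitudes are scaled by `R * CC*`, where `R` is
#' the ratio of the mean zero-B model-map amplitude to the mean full-map
#' amplitude in the shell: amplitudes are raised toward the zero-B model
#' falloff and damped where the map is noisy. Phases are untouched.
#'
#' @param full a [fourier_coeffs()] of the full map.
#' @param half1,half2 the two half-maps as [volume_grid()]s on a common grid.
#' @param model an [atomic_model()] providing the zero-B amplitude reference.
#' @param resolution high-resolution limit in Angstrom.
#' @param n_shells resolution shells (default 20).
#' @return the rescaled [fourier_coeffs()], with the per-shell table
#'   (including `fsc`, `cc_star`, `ratio_r`) in attribute `"shells"`.
#' @export
halfmap_sharpen <- function(full, half1, half2, model, resolution, n_shells = 20) {
  stopifnot(inherits(full, "fourier_coeffs"),
            inherits(half1, "volume_grid"), inherits(half2, "volume_grid"))
  if (!identical(dim(half1$values), dim(half2$values)))
    stop("half-maps are on different grids", call. = FALSE)
  full <- truncate_coeffs(full, resolution)
  c1 <- map_to_coeffs(half1, d_min = resolution)
  c2 <- map_to_coeffs(half2, d_min = resolution)
  fsc_tab <- fsc_shells(c1, c2, n_shells)
  cc_star <- cc_star_from_halfmap_fsc(pmax(fsc_tab$fsc, -0.999))
  sb <- shell_bins(full, n_shells)
  out <- scale_by_shell_ccstar(full, model, resolution, cc_star, sb)
  sh <- attr(out, "shells")
  sh$fsc <- fsc_tab$fsc
  attr(out, "shells") <- sh
  out
}

#' Effective error B from an assumed model coordinate error
#'
#' `B_eff = 8 pi^2 rmse^2 / 3`, the standard relation between an isotropic
#' B value and a mean-square total displacement `rmse^2`.
#'
#' @param rmse r.m.s. model coordinate error in Angstrom.
#' @return list of class `model_error_params` with `rmse` and `b_eff`
#'   (Angstrom^2).
#' @export
model_error_params <- function(rmse) {
  stopifnot(rmse >= 0)
  structure(list(rmse = rmse, b_eff = 8 * pi^2 * rmse^2 / 3),
            class = "model_error_params")
}

#' Model-based sharpening
#'
#' Per resolution shell, the map-model FSC is corrected for assumed model
#' coordinate error by the exponential error factor
#' `CC = CC* exp(-B_eff/(4 d^2))` (so `CC* = CC exp(+B_eff/(4 d^2))`, clipped
#' to `[0, 1]`), with `B_eff` from the assumed r.m.s. error (default one
#' quarter of the resolution). Amplitudes are then scaled by `R * CC*` as in
#' [halfmap_sharpen()].
#'
#' @param full a [fourier_coeffs()] of the map.
#' @param model an [atomic_model()].
#' @param resolution high-resolution limit in Angstrom.
#' @param err a [model_error_params()]; default assumes
#'   `rmse = resolution / 4`.
#' @param n_shells resolution shells (default 20).
#' @return the rescaled [fourier_coeffs()] with the per-shell table in
#'   attribute `"shells"`.
#' @export
model_sharpen <- function(full, model, resolution,
                          err = model_error_params(resolution / 4),
                          n_shells = 20) {
  stopifnot(inherits(full, "fourier_coeffs"), inherits(model, "atomic_model"),
            inherits(err, "model_error_params"))
  full <- truncate_coeffs(full, resolution)
  mm <- model_to_map(model, full$cell, dim(full$terms), b_values = 0,
                     d_min = resolution)
  mc <- map_to_coeffs(mm, d_min = resolution)
  fsc_tab <- fsc_shells(full, mc, n_shells)
  cc_star <- pmin(1, pmax(0, fsc_tab$fsc * exp(err$b_eff * fsc_tab$x_mid)))
  sb <- shell_bins(full, n_shells)
  out <- scale_by_shell_ccstar(full, model, resolution, cc_star, sb)
  sh <- attr(out, "shells")
  sh$fsc <- fsc_tab$fsc
  attr(out, "shells") <- sh
  out
}

#' Zero-B map-model correlation
#'
#' The map-quality metric: Pearson correlation between the map (truncated to
#' `resolution`) and a map computed from the model with all B values set to
#' zero, over grid points within `mask_radius` of any atom.
#'
#' @param map a [volume_grid()].
#' @param model an [atomic_model()] overlapping the map.
#' @param resolution truncation resolution in Angstrom.
#' @param mask_radius near-atom radius in Angstrom (default 3).
#' @return the correlation coefficient.
#' @export
map_model_cc_zero_b <- function(map, model, resolution, mask_radius = 3) {
  stopifnot(inherits(map, "volume_grid"), inherits(model, "atomic_model"))
  m_t <- coeffs_to_map(map_to_coeffs(map, d_min = resolution), origin = map$origin)
  mm <- model_to_map(model, map$cell, dim(map$values), b_values = 0,
                     d_min = resolution, origin = map$origin)
  near <- points_near_atoms(map, model, mask_radius)
  if (!any(near)) stop("no grid points within mask_radius of any atom", call. = FALSE)
  stats::cor(m_t$values[near], mm$values[near])
}
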