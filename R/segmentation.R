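# Gaussian smoothing of a 3D array by FFT convolution (periodic boundaries;
# maps are boxed with solvent margins, so wrap-around touches near-flat
# density). The kernel is truncated at 3 sigma and normalized to unit sum;
# sigma = radius / sqrt(3) so the kernel's radius of gyration matches the
# requested smoothing radius.
smooth_gaussian <- function(arr, cell, radius) {
  dm <- dim(arr)
  sp <- cell / dm
  kern1 <- function(n, h, sigma) {
    x <- fft_freq(n) * h              # signed distance from kernel centre, A
    k <- exp(-x^2 / (2 * sigma^2))
    k[abs(x) > 3 * sigma] <- 0
    k
  }
  sigma <- radius / sqrt(3)
  kx <- kern1(dm[1], sp[1], sigma)
  ky <- kern1(dm[2], sp[2], sigma)
  kz <- kern1(dm[3], sp[3], sigma)
  kern <- outer(outer(kx, ky), kz)
  kern <- kern / sum(kern)
  Re(stats::fft(stats::fft(arr) * stats::fft(kern), inverse = TRUE)) / length(arr)
}

#' Identify the region occupied by the macromolecule
#'
#' The molecular region is taken to be where the locally smoothed squared
#' density (after mean removal) is high, i.e. where density variability is
#' high; the essentially flat solvent region is excluded. Starting from each
#' guessed volume fraction, the mask is refined by a two-means update on the
#' smoothed variance (points are reassigned by the midpoint of the inside and
#' outside class means) and iterated to convergence; if the map has no
#' variance contrast the guess is returned unchanged, and if different
#' starting guesses do not agree a warning is raised and the median converged
#' fraction is used.
#'
#' @param map a [volume_grid()].
#' @param resolution nominal map resolution in Angstrom; the smoothing radius
#'   defaults to 1.5x this value.
#' @param initial_fraction_guesses starting guesses for the molecular volume
#'   fraction (default `c(0.2, 0.3, 0.4, 0.5)`).
#' @param smoothing_radius override for the smoothing radius in Angstrom.
#' @param max_cycles maximum refinement cycles per guess (default 5).
#' @param tol convergence tolerance on the volume fraction (default 0.01).
#' @return an object of class `molecule_mask`: logical grid `mask`,
#'   `volume_fraction`, `smoothing_radius`.
#' @export
find_molecule_mask <- function(map, resolution,
                               initial_fraction_guesses = c(0.2, 0.3, 0.4, 0.5),
                               smoothing_radius = 1.5 * resolution,
                               max_cycles = 5, tol = 0.01) {
  stopifnot(inherits(map, "volume_grid"))
  if (stats::sd(map$values) == 0) stop("map is constant: no molecular region", call. = FALSE)
  z <- map$values - mean(map$values)
  # local r.m.s. density: square root of the smoothed squared deviation (the
  # rms is far less peaked than the squared density, so the two-class split
  # tracks the molecular envelope rather than just the atom cores)
  sv <- sqrt(pmax(smooth_gaussian(z^2, map$cell, smoothing_radius), 0))
  svv <- as.numeric(sv)
  refine <- function(f) {
    for (cycle in seq_len(max_cycles)) {
      thr <- stats::quantile(svv, 1 - f, names = FALSE)
      v_in <- mean(svv[svv >= thr])
      v_out <- mean(svv[svv < thr])
      if (!is.finite(v_out) || (v_in - v_out) < 0.2 * mean(svv))
        return(f)                       # no contrast to refine against
      f_new <- mean(svv > (v_in + v_out) / 2)
      f_new <- min(max(f_new, 0.01), 0.99)
      if (abs(f_new - f) < tol) return(f_new)
      f <- f_new
    }
    f
  }
  fr <- vapply(initial_fraction_guesses, refine, numeric(1))
  if (length(fr) > 1 && (max(fr) - min(fr)) > 0.1)
    warning("molecular volume fraction did not stabilize across starting guesses; ",
            "using the median")
  f_final <- stats::median(fr)
  thr <- stats::quantile(svv, 1 - f_final, names = FALSE)
  structure(list(mask = sv >= thr,
                 volume_fraction = mean(sv >= thr),
                 smoothing_radius = smoothing_radius),
            class = "molecule_mask")
}

#' @export
print.molecule_mask <- function(x, ...) {
  cat(sprintf("<molecule_mask> %s grid, volume fraction %.3f, smoothing radius %.2f A\n",
              paste(dim(x$mask), collapse = " x "), x$volume_fraction,
              x$smoothing_radius))
  invisible(x)
}

#' Iso-contour threshold enclosing a fixed molecular volume
#'
#' Finds the smallest density threshold such that the fraction of masked
#' (molecular) grid points at or above it does not exceed `fraction`.
#'
#' @param map a [volume_grid()].
#' @param mask a [find_molecule_mask()] result, or a logical array.
#' @param fraction target fraction of the molecular volume inside the
#'   contour (default 0.2).
#' @return the threshold in map units.
#' @export
threshold_for_volume <- function(map, mask, fraction = 0.2) {
  stopifnot(inherits(map, "volume_grid"))
  if (inherits(mask, "molecule_mask")) mask <- mask$mask
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)", call. = FALSE)
  v <- map$values[mask]
  if (length(v) == 0) stop("empty mask", call. = FALSE)
  if (max(v) == min(v)) stop("density is constant inside the mask", call. = FALSE)
  vs <- sort(v, decreasing = TRUE)
  k <- max(1L, min(length(vs), as.integer(round(fraction * length(vs)))))
  vs[k]
}

#' Contour statistics: regions and surface area at a threshold
#'
#' Points with density `>= threshold` are inside the contour. The number of
#' regions is the count of 6-connected (face-neighbour) components of the
#' inside set; the surface area is the number of outside grid points that are
#' face-adjacent to at least one inside point. Points beyond the map bounds
#' count as outside.
#'
#' @param map a [volume_grid()].
#' @param threshold contour level in map units.
#' @param mask optional logical array (or [find_molecule_mask()]) of the
#'   molecular region, used only to report the enclosed volume fraction.
#' @return an object of class `contour_stats`: `threshold`, `n_regions`,
#'   `surface_area`, `enclosed_fraction`.
#' @export
contour_stats <- function(map, threshold, mask = NULL) {
  stopifnot(inherits(map, "volume_grid"))
  inside <- map$values >= threshold
  st <- binary_contour_stats(inside)
  ef <- NA_real_
  if (!is.null(mask)) {
    if (inherits(mask, "molecule_mask")) mask <- mask$mask
    ef <- mean(inside[mask])
  }
  structure(list(threshold = threshold, n_regions = st$n_regions,
                 surface_area = st$surface_area, enclosed_fraction = ef),
            class = "contour_stats")
}

# region count + surface area for a logical 3D array
binary_contour_stats <- function(inside) {
  if (!any(inside)) return(list(n_regions = 0L, surface_area = 0L))
  labels <- .label_components6(inside, dim(inside))
  list(n_regions = attr(labels, "n_regions"),
       surface_area = surface_area_grid(inside))
}

# outside points face-adjacent to >= 1 inside point, by array shifting
surface_area_grid <- function(inside) {
  dm <- dim(inside)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  near <- array(FALSE, dim = dm)
  near[1:(nx - 1), , ] <- near[1:(nx - 1), , ] | inside[2:nx, , ]
  near[2:nx, , ] <- near[2:nx, , ] | inside[1:(nx - 1), , ]
  near[, 1:(ny - 1), ] <- near[, 1:(ny - 1), ] | inside[, 2:ny, ]
  near[, 2:ny, ] <- near[, 2:ny, ] | inside[, 1:(ny - 1), ]
  near[, , 1:(nz - 1)] <- near[, , 1:(nz - 1)] | inside[, , 2:nz]
  near[, , 2:nz] <- near[, , 2:nz] | inside[, , 1:(nz - 1)]
  sum(!inside & near)
}

#' @export
print.contour_stats <- function(x, ...) {
  cat(sprintf("<contour_stats> threshold %.4g: %d region(s), surface area %d%s\n",
              x$threshold, x$n_regions, x$surface_area,
              if (is.finite(x$enclosed_fraction))
                sprintf(", enclosed fraction %.3f", x$enclosed_fraction) else ""))
  invisible(x)
}

#' Adjusted surface area
#'
#' The sharpening objective: surface area minus a scaled count of contiguous
#' regions, `SA_adjusted = SA - C_scale * N_regions`. Detail raises the
#' surface area; fragmentation raises the region count and is penalized.
#'
#' @param stats a [contour_stats()] object (or anything with elements
#'   `surface_area` and `n_regions`).
#' @param c_scale the region-count scale factor.
#' @return the adjusted surface area.
#' @export
adjusted_surface_area <- function(stats, c_scale) {
  stats$surface_area - c_scale * stats$n_regions
}

#' Calibrate the region-count scale factor from a sharpening scan
#'
#' Sets `C_scale` so the adjusted surface area is identical for the
#' most-sharpened (lowest candidate B) and least-sharpened (highest candidate
#' B) entries of a scan:
#' `C_scale = (SA_first - SA_last) / (N_first - N_last)`.
#'
#' @param trace a data frame sorted by candidate B with columns
#'   `surface_area` and `n_regions` (e.g. an [scan_sharpening()] trace).
#' @return the calibrated `C_scale`.
#' @export
calibrate_c_scale <- function(trace) {
  if (nrow(trace) < 3L) stop("need a scan of >= 3 points", call. = FALSE)
  n <- nrow(trace)
  dn <- trace$n_regions[1] - trace$n_regions[n]
  if (dn == 0)
    stop("region counts are equal at the scan extremes: C_scale undefined, ",
         "adjusted-surface-area sharpening not applicable", call. = FALSE)
  (trace$surface_area[1] - trace$surface_area[n]) / dn
}

#' Signal-to-noise applicability test for surface-area sharpening
#'
#' The adjusted-surface-area criterion is only used when its maximum is a
#' clear interior feature of the scan. Two checks: (i) the adjusted surface
#' area at the scanned point nearest a probe B (default 50 A^2) must not fall
#' below the (equal) endpoint values; (ii) the signal, the maximum adjusted
#' surface area minus the endpoint value, must exceed `min_snr` times the
#' noise, the r.m.s. deviation of interior points from the linear
#' interpolation of their two neighbours.
#'
#' @param trace data frame sorted by `b_candidate` with an `sa_adjusted`
#'   column (endpoints equal after [calibrate_c_scale()]).
#' @param b_probe probe overall B in Angstrom^2 (default 50).
#' @param min_snr minimum signal-to-noise ratio (default 3).
#' @return list with `applicable` (logical), `signal`, `noise`.
#' @export
applicability_check <- function(trace, b_probe = 50, min_snr = 3) {
  if (nrow(trace) < 4L) stop("need a scan of >= 4 points", call. = FALSE)
  sa <- trace$sa_adjusted
  n <- length(sa)
  endpoint <- sa[1]
  i_probe <- which.min(abs(trace$b_candidate - b_probe))
  probe_ok <- sa[i_probe] >= endpoint
  signal <- max(sa) - endpoint
  interior <- 2:(n - 1)
  resid <- sa[interior] - (sa[interior - 1] + sa[interior + 1]) / 2
  noise <- sqrt(mean(resid^2))
  snr_ok <- if (noise == 0) signal > 0 else (signal / noise) >= min_snr
  list(applicable = probe_ok && snr_ok, signal = signal, noise = noise)
}

#' Write a molecule mask as an MRC map of 0/1 values
#'
#' @param mask a [find_molecule_mask()] result.
#' @param map the [volume_grid()] the mask belongs to (for cell/origin).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, map, path) {
  stopifnot(inherits(mask, "molecule_mask"), inherits(map, "volume_grid"))
  write_map(volume_grid(array(as.numeric(mask$mask), dim = dim(mask$mask)),
                        cell = map$cell, origin = map$origin), path)
}
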