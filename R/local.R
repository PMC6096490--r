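#' Plan overlapping boxes covering the molecular region
#'
#' Tiles the bounding box of the mask with cubes of `size` grid units at
#' 50 percent overlap (stride `size/2`), clipped at the map edges; boxes
#' containing no masked point are dropped. Every masked point lies in at
#' least one box. An axis whose masked extent fits in one box gets a single
#' box centred on the masked region.
#'
#' @param map a [volume_grid()].
#' @param mask a [find_molecule_mask()] result or logical array.
#' @param size box edge in grid units (default 40).
#' @param stride box spacing in grid units (default `size / 2`).
#' @return list of `local_box` objects, each with 0-based grid `origin`,
#'   integer `size` (per axis, clipped), and Cartesian `center` (Angstrom).
#' @export
plan_boxes <- function(map, mask, size = 40, stride = max(1L, size %/% 2L)) {
  stopifnot(inherits(map, "volume_grid"))
  if (inherits(mask, "molecule_mask")) mask <- mask$mask
  if (!any(mask)) stop("mask is empty: nothing to box", call. = FALSE)
  if (size < 8) stop("box size must be >= 8 grid units", call. = FALSE)
  dm <- dim(map$values)
  idx <- which(mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  axis_starts <- function(ax) {
    extent <- hi[ax] - lo[ax] + 1L
    n <- dm[ax]
    if (extent <= size) {
      ctr <- (lo[ax] + hi[ax]) / 2
      s <- round(ctr - size / 2)
      max(1L, min(as.integer(s), n - min(size, n) + 1L))
    } else {
      lo[ax] + stride * (0:(ceiling(extent / stride) - 1L))
    }
  }
  sx <- axis_starts(1); sy <- axis_starts(2); sz <- axis_starts(3)
  sp <- grid_spacing(map)
  boxes <- list()
  for (x0 in sx) for (y0 in sy) for (z0 in sz) {
    start <- c(x0, y0, z0)
    end <- pmin(dm, start + size - 1L)
    sub <- mask[start[1]:end[1], start[2]:end[2], start[3]:end[3], drop = FALSE]
    if (!any(sub)) next
    bsize <- end - start + 1L
    if (any(bsize < 4L)) {             # widen degenerate clipped boxes
      start <- pmax(1L, end - pmax(bsize, 4L) + 1L)
      bsize <- end - start + 1L
    }
    boxes[[length(boxes) + 1L]] <- structure(
      list(origin = as.integer(start - 1L), size = as.integer(bsize),
           center = (map$origin + start - 1L + (bsize - 1) / 2) * sp),
      class = "local_box")
  }
  boxes
}

# Cartesian distance from every voxel of a box to a point (Angstrom)
box_distances <- function(box, map_origin, sp) {
  ax <- lapply(1:3, function(i)
    (map_origin[i] + box$origin[i] + seq_len(box$size[i]) - 1) * sp[i])
  dx2 <- (ax[[1]] - box$center[1])^2
  dy2 <- (ax[[2]] - box$center[2])^2
  dz2 <- (ax[[3]] - box$center[3])^2
  sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
}

# mean nearest-neighbour distance between box centres (Angstrom)
mean_nn_center_distance <- function(boxes, fallback) {
  if (length(boxes) < 2) return(fallback)
  ctrs <- do.call(rbind, lapply(boxes, `[[`, "center"))
  dd <- as.matrix(stats::dist(ctrs))
  diag(dd) <- Inf
  mean(apply(dd, 1, min))
}

#' Recombine sharpened boxes with distance-weighted averaging
#'
#' Each output grid point takes the weighted average of all boxes covering
#' it, with weight `w = exp(-d / d_o)` where `d` is the Cartesian distance
#' from the point to the box centre; the combination is exact for constant
#' fields and independent of box order.
#'
#' @param boxes list of `local_box` objects from [plan_boxes()].
#' @param maps list of [volume_grid()]s, the sharpened density of each box.
#' @param template a [volume_grid()] giving the output geometry.
#' @param d_o weight characteristic distance in Angstrom; default is the
#'   mean nearest-neighbour distance between box centres.
#' @param fill optional array of values for grid points covered by no box
#'   (e.g. the original density outside the boxed molecular region); when
#'   `NULL` (default) an uncovered point is an error.
#' @return a [volume_grid()] on the template grid.
#' @export
combine_boxes <- function(boxes, maps, template, d_o = NULL, fill = NULL) {
  stopifnot(inherits(template, "volume_grid"), length(boxes) == length(maps))
  sp <- grid_spacing(template)
  if (is.null(d_o))
    d_o <- mean_nn_center_distance(boxes, fallback = mean(sp) * mean(boxes[[1]]$size) / 2)
  if (!is.finite(d_o) || d_o <= 0) stop("d_o must be > 0", call. = FALSE)
  dm <- dim(template$values)
  num <- array(0, dm)
  den <- array(0, dm)
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]
    w <- exp(-box_distances(b, template$origin, sp) / d_o)
    ix <- (b$origin[1] + 1):(b$origin[1] + b$size[1])
    iy <- (b$origin[2] + 1):(b$origin[2] + b$size[2])
    iz <- (b$origin[3] + 1):(b$origin[3] + b$size[3])
    num[ix, iy, iz] <- num[ix, iy, iz] + w * maps[[i]]$values
    den[ix, iy, iz] <- den[ix, iy, iz] + w
  }
  uncovered <- den == 0
  if (any(uncovered)) {
    if (is.null(fill))
      stop("some output grid points are covered by no box", call. = FALSE)
    num[uncovered] <- fill[uncovered]
    den[uncovered] <- 1
  }
  volume_grid(num / den, cell = template$cell, origin = template$origin)
}

#' Local (per-box) map sharpening
#'
#' Cuts overlapping boxes over the molecular region, sharpens each box
#' independently with the chosen global method at the global resolution, and
#' recombines the boxes with exponential distance weighting. Boxes where the
#' method declines or fails fall back to the unsharpened box with a warning.
#'
#' @param map a [volume_grid()].
#' @param resolution nominal resolution in Angstrom (used for every box).
#' @param method `"sa"`, `"kurtosis"`, `"model"` or `"half_map"`.
#' @param model an [atomic_model()] (required for `"model"` and
#'   `"half_map"`).
#' @param half1,half2 half-maps (required for `"half_map"`).
#' @param size box edge in grid units (default 40).
#' @param d_o weight falloff distance in Angstrom (default: mean
#'   nearest-neighbour box-centre distance).
#' @param mask optional molecule mask; computed from the map if missing.
#' @param ... further options passed to the per-box scan (e.g. `b_targets`).
#' @return a [volume_grid()]; attribute `"box_trace"` holds a data frame of
#'   box centres and per-box chosen overall B (NA where the method declined).
#' @export
local_sharpen <- function(map, resolution, method = c("sa", "kurtosis", "model", "half_map"),
                          model = NULL, half1 = NULL, half2 = NULL,
                          size = 40, d_o = NULL, mask = NULL, ...) {
  method <- match.arg(method)
  stopifnot(inherits(map, "volume_grid"))
  if (method %in% c("model", "half_map") && is.null(model))
    stop("method '", method, "' requires a model", call. = FALSE)
  if (method == "half_map" && (is.null(half1) || is.null(half2)))
    stop("method 'half_map' requires both half-maps", call. = FALSE)
  if (is.null(mask)) mask <- find_molecule_mask(map, resolution)
  boxes <- plan_boxes(map, mask, size = size)
  sp <- grid_spacing(map)
  cut_box <- function(src, b) {
    ix <- (b$origin[1] + 1):(b$origin[1] + b$size[1])
    iy <- (b$origin[2] + 1):(b$origin[2] + b$size[2])
    iz <- (b$origin[3] + 1):(b$origin[3] + b$size[3])
    volume_grid(src$values[ix, iy, iz, drop = FALSE], cell = sp * b$size,
                origin = src$origin + b$origin)
  }
  model_in_box <- function(b) {
    lo <- (map$origin + b$origin) * sp
    hi <- lo + b$size * sp
    sel <- model$x >= lo[1] & model$x <= hi[1] &
      model$y >= lo[2] & model$y <= hi[2] &
      model$z >= lo[3] & model$z <= hi[3]
    model[sel, , drop = FALSE]
  }
  chosen <- rep(NA_real_, length(boxes))
  maps <- vector("list", length(boxes))
  for (i in seq_along(boxes)) {
    b <- boxes[[i]]
    sub <- cut_box(map, b)
    res <- tryCatch({
      if (method == "sa") {
        r <- auto_sharpen_sa(sub, resolution, aniso_correct = FALSE, ...)
        if (!isTRUE(trace_info(r$trace)$applicable)) stop("declined")
        r
      } else if (method == "kurtosis") {
        suppressWarnings(auto_sharpen_kurtosis(sub, resolution,
                                               aniso_correct = FALSE, ...))
      } else if (method == "model") {
        bm <- model_in_box(b)
        if (nrow(bm) < 3) stop("too few atoms in box")
        suppressWarnings(auto_sharpen_model(sub, bm, resolution,
                                            aniso_correct = FALSE, ...))
      } else {
        bm <- model_in_box(b)
        if (nrow(bm) < 3) stop("too few atoms in box")
        fc <- halfmap_sharpen(map_to_coeffs(sub, d_min = resolution),
                              cut_box(half1, b), cut_box(half2, b),
                              bm, resolution)
        list(map = coeffs_to_map(fc, origin = sub$origin), trace = NULL)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("box %d at (%.0f, %.0f, %.0f) A not sharpened (%s); using original density",
                      i, b$center[1], b$center[2], b$center[3],
                      conditionMessage(res)))
      maps[[i]] <- sub
    } else {
      maps[[i]] <- res$map
      if (!is.null(res$trace)) chosen[i] <- trace_info(res$trace)$chosen_b
    }
  }
  out <- combine_boxes(boxes, maps, template = map, d_o = d_o, fill = map$values)
  ctrs <- do.call(rbind, lapply(boxes, `[[`, "center"))
  attr(out, "box_trace") <- data.frame(center_x = ctrs[, 1], center_y = ctrs[, 2],
                                       center_z = ctrs[, 3], chosen_b = chosen)
  out
}
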