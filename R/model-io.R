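#' Construct an atomic model
#'
#' A minimal per-atom table used for synthetic map generation, model-based
#' sharpening and the zero-B map-model correlation metric.
#'
#' @param element character vector of element symbols.
#' @param x,y,z Cartesian coordinates in Angstrom.
#' @param b isotropic atomic B values in Angstrom^2 (>= 0).
#' @param occ occupancies in `[0, 1]`.
#' @return a data frame of class `atomic_model` with columns
#'   `element, x, y, z, b, occ`.
#' @export
atomic_model <- function(element, x, y, z, b = 0, occ = 1) {
  n <- length(x)
  df <- data.frame(element = rep_len(as.character(element), n),
                   x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                   b = rep_len(as.numeric(b), n),
                   occ = rep_len(as.numeric(occ), n),
                   stringsAsFactors = FALSE)
  if (any(!is.finite(df$x + df$y + df$z)))
    stop("atom positions must be finite", call. = FALSE)
  if (any(df$occ < 0 | df$occ > 1)) stop("occupancy must be in [0, 1]", call. = FALSE)
  if (any(is.finite(df$b) & df$b < 0)) stop("B values must be >= 0", call. = FALSE)
  class(df) <- c("atomic_model", "data.frame")
  df
}

#' Read an atomic model from PDB or mmCIF
#'
#' Thin wrapper over [bio3d::read.pdb()] / [bio3d::read.cif()]; the format is
#' chosen from the file extension (`.cif` is mmCIF, anything else PDB).
#'
#' @param path path to a PDB or mmCIF file.
#' @return an [atomic_model()].
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("cannot read model: no such file: ", path, call. = FALSE)
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- if (is_cif) bio3d::read.cif(path) else bio3d::read.pdb(path)
  a <- pdb$atom
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(a$elety), 1, 1)
  occ <- a$o
  occ[is.na(occ)] <- 1
  b <- a$b
  b[is.na(b)] <- 0
  atomic_model(trimws(elem), a$x, a$y, a$z, b = pmax(b, 0), occ = pmin(pmax(occ, 0), 1))
}

#' Write an atomic model as PDB
#'
#' @param model an [atomic_model()].
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "atomic_model"))
  n <- nrow(model)
  xyz <- as.numeric(t(as.matrix(model[, c("x", "y", "z")])))
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", n),
                   resno = seq_len(n), resid = rep("ALA", n),
                   elety = rep("CA", n), chain = rep("A", n),
                   o = model$occ, b = model$b,
                   elesy = model$element)
  invisible(path)
}

# logical grid: TRUE where a grid point lies within `radius` (Angstrom) of
# any atom. Works per atom over a local sub-cube, so cost is O(n_atoms * r^3).
points_near_atoms <- function(map, model, radius) {
  sp <- grid_spacing(map)
  dm <- dim(map$values)
  ax <- grid_axes(map)
  near <- array(FALSE, dim = dm)
  nr <- ceiling(radius / sp)
  for (i in seq_len(nrow(model))) {
    p <- c(model$x[i], model$y[i], model$z[i])
    ctr <- p / sp - map$origin + 1        # fractional 1-based grid index
    lo <- pmax(1, floor(ctr - nr)); hi <- pmin(dm, ceiling(ctr + nr))
    if (any(lo > hi)) next
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    dx2 <- (ax[[1]][ix] - p[1])^2
    dy2 <- (ax[[2]][iy] - p[2])^2
    dz2 <- (ax[[3]][iz] - p[3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    near[ix, iy, iz] <- near[ix, iy, iz] | (d2 <= radius^2)
  }
  near
}

#' Extract the map region near an atomic model
#'
#' Cuts the minimal enclosing box (same grid spacing) around all grid points
#' within `radius` of any atom, zeroing density farther than `radius` from
#' every atom. The output grid keeps the global Cartesian frame through its
#' origin shift, so the model coordinates remain valid for the extracted map.
#'
#' @param map a [volume_grid()].
#' @param model an [atomic_model()] overlapping the map.
#' @param radius inclusion radius in Angstrom (default 5).
#' @return a [volume_grid()] covering the model neighbourhood.
#' @export
extract_region_near_model <- function(map, model, radius = 5) {
  stopifnot(inherits(map, "volume_grid"), inherits(model, "atomic_model"))
  near <- points_near_atoms(map, model, radius)
  if (!any(near)) stop("model does not overlap the map within `radius`", call. = FALSE)
  idx <- which(near, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  vals <- map$values
  vals[!near] <- 0
  sub <- vals[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  n_new <- hi - lo + 1
  if (any(n_new < 4L)) {  # pad tiny boxes up to the minimum legal grid
    pad <- pmax(0L, 4L - n_new)
    hi2 <- pmin(dim(map$values), hi + pad)
    lo2 <- pmax(1L, lo - pmax(0L, 4L - (hi2 - lo + 1L)))
    sub <- vals[lo2[1]:hi2[1], lo2[2]:hi2[2], lo2[3]:hi2[3], drop = FALSE]
    lo <- lo2
    n_new <- dim(sub)
  }
  sp <- grid_spacing(map)
  volume_grid(sub, cell = sp * n_new, origin = map$origin + lo - 1L)
}
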