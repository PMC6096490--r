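#' Construct a density map on a 3D grid
#'
#' A `volume_grid` holds real-space density values on a regular 3D grid in an
#' orthogonal unit cell (angles fixed at 90 degrees). The Cartesian position
#' (in Angstrom) of the 0-based grid index `(i, j, k)` is
#' `(origin + c(i, j, k)) * cell / grid_shape`, so `origin` is a grid-index
#' offset of the first stored point, as in the MRC/CCP4 `NXSTART` fields.
#'
#' @param values numeric 3D array of density values (arbitrary map units).
#' @param cell numeric(3), unit-cell edge lengths a, b, c in Angstrom spanned
#'   by the stored grid.
#' @param origin integer(3), grid-index offset of the first grid point.
#'   Default `c(0, 0, 0)`.
#' @return an object of class `volume_grid` with elements `values`, `cell`,
#'   `origin`.
#' @examples
#' m <- volume_grid(array(rnorm(4^3), dim = c(4, 4, 4)), cell = c(8, 8, 8))
#' grid_spacing(m)
#' @export
volume_grid <- function(values, cell, origin = c(0L, 0L, 0L)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(dim(values) < 4L))
    stop("degenerate grid: all grid dimensions must be >= 4", call. = FALSE)
  cell <- as.numeric(cell)
  if (length(cell) != 3L || any(!is.finite(cell)) || any(cell <= 0))
    stop("`cell` must be 3 positive finite edge lengths (Angstrom)", call. = FALSE)
  if (any(!is.finite(values)))
    stop("map values must be finite (no NA/NaN/Inf)", call. = FALSE)
  storage.mode(values) <- "double"
  structure(
    list(values = values, cell = cell, origin = as.integer(round(origin))),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$values)
  cat("<volume_grid> ", paste(d, collapse = " x "),
      " grid, cell ", paste(format(x$cell, digits = 4), collapse = " x "),
      " A (spacing ", paste(format(grid_spacing(x), digits = 3), collapse = ", "),
      " A)\n", sep = "")
  cat("  origin shift: ", paste(x$origin, collapse = ", "),
      "; density range [", format(min(x$values), digits = 4), ", ",
      format(max(x$values), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Grid spacing of a density map
#'
#' @param map a [volume_grid()].
#' @return numeric(3) grid spacing along each axis in Angstrom.
#' @export
grid_spacing <- function(map) {
  stopifnot(inherits(map, "volume_grid"))
  map$cell / dim(map$values)
}

#' Cartesian coordinates of grid axes
#'
#' Positions (Angstrom) of the grid points along each axis, honouring the
#' origin shift.
#' @param map a [volume_grid()].
#' @return list of three numeric vectors (x, y, z axis coordinates).
#' @keywords internal
grid_axes <- function(map) {
  sp <- grid_spacing(map)
  d <- dim(map$values)
  lapply(1:3, function(i) (map$origin[i] + seq_len(d[i]) - 1) * sp[i])
}

# MRC/CCP4 format: 1024-byte header of 56 4-byte words + 800 bytes of labels,
# followed by the density raster. Only modes 0 (int8), 1 (int16) and 2
# (float32) are supported; files are read/written little-endian.

#' Read an MRC/CCP4 density map
#'
#' Reads modes 0, 1 and 2. The axis order is normalized at read time so that
#' the stored array always has crystallographic X as the fastest-varying
#' (first) array index, whatever the file's `MAPC/MAPR/MAPS` permutation.
#' Only orthogonal cells (all angles 90 degrees) are supported.
#'
#' @param path path to an MRC/CCP4 file.
#' @return a [volume_grid()].
#' @seealso [write_map()]
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("cannot read map: no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  n_crs <- hdr_int[1:3]                      # NX NY NZ (column/row/section counts)
  mode <- hdr_int[4]
  start_crs <- hdr_int[5:7]                  # NXSTART NYSTART NZSTART
  m_xyz <- hdr_int[8:10]                     # MX MY MZ (grid sampling of full cell)
  cell_len <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cell_ang <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  map_crs <- readBin(con, "integer", n = 3, size = 4, endian = "little")  # MAPC MAPR MAPS
  invisible(readBin(con, "numeric", n = 3, size = 4, endian = "little"))  # DMIN DMAX DMEAN
  invisible(readBin(con, "integer", n = 2, size = 4, endian = "little"))  # ISPG NSYMBT
  invisible(readBin(con, "raw", n = 1024 - 24 * 4))                       # rest of header
  if (!mode %in% c(0L, 1L, 2L))
    stop("unsupported MRC mode ", mode, " (modes 0/1/2 supported)", call. = FALSE)
  if (any(abs(cell_ang - 90) > 1e-3))
    stop("non-orthogonal cell (angles ", paste(format(cell_ang), collapse = ", "),
         "): only 90-degree cells are supported", call. = FALSE)
  if (any(n_crs < 4L) || any(m_xyz <= 0L) || any(cell_len <= 0))
    stop("degenerate grid or cell in MRC header", call. = FALSE)
  n_pts <- prod(n_crs)
  vals <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n_pts, size = 1, signed = TRUE)),
    "1" = as.numeric(readBin(con, "integer", n = n_pts, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n_pts, size = 4, endian = "little"))
  if (length(vals) != n_pts) stop("truncated MRC data block", call. = FALSE)
  arr <- array(vals, dim = n_crs)
  # permute so axis order is x, y, z regardless of MAPC/MAPR/MAPS
  if (!identical(map_crs, 1:3)) {
    if (!setequal(map_crs, 1:3)) stop("invalid MAPC/MAPR/MAPS in header", call. = FALSE)
    perm <- order(map_crs)       # position of x, y, z among file axes
    arr <- aperm(arr, perm)
    start_xyz <- start_crs[perm]
    n_xyz <- n_crs[perm]
  } else {
    start_xyz <- start_crs
    n_xyz <- n_crs
  }
  spacing <- cell_len / m_xyz
  volume_grid(arr, cell = spacing * n_xyz, origin = start_xyz)
}

#' Write a density map as MRC/CCP4 (mode 2, 32-bit float)
#'
#' @param map a [volume_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "volume_grid"))
  d <- dim(map$values)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L, map$origin, d)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(map$cell, 90, 90, 90)), con, size = 4, endian = "little")
  writeBin(1:3, con, size = 4, endian = "little")   # MAPC MAPR MAPS
  writeBin(as.numeric(c(min(map$values), max(map$values), mean(map$values))),
           con, size = 4, endian = "little")
  writeBin(c(1L, 0L), con, size = 4, endian = "little")  # ISPG = 1 (P1), NSYMBT = 0
  writeBin(integer(25), con, size = 4, endian = "little")  # EXTRA (words 25-49)
  # words 50-52 hold the Cartesian ORIGIN records used by some programs; the
  # origin is carried in the NXSTART-style fields instead, so zeros go here.
  writeBin(numeric(3), con, size = 4, endian = "little")
  # word 53 'MAP ', word 54 machine stamp (little-endian), word 55 RMS, 56 NLABL
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)
  writeBin(as.numeric(stats::sd(map$values)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(raw(800), con)
  writeBin(as.numeric(map$values), con, size = 4, endian = "little")
  invisible(path)
}
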