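#' Construct a density map
#'
#' A `density_map` is a 3D scalar grid with physical metadata: the voxel size
#' in Angstrom along each axis and the Angstrom position of grid index
#' (1,1,1). The physical coordinate of voxel (i,j,k) is
#' `origin + (i-1, j-1, k-1) * voxel_size` (0-based voxel offsets). Axis
#' order is always canonical x,y,z with x varying fastest in memory.
#' Summary statistics (mean and sigma, the standard deviation over all
#' voxels) are stored on the object and recomputed by every operation that
#' mutates the grid.
#'
#' @param grid 3D numeric array of density values (each dimension >= 2).
#' @param voxel_size numeric length-1 or length-3, Angstrom per voxel
#'   along each axis; must be positive.
#' @param origin numeric length-3, Angstrom position of voxel (1,1,1).
#' @return An object of class `density_map` with fields `grid`,
#'   `voxel_size`, `origin`, `mean`, `sigma`.
#' @examples
#' m <- density_map(array(0, c(4, 4, 4)), voxel_size = 0.8)
#' m$sigma
#' @export
density_map <- function(grid, voxel_size = 1, origin = c(0, 0, 0)) {
  if (!is.array(grid) || length(dim(grid)) != 3L)
    stop("grid must be a 3D array")
  if (any(dim(grid) < 2L))
    stop("grid dimensions must be >= 2 per axis")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be positive on all axes")
  origin <- rep_len(as.numeric(origin), 3L)
  m <- structure(list(grid = grid, voxel_size = voxel_size, origin = origin,
                      mean = NA_real_, sigma = NA_real_),
                 class = "density_map")
  update_stats(m)
}

#' Recompute map statistics
#'
#' Population mean and standard deviation (sigma) over all voxels. Called
#' internally after any grid mutation; exposed because contour levels
#' throughout the package are expressed as multiples of sigma.
#'
#' @param map a `density_map`.
#' @return The map with `mean` and `sigma` refreshed.
#' @export
update_stats <- function(map) {
  stopifnot(inherits(map, "density_map"))
  v <- as.numeric(map$grid)
  map$mean <- mean(v)
  # population (not sample) sd: sigma^2 = mean of squared deviations
  map$sigma <- sqrt(mean((v - map$mean)^2))
  map
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<density_map> %d x %d x %d voxels, voxel %.4g x %.4g x %.4g A\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin (%.3f, %.3f, %.3f) A; mean %.5g; sigma %.5g\n",
              x$origin[1], x$origin[2], x$origin[3], x$mean, x$sigma))
  invisible(x)
}

#' Physical coordinates of every voxel along one axis
#' @noRd
axis_coords <- function(map, axis) {
  n <- dim(map$grid)[axis]
  map$origin[axis] + (seq_len(n) - 1) * map$voxel_size[axis]
}

#' Check that two maps share grid geometry
#' @noRd
check_same_geometry <- function(a, b) {
  if (!identical(dim(a$grid), dim(b$grid)))
    stop("grid dimensions differ: ", paste(dim(a$grid), collapse = "x"),
         " vs ", paste(dim(b$grid), collapse = "x"))
  if (max(abs(a$voxel_size - b$voxel_size)) > 1e-6)
    stop("voxel_size differs between maps")
  if (max(abs(a$origin - b$origin)) > 1e-4)
    stop("origin differs between maps")
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# MRC/CCP4 2014 volume format (mode 2, 32-bit float, orthogonal cells).
# The 1024-byte header is addressed in 4-byte words; words 1-3 NX NY NZ,
# 4 MODE, 5-7 N*START, 8-10 MX MY MZ, 11-13 CELLA, 14-16 cell angles,
# 17-19 MAPC MAPR MAPS, 20-22 DMIN DMAX DMEAN, 23 ISPG, 24 NSYMBT,
# 50-52 ORIGIN, 53 "MAP ", 54 MACHST, 55 RMS, 56 NLABL.
# ---------------------------------------------------------------------------

#' Read an MRC/CCP4 volume
#'
#' Parses a 2014-style MRC volume (mode 2 float, orthogonal cell) and
#' returns the grid in canonical x,y,z axis order regardless of the axis
#' permutation recorded in the header (MAPC/MAPR/MAPS). The returned origin
#' combines the header ORIGIN record with any N*START voxel offsets, so a
#' fixed physical coordinate addresses the same density before and after
#' permutation.
#'
#' @param path path to an MRC/CCP4 volume file.
#' @return A [density_map()].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("cannot read map: no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  if (length(hdr_int) < 256)
    stop("not an MRC volume (truncated header): ", path)
  seek(con, 0)
  hdr_flt <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nxyz <- hdr_int[1:3]
  mode <- hdr_int[4]
  if (mode != 2L)
    stop("unsupported MRC MODE field: ", mode, " (only mode 2 float supported)")
  nstart <- hdr_int[5:7]
  mxyz <- hdr_int[8:10]
  cella <- hdr_flt[11:13]
  angles <- hdr_flt[14:16]
  if (any(abs(angles - 90) > 1e-3))
    stop("non-orthogonal unit cell (CELLB = ",
         paste(signif(angles, 6), collapse = ", "), "); only orthogonal maps supported")
  mapcrs <- hdr_int[17:19]
  if (!setequal(mapcrs, 1:3))
    stop("invalid MAPC/MAPR/MAPS axis fields: ", paste(mapcrs, collapse = ","))
  nsymbt <- hdr_int[24]
  orig <- hdr_flt[50:52]
  if (any(nxyz < 1) || any(mxyz < 1))
    stop("invalid grid dimension fields NX/NY/NZ or MX/MY/MZ")
  seek(con, 1024 + nsymbt)
  nvox <- prod(nxyz)
  vals <- readBin(con, "numeric", n = nvox, size = 4, endian = "little")
  if (length(vals) < nvox) stop("truncated MRC data block in ", path)
  arr <- array(vals, dim = nxyz)          # dims in file axis order (mapc,mapr,maps)
  perm <- match(1:3, mapcrs)              # new axis j <- file dim holding axis j
  arr <- aperm(arr, perm)
  voxel <- cella / mxyz                   # sampling along crystallographic x,y,z
  start_xyz <- nstart[perm]               # N*START re-expressed on x,y,z axes
  origin <- orig + start_xyz * voxel
  density_map(arr, voxel_size = voxel, origin = origin)
}

#' Write an MRC/CCP4 volume
#'
#' Writes mode-2 (32-bit float) with canonical axis order and the physical
#' origin stored in the ORIGIN header record. `read_map(write_map(m))`
#' reproduces `m` to single-float precision.
#'
#' @param map a [density_map()].
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  stopifnot(inherits(map, "density_map"))
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop("cannot open for writing: ", path, " (", conditionMessage(e), ")"))
  on.exit(close(con), add = TRUE)
  d <- dim(map$grid)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d); wi(2L)                       # NX NY NZ, MODE
  wi(c(0L, 0L, 0L))                   # N*START
  wi(d)                               # MX MY MZ
  wf(d * map$voxel_size)              # CELLA
  wf(c(90, 90, 90))                   # CELLB
  wi(1:3)                             # MAPC MAPR MAPS canonical
  wf(c(min(map$grid), max(map$grid), map$mean))   # DMIN DMAX DMEAN
  wi(1L); wi(0L)                      # ISPG, NSYMBT
  wi(integer(25))                     # EXTRA words 25-49
  wf(map$origin)                      # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(map$sigma)                       # RMS
  wi(0L)                              # NLABL
  writeBin(raw(800), con)             # labels
  writeBin(as.numeric(map$grid), con, size = 4, endian = "little")
  invisible(path)
}

#' Interpolate map density at physical points
#'
#' Trilinear interpolation of the 8 surrounding voxels (default), or
#' separable tricubic (Catmull-Rom) interpolation of the 64 surrounding
#' voxels. The cubic variant is C1-continuous and is what the real-space
#' refinement optimizes against -- gradient ascent on the piecewise-linear
#' trilinear surface would snap atoms to voxel corners.
#'
#' @param map a [density_map()].
#' @param points numeric vector of length 3 or an n x 3 matrix of Angstrom
#'   coordinates. All points must lie inside the grid (no wrapping).
#' @param method `"linear"` or `"cubic"`.
#' @return Numeric vector of interpolated density values.
#' @export
interpolate_map <- function(map, points, method = c("linear", "cubic")) {
  stopifnot(inherits(map, "density_map"))
  method <- match.arg(method)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  if (method == "cubic") return(interpolate_cubic(map, points))
  d <- dim(map$grid)
  # fractional voxel index, 1-based
  fi <- sweep(sweep(points, 2, map$origin, "-"), 2, map$voxel_size, "/") + 1
  if (any(fi < 1 - 1e-9) || any(sweep(fi, 2, d, "-") > 1e-9))
    stop("interpolation point outside grid bounds")
  fi <- pmin(pmax(fi, 1), matrix(d, nrow(fi), 3, byrow = TRUE))
  i0 <- pmin(floor(fi), matrix(d - 1L, nrow(fi), 3, byrow = TRUE))
  t <- fi - i0
  g <- map$grid
  idx <- function(dx, dy, dz)
    g[cbind(i0[, 1] + dx, i0[, 2] + dy, i0[, 3] + dz)]
  v <-
    idx(0, 0, 0) * (1 - t[, 1]) * (1 - t[, 2]) * (1 - t[, 3]) +
    idx(1, 0, 0) *      t[, 1]  * (1 - t[, 2]) * (1 - t[, 3]) +
    idx(0, 1, 0) * (1 - t[, 1]) *      t[, 2]  * (1 - t[, 3]) +
    idx(0, 0, 1) * (1 - t[, 1]) * (1 - t[, 2]) *      t[, 3]  +
    idx(1, 1, 0) *      t[, 1]  *      t[, 2]  * (1 - t[, 3]) +
    idx(1, 0, 1) *      t[, 1]  * (1 - t[, 2]) *      t[, 3]  +
    idx(0, 1, 1) * (1 - t[, 1]) *      t[, 2]  *      t[, 3]  +
    idx(1, 1, 1) *      t[, 1]  *      t[, 2]  *      t[, 3]
  as.numeric(v)
}

#' Catmull-Rom cubic convolution weights for fractional offset t in [0,1)
#' @noRd
cr_weights <- function(t) {
  t2 <- t * t; t3 <- t2 * t
  cbind(-0.5 * t3 + t2 - 0.5 * t,
         1.5 * t3 - 2.5 * t2 + 1,
        -1.5 * t3 + 2 * t2 + 0.5 * t,
         0.5 * t3 - 0.5 * t2)
}

#' Separable tricubic interpolation; border voxels are clamp-replicated
#' @noRd
interpolate_cubic <- function(map, points) {
  d <- dim(map$grid)
  fi <- sweep(sweep(points, 2, map$origin, "-"), 2, map$voxel_size, "/") + 1
  if (any(fi < 1 - 1e-9) || any(sweep(fi, 2, d, "-") > 1e-9))
    stop("interpolation point outside grid bounds")
  fi <- pmin(pmax(fi, 1), matrix(d, nrow(fi), 3, byrow = TRUE))
  i0 <- pmin(floor(fi), matrix(d - 1L, nrow(fi), 3, byrow = TRUE))
  t <- fi - i0
  w <- lapply(1:3, function(k) cr_weights(t[, k]))
  g <- map$grid
  out <- numeric(nrow(points))
  clamp <- function(i, k) pmin(pmax(i, 1L), d[k])
  for (a in -1:2) for (b in -1:2) for (cc in -1:2) {
    v <- g[cbind(clamp(i0[, 1] + a, 1),
                 clamp(i0[, 2] + b, 2),
                 clamp(i0[, 3] + cc, 3))]
    out <- out + v * w[[1]][, a + 2] * w[[2]][, b + 2] * w[[3]][, cc + 2]
  }
  out
}
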