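#' @useDynLib vplct, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd cor pt qt
#' @importFrom utils read.delim write.csv packageVersion
NULL

VALID_UNITS <- c("HU", "iodine_HU", "fraction", "percent", "dimensionless", "label")

#' 3D scalar volume with physical geometry
#'
#' The basic image container of the package: a 3D array on a regular grid
#' with voxel spacing (mm), world origin (mm) and a unit tag. World
#' coordinates follow `world = origin + index * spacing` with 0-based
#' indices, axes in RAS+ order.
#'
#' @param data numeric 3D array (nx, ny, nz), each axis of length >= 2.
#' @param spacing numeric length-3, voxel size in mm, strictly positive.
#' @param origin numeric length-3, world position of voxel (0,0,0) in mm.
#' @param unit one of "HU", "iodine_HU", "fraction", "percent",
#'   "dimensionless", "label".
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                          unit = "dimensionless") {
  unit <- match.arg(unit, VALID_UNITS)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 2L))
    stop("each volume axis must have length >= 2", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, origin = origin, unit = unit),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<scalar_volume> %d x %d x %d, spacing (%g, %g, %g) mm, unit %s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$unit))
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("  range [%g, %g], origin (%g, %g, %g) mm\n",
              rng[1], rng[2], x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

is_scalar_volume <- function(x) inherits(x, "scalar_volume")

#' Grid geometry descriptor
#'
#' @param shape integer length-3 grid size.
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param origin numeric length-3 world origin in mm.
#' @return A `grid_geometry` object.
#' @export
grid_geometry <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 2L)) stop("shape must be 3 integers >= 2")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be positive")
  structure(list(shape = shape, spacing = spacing, origin = as.numeric(origin)),
            class = "grid_geometry")
}

#' Extract the grid geometry of a volume or field
#' @param x a `scalar_volume` or `displacement_field`.
#' @return A `grid_geometry`.
#' @export
geometry_of <- function(x) {
  if (is_scalar_volume(x))
    return(grid_geometry(dim(x$data), x$spacing, x$origin))
  if (is_displacement_field(x))
    return(grid_geometry(dim(x$vectors)[1:3], x$spacing, x$origin))
  stop("no geometry for this object")
}

same_grid <- function(a, b, tol = 1e-6) {
  ga <- geometry_of(a); gb <- geometry_of(b)
  all(ga$shape == gb$shape) &&
    all(abs(ga$spacing - gb$spacing) < tol) &&
    all(abs(ga$origin - gb$origin) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(sprintf("geometry mismatch: %s must share one grid", what), call. = FALSE)
  invisible(TRUE)
}

#' Per-voxel displacement field (mm) on a fixed grid
#'
#' Pull-back convention: the field lives on the fixed (expiration) grid and
#' maps fixed world coordinates to moving (inspiration) world coordinates,
#' `phi(x) = x + u(x)`.
#'
#' @param vectors numeric 4D array (nx, ny, nz, 3) of displacements in mm.
#' @param spacing,origin geometry of the fixed grid (mm).
#' @return A `displacement_field` object.
#' @export
displacement_field <- function(vectors, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(vectors) || length(dim(vectors)) != 4L || dim(vectors)[4] != 3L)
    stop("`vectors` must be a 4D array with last dimension 3", call. = FALSE)
  if (any(!is.finite(vectors)))
    stop("displacement field must be finite everywhere", call. = FALSE)
  storage.mode(vectors) <- "double"
  structure(list(vectors = vectors, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "displacement_field")
}

is_displacement_field <- function(x) inherits(x, "displacement_field")

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$vectors)
  mags <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 + x$vectors[, , , 3]^2)
  cat(sprintf("<displacement_field> %d x %d x %d, |u| max %.3f mm, mean %.3f mm\n",
              d[1], d[2], d[3], max(mags), mean(mags)))
  invisible(x)
}

#' Resample a volume onto a target grid
#'
#' Maps each target voxel to world coordinates and samples the source
#' volume there. Linear interpolation for scalar images, nearest neighbour
#' for label maps. Voxels outside the source support are filled with
#' -1024 for HU volumes and 0 otherwise.
#'
#' @param vol a `scalar_volume`.
#' @param target a `grid_geometry` (or object with one, via [geometry_of()]).
#' @param interpolation "linear" or "nearest".
#' @param fill optional override of the out-of-support fill value.
#' @return A `scalar_volume` on the target grid.
#' @export
resample_to_grid <- function(vol, target, interpolation = c("linear", "nearest"),
                             fill = NULL) {
  interpolation <- match.arg(interpolation)
  if (!inherits(target, "grid_geometry")) target <- geometry_of(target)
  if (vol$unit == "label" && interpolation == "linear")
    stop("label maps must be resampled with nearest interpolation", call. = FALSE)
  if (is.null(fill)) fill <- if (vol$unit == "HU") -1024 else 0
  out <- c_resample(as.vector(vol$data), dim(vol$data), vol$spacing, vol$origin,
                    target$shape, target$spacing, target$origin,
                    interpolation == "linear", fill)
  scalar_volume(array(out, target$shape), target$spacing, target$origin, vol$unit)
}

# world coordinates (n x 3 matrix) of all voxels of a geometry
grid_world_coords <- function(geom) {
  idx <- lapply(1:3, function(a) (seq_len(geom$shape[a]) - 1) * geom$spacing[a] + geom$origin[a])
  list(x = idx[[1]], y = idx[[2]], z = idx[[3]])
}

# evaluate f(X, Y, Z) on the full grid without materialising an expand.grid
eval_on_grid <- function(geom, f) {
  co <- grid_world_coords(geom)
  nx <- geom$shape[1]; ny <- geom$shape[2]; nz <- geom$shape[3]
  X <- array(rep(co$x, times = ny * nz), geom$shape)
  Y <- array(rep(rep(co$y, each = nx), times = nz), geom$shape)
  Z <- array(rep(co$z, each = nx * ny), geom$shape)
  f(X, Y, Z)
}
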