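# Minimal NIfTI-1 I/O.
#
# Scope: single-file .nii / .nii.gz, scalar 3D images, 3-component vector
# fields (dim[0] = 5, dim[5] = 3, intent code 1007) and integer label maps.
# Written files carry an axis-aligned sform (RAS+); on read, any affine that
# is a signed permutation of a diagonal matrix is reoriented to RAS+ by axis
# permutation/flip. Oblique acquisitions are rejected rather than silently
# mangled.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

write_nifti_raw <- function(data, spacing, origin, path, datatype, intent_code = 0L) {
  nd <- length(dim(data))
  dims <- rep(1L, 8)
  if (nd == 3L) {
    dims[1] <- 3L
    dims[2:4] <- dim(data)
  } else if (nd == 4L) {   # vector field stored as (nx, ny, nz, 1, ncomp)
    dims[1] <- 5L
    dims[2:4] <- dim(data)[1:3]
    dims[5] <- 1L
    dims[6] <- dim(data)[4]
  } else stop("unsupported array rank for NIfTI export")
  bitpix <- switch(as.character(datatype), `8` = 32L, `16` = 32L, `64` = 64L,
                   stop("unsupported write datatype"))
  con <- tryCatch(nifti_connection(path, "wb"),
                  error = function(e) stop(sprintf("cannot open '%s' for writing", path),
                                           call. = FALSE),
                  warning = function(w) stop(sprintf("cannot open '%s' for writing", path),
                                             call. = FALSE))
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(348L, 4)                              # sizeof_hdr
  writeBin(raw(35), con)                   # data_type, db_name, extents, session_error, regular
  writeBin(as.raw(0L), con)                # dim_info
  wi(dims, 2)                              # dim[8]
  wf(c(0, 0, 0))                           # intent_p1..3
  wi(intent_code, 2)                       # intent_code
  wi(datatype, 2)                          # datatype
  wi(bitpix, 2)                            # bitpix
  wi(0L, 2)                                # slice_start
  wf(c(1, spacing, 1, 1, 1, 1))            # pixdim[8] (qfac = 1)
  wf(352)                                  # vox_offset
  wf(1); wf(0)                             # scl_slope, scl_inter
  wi(0L, 2); writeBin(as.raw(c(0L, 0L)), con)  # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                           # cal_max, cal_min, slice_duration
  wf(0)                                    # toffset
  wi(c(0L, 0L), 4)                         # glmax, glmin
  writeBin(raw(104), con)                  # descrip[80] + aux_file[24]
  wi(0L, 2)                                # qform_code
  wi(1L, 2)                                # sform_code
  wf(c(0, 0, 0))                           # quatern_b, c, d
  wf(origin)                               # qoffset_x, y, z
  wf(c(spacing[1], 0, 0, origin[1]))       # srow_x
  wf(c(0, spacing[2], 0, origin[2]))       # srow_y
  wf(c(0, 0, spacing[3], origin[3]))       # srow_z
  writeBin(raw(16), con)                   # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL); writeBin(as.raw(0L), con)  # magic
  writeBin(raw(4), con)                    # extension flag
  if (datatype == 8L) {
    writeBin(as.integer(round(data)), con, size = 4L, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = if (datatype == 64L) 8L else 4L,
             endian = "little")
  }
  invisible(path)
}

read_nifti_raw <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header", call. = FALSE)
  endian <- "little"
  sz <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr)", call. = FALSE)
  }
  ri <- function(off, n, size) readBin(hdr_raw[(off + 1):(off + n * size)],
                                       "integer", n = n, size = size, endian = endian)
  rf <- function(off, n) readBin(hdr_raw[(off + 1):(off + n * 4L)],
                                 "double", n = n, size = 4L, endian = endian)
  dims <- ri(40L, 8L, 2L)
  intent_code <- ri(68L, 1L, 2L)
  datatype <- ri(70L, 1L, 2L)
  pixdim <- rf(76L, 8L)
  vox_offset <- rf(108L, 1L)
  scl_slope <- rf(112L, 1L)
  scl_inter <- rf(116L, 1L)
  qform_code <- ri(252L, 1L, 2L)
  sform_code <- ri(254L, 1L, 2L)
  quatern <- rf(256L, 3L)
  qoffset <- rf(268L, 3L)
  srow <- rbind(rf(280L, 4L), rf(296L, 4L), rf(312L, 4L))
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop(sprintf("unsupported NIfTI datatype code %d", datatype),
                        call. = FALSE)
  nd <- dims[1]
  shape <- dims[2:(nd + 1)]
  nvox <- prod(shape)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < nvox) stop("truncated NIfTI data section", call. = FALSE)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  # spatial affine (3 x 4), voxel index -> world mm
  if (sform_code > 0L) {
    aff <- srow
  } else if (qform_code > 0L) {
    b <- quatern[1]; c_ <- quatern[2]; d <- quatern[3]
    a2 <- 1 - b * b - c_ * c_ - d * d
    a <- sqrt(max(a2, 0))
    R <- rbind(c(a * a + b * b - c_ * c_ - d * d, 2 * (b * c_ - a * d), 2 * (b * d + a * c_)),
               c(2 * (b * c_ + a * d), a * a + c_ * c_ - b * b - d * d, 2 * (c_ * d - a * b)),
               c(2 * (b * d - a * c_), 2 * (c_ * d + a * b), a * a + d * d - c_ * c_ - b * b))
    qfac <- if (pixdim[1] < 0) -1 else 1
    aff <- cbind(R %*% diag(c(pixdim[2], pixdim[3], pixdim[4] * qfac)), qoffset)
  } else {
    aff <- cbind(diag(pixdim[2:4]), c(0, 0, 0))
  }
  list(shape = shape, values = vals, affine = aff, intent_code = intent_code)
}

# Reorient an axis-aligned (possibly flipped/permuted) volume to RAS+,
# returning data + spacing + origin in world (x, y, z) order.
reorient_to_ras <- function(arr3, aff) {
  A <- aff[, 1:3, drop = FALSE]
  src_axis <- integer(3); sgn <- numeric(3)
  for (r in 1:3) {
    row <- A[r, ]
    a <- which.max(abs(row))
    if (sum(abs(row) > 1e-6 * max(abs(row), 1e-12)) != 1L)
      stop("oblique NIfTI orientation not supported; resample to an axis-aligned grid first",
           call. = FALSE)
    src_axis[r] <- a
    sgn[r] <- if (row[a] < 0) -1 else 1
  }
  if (anyDuplicated(src_axis)) stop("degenerate NIfTI affine", call. = FALSE)
  shape <- dim(arr3)
  flip <- logical(3)
  flip[src_axis] <- sgn < 0
  corner <- ifelse(flip, shape - 1, 0)
  origin_w <- as.vector(A %*% corner + aff[, 4])
  for (a in 1:3) if (flip[a]) {
    idx <- lapply(shape, seq_len)
    idx[[a]] <- rev(idx[[a]])
    arr3 <- do.call(`[`, c(list(arr3), idx, list(drop = FALSE)))
  }
  arr3 <- aperm(arr3, src_axis)
  spacing_w <- vapply(1:3, function(r) abs(A[r, src_axis[r]]), 0)
  list(data = arr3, spacing = spacing_w, origin = origin_w)
}

#' Read a 3D scalar volume from NIfTI
#'
#' Loads a NIfTI-1 image (.nii or .nii.gz), reorients it to RAS+ if the
#' header carries axis flips/permutations, and tags it with `unit`. HU
#' volumes are clipped to the 12-bit CT range \[-1024, 3071\] on load.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param unit unit tag for the result (see [scalar_volume()]).
#' @return A `scalar_volume`.
#' @export
read_volume <- function(path, unit = "HU") {
  unit <- match.arg(unit, VALID_UNITS)
  raw <- read_nifti_raw(path)
  extra <- raw$shape[-(1:3)]
  if (length(raw$shape) < 3L || any(extra != 1L))
    stop(sprintf("expected a 3D image, got dimensions (%s)",
                 paste(raw$shape, collapse = ", ")), call. = FALSE)
  arr <- array(raw$values, raw$shape[1:3])
  if (any(!is.finite(arr)))
    stop("volume contains non-finite voxels", call. = FALSE)
  o <- reorient_to_ras(arr, raw$affine)
  if (unit == "HU") o$data <- pmin(pmax(o$data, -1024), 3071)
  vol <- scalar_volume(o$data, o$spacing, o$origin, unit)
  if (unit == "label") vol$data <- round(vol$data)
  vol
}

#' Write a scalar volume to NIfTI
#'
#' Label volumes are stored as int32, all other units as float32, with an
#' axis-aligned RAS+ sform. Readable back by [read_volume()] with identical
#' data and geometry (within float32 precision).
#'
#' @param vol a `scalar_volume`.
#' @param path output path (.nii or .nii.gz).
#' @return The path, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_scalar_volume(vol))
  datatype <- if (vol$unit == "label") 8L else 16L
  write_nifti_raw(vol$data, vol$spacing, vol$origin, path, datatype)
  invisible(path)
}

#' Read a displacement field from a NIfTI vector image
#'
#' Accepts 5D NIfTI vector images (dim \[5\], 3 components, as written by
#' [write_field()]) or plain 4D images with 3 volumes. Components are in mm,
#' ordered (x, y, z).
#'
#' @param path path to the vector NIfTI file.
#' @return A `displacement_field`.
#' @export
read_field <- function(path) {
  raw <- read_nifti_raw(path)
  sh <- raw$shape
  comp_axis <- length(sh)
  if (!(sh[comp_axis] == 3L && all(sh[-c(1:3, comp_axis)] == 1L)))
    stop("expected a 3-component vector NIfTI image", call. = FALSE)
  arr <- array(raw$values, c(sh[1:3], 3L))
  if (any(!is.finite(arr))) stop("displacement field contains non-finite values",
                                 call. = FALSE)
  A <- raw$affine[, 1:3]
  if (any(abs(A - diag(diag(A))) > 1e-6) || any(diag(A) <= 0))
    stop("displacement-field NIfTI must be RAS+ axis-aligned", call. = FALSE)
  displacement_field(arr, diag(A), raw$affine[, 4])
}

#' Write a displacement field as a 3-component vector NIfTI image
#'
#' @param field a `displacement_field`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(is_displacement_field(field))
  write_nifti_raw(field$vectors, field$spacing, field$origin, path,
                  datatype = 16L, intent_code = 1007L)
  invisible(path)
}
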