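# Lung segmentation and Hounsfield-band classification.
#
# Band semantics (inspiration VNC, half-open intervals):
#   HU <  -950          -> LAA (emphysema / honeycomb air), label 1
#   -950 <= HU < -600   -> NAA (normal attenuation),        label 2
#   -600 <= HU < -250   -> HAA (fibrotic attenuation),      label 3
#   HU >= -250          -> excluded (vessels, consolidation), label 4
# NAA + HAA form the functional lung tissue.

BAND_LABELS <- c(outside = 0L, LAA = 1L, NAA = 2L, HAA = 3L, excluded = 4L)

# shift a logical array by one voxel along an axis
shift1 <- function(m, axis, dir, pad = FALSE) {
  d <- dim(m)
  out <- array(pad, d)
  src <- lapply(d, seq_len)
  dst <- src
  if (dir > 0) { dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1) }
  else { dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

# 6-neighbourhood binary erosion / dilation; erosion pads with TRUE
# (replicate) so a component touching the volume border keeps touching it
erode6 <- function(m) {
  e <- m
  for (ax in 1:3) for (dir in c(-1, 1)) e <- e & shift1(m, ax, dir, pad = TRUE)
  e
}

dilate6 <- function(m) {
  e <- m
  for (ax in 1:3) for (dir in c(-1, 1)) e <- e | shift1(m, ax, dir)
  e
}

#' Segment the lungs on a VNC volume
#'
#' Classical threshold-and-morphology substitute for a learned segmenter:
#' voxels below `threshold_hu` are air candidates; connected components
#' touching the volume border (outside-body air) are removed; the largest
#' one or two remaining components are kept (two lungs may merge through
#' the anterior junction); interior holes (vessels) are filled.
#'
#' @param vnc_insp `scalar_volume` in HU.
#' @param threshold_hu air-candidate threshold, default -320 HU.
#' @param min_fraction minimum lung size as a fraction of the volume below
#'   which segmentation is considered failed.
#' @return logical 3D array (lung mask) with attribute `n_components`.
#' @export
segment_lungs <- function(vnc_insp, threshold_hu = -320, min_fraction = 0.005) {
  stopifnot(is_scalar_volume(vnc_insp))
  d <- dim(vnc_insp$data)
  cand <- vnc_insp$data < threshold_hu
  if (!any(cand))
    stop("lung segmentation failed: no voxels below threshold", call. = FALSE)
  # open first: partial-volume shells can form thin bridges between lung
  # air and outside-body air; deepen the opening until the lungs separate
  # from the border component (up to 3 voxels)
  interior <- integer(0)
  core <- cand
  depth <- 0L
  while (depth < 3L && length(interior) == 0L) {
    depth <- depth + 1L
    core <- erode6(core)
    if (!any(core)) break
    lab <- array(c_cc3d(as.vector(core), d), d)
    border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
    border <- border[border != 0L]
    counts <- tabulate(lab[lab != 0L])
    interior <- setdiff(seq_along(counts)[counts > 0], border)
    interior <- interior[counts[interior] >= max(8, 0.2 * min_fraction * prod(d))]
  }
  if (length(interior) == 0L)
    stop("lung segmentation failed: no interior air component", call. = FALSE)
  keep <- interior[order(counts[interior], decreasing = TRUE)]
  keep <- keep[seq_len(min(2L, length(keep)))]
  # drop a second component that is tiny relative to the first (noise blobs)
  if (length(keep) == 2L && counts[keep[2]] < 0.05 * counts[keep[1]])
    keep <- keep[1]
  mask <- array(lab %in% keep, d)
  # conditional dilation restores the eroded rim without re-crossing the
  # threshold boundary
  for (pass in seq_len(depth + 1L)) mask <- dilate6(mask) & cand
  if (sum(mask) < min_fraction * prod(d))
    stop("lung segmentation failed: candidate component too small", call. = FALSE)
  # hole filling: complement components not touching the border are interior
  # structures (vessels) and belong to the lung
  clab <- array(c_cc3d(as.vector(!mask), d), d)
  cborder <- unique(c(clab[c(1, d[1]), , ], clab[, c(1, d[2]), ], clab[, , c(1, d[3])]))
  cborder <- cborder[cborder != 0L]
  holes <- !(clab %in% c(0L, cborder))
  mask <- mask | array(holes, d)
  attr(mask, "n_components") <- length(keep)
  mask
}

#' Classify lung voxels into attenuation bands
#'
#' @param vnc_insp `scalar_volume` in HU.
#' @param lung_mask logical array on the same grid.
#' @param edges band edges in HU, default c(-950, -600, -250); intervals are
#'   half-open `[lo, hi)` so -600 HU falls in HAA.
#' @return A `band_label_map`: integer array with labels 0 outside, 1 LAA,
#'   2 NAA, 3 HAA, 4 excluded, plus geometry and edge attributes.
#' @export
classify_bands <- function(vnc_insp, lung_mask, edges = c(-950, -600, -250)) {
  stopifnot(is_scalar_volume(vnc_insp))
  if (!all(dim(lung_mask) == dim(vnc_insp$data)))
    stop("geometry mismatch between mask and volume", call. = FALSE)
  if (is.unsorted(edges, strictly = TRUE)) stop("band edges must be increasing")
  hu <- vnc_insp$data
  lab <- array(0L, dim(hu))
  inl <- which(lung_mask)
  h <- hu[inl]
  v <- integer(length(inl))
  v[h < edges[1]] <- BAND_LABELS[["LAA"]]
  v[h >= edges[1] & h < edges[2]] <- BAND_LABELS[["NAA"]]
  v[h >= edges[2] & h < edges[3]] <- BAND_LABELS[["HAA"]]
  v[h >= edges[3]] <- BAND_LABELS[["excluded"]]
  lab[inl] <- v
  structure(lab, class = "band_label_map",
            spacing = vnc_insp$spacing, origin = vnc_insp$origin, edges = edges)
}

#' Fraction of the lung that is functional tissue
#'
#' Functional tissue = NAA + HAA voxels over all lung voxels.
#'
#' @param bands a `band_label_map` from [classify_bands()].
#' @return scalar fraction in \[0, 1\].
#' @export
functional_fraction <- function(bands) {
  n_lung <- sum(bands != BAND_LABELS[["outside"]])
  if (n_lung == 0L) stop("empty lung mask", call. = FALSE)
  sum(bands == BAND_LABELS[["NAA"]] | bands == BAND_LABELS[["HAA"]]) / n_lung
}

#' Logical mask for a named band region
#' @param bands a `band_label_map`.
#' @param region one of "functional", "NAA", "HAA", "LAA", "lung".
#' @return logical array.
#' @export
band_region_mask <- function(bands, region = c("functional", "NAA", "HAA", "LAA", "lung")) {
  region <- match.arg(region)
  switch(region,
         functional = bands == BAND_LABELS[["NAA"]] | bands == BAND_LABELS[["HAA"]],
         NAA = bands == BAND_LABELS[["NAA"]],
         HAA = bands == BAND_LABELS[["HAA"]],
         LAA = bands == BAND_LABELS[["LAA"]],
         lung = bands != BAND_LABELS[["outside"]])
}

#' Convert a band label map to a label `scalar_volume` for export
#' @param bands a `band_label_map`.
#' @return `scalar_volume` with unit "label".
#' @export
bands_as_volume <- function(bands) {
  scalar_volume(array(as.numeric(bands), dim(bands)),
                attr(bands, "spacing"), attr(bands, "origin"), "label")
}
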