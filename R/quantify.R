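# Per-patient scalar summaries: band-wise functional means, lung volume,
# mean lung density, histograms.

#' Mean of a functional map over a band region
#'
#' Arithmetic mean over valid (non-NA) voxels of the requested region;
#' masked voxels are excluded from numerator and denominator alike.
#'
#' @param map `scalar_volume`.
#' @param bands `band_label_map` on the same grid.
#' @param region "functional", "NAA" or "HAA".
#' @return scalar mean; attribute `n_valid` carries the voxel count.
#' @export
region_mean <- function(map, bands, region = c("functional", "NAA", "HAA")) {
  region <- match.arg(region)
  if (!all(dim(bands) == dim(map$data)))
    stop("geometry mismatch between map and band label map", call. = FALSE)
  m <- band_region_mask(bands, region)
  if (!any(m)) stop(sprintf("empty region '%s'", region), call. = FALSE)
  v <- map$data[m]
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop(sprintf("region '%s' has no valid voxels", region),
                            call. = FALSE)
  structure(mean(v), n_valid = length(v))
}

#' Lung volume (mL) and mean lung density (HU) from a segmentation mask
#'
#' @param vnc_insp `scalar_volume` in HU.
#' @param lung_mask logical array on the same grid.
#' @return list with `volume_mL` (voxel count x voxel volume / 1000) and
#'   `mean_HU`.
#' @export
lung_volume_and_density <- function(vnc_insp, lung_mask) {
  if (!all(dim(lung_mask) == dim(vnc_insp$data)))
    stop("geometry mismatch between mask and volume", call. = FALSE)
  n <- sum(lung_mask)
  if (n == 0L) stop("empty lung mask", call. = FALSE)
  voxel_mm3 <- prod(vnc_insp$spacing)
  list(volume_mL = n * voxel_mm3 / 1000,
       mean_HU = mean(vnc_insp$data[lung_mask]))
}

#' Histogram of a functional map over a region
#'
#' Counts valid region voxels into bins given by `edges`; values below the
#' first or above the last edge are accumulated into the end bins, so the
#' counts always sum to the number of valid voxels.
#'
#' @param map `scalar_volume`.
#' @param region_mask logical array on the same grid.
#' @param edges increasing numeric bin edges (>= 2 values).
#' @return integer counts of length `length(edges) - 1` with attribute
#'   `edges`.
#' @export
map_histogram <- function(map, region_mask, edges) {
  if (length(edges) < 2L || is.unsorted(edges, strictly = TRUE))
    stop("`edges` must be >= 2 strictly increasing values", call. = FALSE)
  if (!all(dim(region_mask) == dim(map$data)))
    stop("geometry mismatch between map and region mask", call. = FALSE)
  v <- map$data[region_mask]
  v <- v[is.finite(v)]
  v <- pmin(pmax(v, edges[1]), edges[length(edges)])
  counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  structure(counts, edges = edges)
}

default_histogram_edges <- function(parameter = c("ventilation", "perfusion",
                                                  "late_enhancement")) {
  parameter <- match.arg(parameter)
  switch(parameter,
         ventilation = seq(0, 1.2, length.out = 51),
         perfusion = seq(0, 30, length.out = 51),
         late_enhancement = seq(0, 130, length.out = 51))
}

#' Per-patient summary of functional maps
#'
#' Region means (functional / NAA / HAA) of ventilation, perfusion (warped)
#' and late enhancement, lung volume and mean density, functional fraction,
#' and default histograms.
#'
#' @param maps list from [build_functional_maps()].
#' @param bands `band_label_map` on the expiration-frame analysis grid.
#' @param vnc_insp inspiration VNC for volume/density (its own grid).
#' @param lung_mask_insp inspiration lung mask for volume/density.
#' @return nested list (a `patient_summary`).
#' @export
patient_summary <- function(maps, bands, vnc_insp, lung_mask_insp) {
  params <- list(ventilation = maps$ventilation,
                 perfusion = maps$perfusion_warped,
                 late_enhancement = maps$late_enhancement)
  means <- lapply(params, function(p)
    list(functional = as.numeric(region_mean(p, bands, "functional")),
         NAA = as.numeric(region_mean(p, bands, "NAA")),
         HAA = as.numeric(region_mean(p, bands, "HAA"))))
  vd <- lung_volume_and_density(vnc_insp, lung_mask_insp)
  fmask <- band_region_mask(bands, "functional")
  hists <- lapply(names(params), function(nm)
    as.integer(map_histogram(params[[nm]], fmask, default_histogram_edges(nm))))
  names(hists) <- names(params)
  structure(list(
    mean_ventilation = means$ventilation,
    mean_perfusion = means$perfusion,
    mean_late_enhancement = means$late_enhancement,
    lung_volume_mL = vd$volume_mL,
    mean_lung_density_HU = vd$mean_HU,
    functional_fraction = functional_fraction(bands),
    histograms = hists,
    qc = maps$qc
  ), class = "patient_summary")
}
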