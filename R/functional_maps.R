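# Voxel-wise functional parameters: regional ventilation, perfusion and
# late enhancement.
#
# Ventilation model: with S the inverse Jacobian (shrinkage) and alpha the
# per-voxel air content (fraction of the voxel occupied by air),
#     RV = 1 - S * alpha_exp / alpha_insp_warped
# i.e. one minus the ratio of expiration to inspiration air volume of the
# same tissue parcel, normalized to inspiration: 0 = no volume change,
# 1 = total expiratory collapse. The air-content reading of "lung density"
# is what reproduces those endpoints; a mass-conserved tissue density would
# cancel S identically (see the methods vignette).

#' Air-content map from a VNC volume
#'
#' Linear HU-to-air-fraction map `alpha = clamp(-HU / 1000, 0, 1)`:
#' -1000 HU (pure air) maps to 1, 0 HU (water/tissue) to 0.
#'
#' @param vnc `scalar_volume` in HU.
#' @return `scalar_volume` with unit "fraction".
#' @export
air_content <- function(vnc) {
  stopifnot(is_scalar_volume(vnc))
  g <- geometry_of(vnc)
  scalar_volume(array(pmin(pmax(-vnc$data / 1000, 0), 1), g$shape),
                g$spacing, g$origin, "fraction")
}

#' Regional ventilation from inverse Jacobian and air-content maps
#'
#' `RV = 1 - S * alpha_exp / alpha_insp_warped`, computed on the expiration
#' grid. Voxels with near-zero inspiration air content
#' (`alpha_insp_warped < epsilon`) or invalid S are masked (NA), not
#' clamped; the result itself is also not clamped to \[0, 1\], and the
#' fraction of valid voxels falling outside \[0, 1\] is reported.
#'
#' @param inv_jac `scalar_volume` of inverse Jacobian values (NA = invalid).
#' @param air_exp,air_insp_warped air-content `scalar_volume`s on the same
#'   grid (the inspiration map already warped to the expiration frame).
#' @param epsilon mask threshold for the inspiration air content.
#' @return `scalar_volume` (fraction) with attributes `fraction_masked` and
#'   `fraction_outside_01`.
#' @export
regional_ventilation <- function(inv_jac, air_exp, air_insp_warped,
                                 epsilon = 0.01) {
  stop_if_grid_mismatch(inv_jac, air_exp, "inverse Jacobian and expiration air map")
  stop_if_grid_mismatch(inv_jac, air_insp_warped,
                        "inverse Jacobian and warped inspiration air map")
  S <- inv_jac$data
  ai <- air_insp_warped$data
  rv <- 1 - S * air_exp$data / ai
  invalid <- !is.finite(S) | ai < epsilon
  rv[invalid] <- NA_real_
  g <- geometry_of(inv_jac)
  out <- scalar_volume(array(rv, g$shape), g$spacing, g$origin, "fraction")
  valid <- !invalid
  attr(out, "fraction_masked") <- mean(invalid)
  attr(out, "fraction_outside_01") <-
    if (any(valid)) mean(rv[valid] < 0 | rv[valid] > 1) else NA_real_
  out
}

#' Normalize an iodine map to the vascular reference
#'
#' Reference = unweighted mean of the two per-ROI mean iodine values
#' (pulmonary artery trunk, label 1; ascending aorta, label 2), taken from
#' the same phase's PBV. Output is percent of the vascular contrast; values
#' above 100% are preserved unclipped.
#'
#' @param pbv `scalar_volume` (iodine_HU).
#' @param roi vessel ROI: `scalar_volume` with unit "label" (0 background,
#'   1 PA trunk, 2 ascending aorta) on the same grid.
#' @return `scalar_volume` (percent) with attribute `vascular_reference`.
#' @export
normalize_to_vascular <- function(pbv, roi) {
  stop_if_grid_mismatch(pbv, roi, "PBV and vessel ROI")
  lab <- round(roi$data)
  m_pa <- lab == 1
  m_ao <- lab == 2
  if (!any(m_pa) || !any(m_ao))
    stop("vessel ROI must contain both labels 1 (PA trunk) and 2 (aorta)",
         call. = FALSE)
  ref <- (mean(pbv$data[m_pa]) + mean(pbv$data[m_ao])) / 2
  if (!is.finite(ref) || ref <= 0)
    stop("vascular reference is non-positive; cannot normalize", call. = FALSE)
  g <- geometry_of(pbv)
  out <- scalar_volume(array(100 * pbv$data / ref, g$shape),
                       g$spacing, g$origin, "percent")
  attr(out, "vascular_reference") <- ref
  out
}

#' Build all three functional maps from decomposed phases and a field
#'
#' Orchestrates the per-patient map computation: warps the inspiration VNC
#' into the expiration frame, derives air-content maps, computes the
#' inverse Jacobian and regional ventilation, and normalizes the arterial
#' inspiration PBV (perfusion) and the delayed expiration PBV (late
#' enhancement) to their same-phase vascular references. Everything is
#' returned on the expiration grid except `perfusion`, which is native to
#' the inspiration grid and also provided warped.
#'
#' @param vnc_insp,vnc_exp VNC `scalar_volume`s (HU).
#' @param pbv_insp,pbv_delayed iodine `scalar_volume`s (arterial inspiration
#'   and delayed expiration phases).
#' @param field `displacement_field` on the expiration grid.
#' @param roi_insp,roi_exp vessel ROI label volumes in each frame.
#' @param epsilon ventilation mask threshold (see [regional_ventilation()]).
#' @return list with `ventilation`, `perfusion`, `perfusion_warped`,
#'   `late_enhancement`, `vnc_insp_warped`, `inv_jacobian`, and `qc`.
#' @export
build_functional_maps <- function(vnc_insp, vnc_exp, pbv_insp, pbv_delayed,
                                  field, roi_insp, roi_exp, epsilon = 0.01) {
  stop_if_grid_mismatch(vnc_exp, field, "expiration VNC and field")
  vnc_insp_warped <- warp(vnc_insp, field, "linear")
  a_exp <- air_content(vnc_exp)
  a_insp_w <- air_content(vnc_insp_warped)
  S <- inverse_jacobian(field)
  rv <- regional_ventilation(S, a_exp, a_insp_w, epsilon)
  perf <- normalize_to_vascular(pbv_insp, roi_insp)
  perf_w <- warp(perf, field, "linear")
  le <- normalize_to_vascular(pbv_delayed, roi_exp)
  list(
    ventilation = rv,
    perfusion = perf,
    perfusion_warped = perf_w,
    late_enhancement = le,
    vnc_insp_warped = vnc_insp_warped,
    inv_jacobian = S,
    qc = list(
      fraction_masked = attr(rv, "fraction_masked"),
      fraction_outside_01 = attr(rv, "fraction_outside_01"),
      n_nonpositive_jacobian = attr(S, "n_nonpositive"),
      vascular_reference_arterial = attr(perf, "vascular_reference"),
      vascular_reference_delayed = attr(le, "vascular_reference")
    )
  )
}
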