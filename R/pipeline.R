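# Per-patient and cohort pipelines plus run configuration / manifests.

#' Default run configuration
#'
#' A single keyed document of every tunable stage parameter, serialized
#' into each output manifest so runs are reproducible.
#'
#' @param ... overrides of the defaults.
#' @return named list (a `vplct_config`).
#' @export
vplct_config <- function(...) {
  cfg <- list(
    basis_tissue = c(1, 1),
    basis_iodine = c(2, 1),
    band_edges = c(-950, -600, -250),
    segmentation_threshold_hu = -320,
    epsilon_air = 0.01,
    registration_levels = c(4L, 2L, 1L),
    registration_iters = c(10L, 10L, 10L),
    registration_smoothing_mm = 10.0,
    registration_update_smoothing_mm = 8.0,
    registration_max_step_mm = 0.5,
    registration_highpass_mm = 15.0,
    qc_exclude_threshold_mm = 2.0,
    histogram_bins = 50L,
    year_days = 365.25,
    p_adjust = "none",
    seed = 1L
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
    cfg[names(overrides)] <- overrides
  }
  structure(cfg, class = "vplct_config")
}

config_basis <- function(config) {
  decomposition_basis(config$basis_tissue, config$basis_iodine)
}

write_manifest <- function(dir, config, inputs = list(), extra = list()) {
  man <- c(list(
    package = "vplct",
    version = as.character(packageVersion("vplct")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    inputs = inputs
  ), extra)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  invisible(man)
}

#' Run the complete per-patient map pipeline
#'
#' From the four kV volumes (or a precomputed VNC/PBV set): material
#' decomposition, lung segmentation, band classification, deformable
#' registration (or an externally supplied field), functional-map
#' computation, and quantification. Produces the five aligned datasets of
#' one study — expiration VNC, warped inspiration VNC, ventilation, warped
#' perfusion and late enhancement — plus the band map and a summary.
#'
#' @param inputs list with either `insp_low`, `insp_high`, `exp_low`,
#'   `exp_high` (HU `scalar_volume`s) or `vnc_insp`, `vnc_exp`, `pbv_insp`,
#'   `pbv_delayed`; plus `roi_insp` and `roi_exp` label volumes, and
#'   optionally `field` (a `displacement_field`) and `landmarks`.
#' @param config a [vplct_config()].
#' @param out_dir optional directory; when given, all maps and a manifest
#'   are written as NIfTI/JSON.
#' @return list with `summary` (a `patient_summary`), `maps`, `bands`,
#'   `lung_mask_insp`, `field`, `qc`, and `excluded` (TRUE when landmark QC
#'   exceeded the threshold).
#' @export
run_patient_pipeline <- function(inputs, config = vplct_config(), out_dir = NULL) {
  need_any <- function(nms) {
    miss <- nms[!nms %in% names(inputs)]
    if (length(miss))
      stop("missing pipeline input(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  if (all(c("insp_low", "insp_high", "exp_low", "exp_high") %in% names(inputs))) {
    basis <- config_basis(config)
    dec <- pbv_pair(list(low = inputs$insp_low, high = inputs$insp_high),
                    list(low = inputs$exp_low, high = inputs$exp_high), basis)
  } else {
    need_any(c("vnc_insp", "vnc_exp", "pbv_insp", "pbv_delayed"))
    dec <- inputs[c("pbv_insp", "pbv_delayed", "vnc_insp", "vnc_exp")]
  }
  need_any(c("roi_insp", "roi_exp"))
  lung_insp <- segment_lungs(dec$vnc_insp, config$segmentation_threshold_hu)
  field <- inputs$field
  if (is.null(field))
    field <- register(dec$vnc_exp, dec$vnc_insp,
                      levels = config$registration_levels,
                      iters = config$registration_iters,
                      smoothing = config$registration_smoothing_mm,
                      update_smoothing = config$registration_update_smoothing_mm,
                      max_step = config$registration_max_step_mm,
                      highpass_sigma = config$registration_highpass_mm,
                      seed = config$seed)
  maps <- build_functional_maps(dec$vnc_insp, dec$vnc_exp, dec$pbv_insp,
                                dec$pbv_delayed, field,
                                inputs$roi_insp, inputs$roi_exp,
                                epsilon = config$epsilon_air)
  # functional tissue is defined on the inspiration scan; the analysis grid
  # is the expiration frame, so classify the warped inspiration VNC
  lung_exp_frame <- segment_lungs(maps$vnc_insp_warped,
                                  config$segmentation_threshold_hu)
  bands <- classify_bands(maps$vnc_insp_warped, lung_exp_frame,
                          config$band_edges)
  summary <- patient_summary(maps, bands, dec$vnc_insp, lung_insp)
  excluded <- FALSE
  qc_landmarks <- NULL
  if (!is.null(inputs$landmarks)) {
    qc_landmarks <- registration_qc(field, inputs$landmarks,
                                    config$qc_exclude_threshold_mm)
    excluded <- qc_landmarks$exclude
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(dec$vnc_exp, file.path(out_dir, "vnc_exp.nii.gz"))
    write_volume(maps$vnc_insp_warped, file.path(out_dir, "vnc_insp_warped.nii.gz"))
    rv_out <- maps$ventilation
    rv_out$data[!is.finite(rv_out$data)] <- 0   # masked voxels; counts in QC
    write_volume(rv_out, file.path(out_dir, "ventilation.nii.gz"))
    write_volume(maps$perfusion_warped, file.path(out_dir, "perfusion_warped.nii.gz"))
    write_volume(maps$late_enhancement, file.path(out_dir, "late_enhancement.nii.gz"))
    write_volume(bands_as_volume(bands), file.path(out_dir, "bands.nii.gz"))
    write_field(field, file.path(out_dir, "field.nii.gz"))
    sm <- unclass(summary)
    sm$excluded <- excluded
    if (!is.null(qc_landmarks))
      sm$landmark_qc <- qc_landmarks[c("mean_error_mm", "max_error_mm", "exclude")]
    jsonlite::write_json(sm, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    write_manifest(out_dir, config, extra = list(excluded = excluded))
  }
  list(summary = summary, maps = maps, bands = bands,
       lung_mask_insp = lung_insp, field = field,
       qc = c(maps$qc, list(landmarks = qc_landmarks)), excluded = excluded)
}

#' Run the cohort statistics pipeline
#'
#' Reads (or accepts) a cohort table, computes the correlation matrix of
#' baseline functional means against baseline references and annualized
#' follow-up/baseline ratios, and the NAA-vs-HAA paired tests.
#'
#' @param cohort data.frame or path to a cohort TSV.
#' @param config a [vplct_config()].
#' @param out_dir optional output directory for JSON/CSV reports.
#' @return list with `correlations` (data.frame), `paired_tests` (list per
#'   functional parameter), `n_patients`.
#' @export
run_cohort_pipeline <- function(cohort, config = vplct_config(), out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (nrow(cohort) == 0L) stop("cohort table is empty", call. = FALSE)
  tab <- correlation_table(cohort, year_days = config$year_days,
                           p_adjust = config$p_adjust)
  tests <- list()
  for (fp in COHORT_FUNCTIONALS) {
    naa <- cohort[[paste0(fp, "_naa")]]
    haa <- cohort[[paste0(fp, "_haa")]]
    tests[[fp]] <- if (!is.null(naa) && !is.null(haa))
      tryCatch(paired_t(haa, naa), error = function(e) list(error = conditionMessage(e)))
    else NULL
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(correlations = tab, paired_tests = tests),
                         file.path(out_dir, "cohort_report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    write.csv(tab, file.path(out_dir, "correlations.csv"), row.names = FALSE)
    write_manifest(out_dir, config, extra = list(n_patients = nrow(cohort)))
  }
  list(correlations = tab, paired_tests = tests, n_patients = nrow(cohort))
}
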