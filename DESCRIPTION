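Package: vplct
Title: Ventilation-Perfusion-Late-Enhancement CT Processing for Fibrotic Lung Disease
Version: 0.1.0
Authors@R: person("VPL-CT", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Processing pipeline for paired inspiration/expiration dual-energy
    chest CT in fibrotic lung disease. Performs two-material decomposition of
    low/high-kV pairs into virtual non-contrast (VNC) and iodine (PBV) volumes,
    deformable registration of inspiration to expiration, computation of
    regional ventilation from the inverse Jacobian determinant of the
    deformation field together with air-content maps, vascular-normalized
    perfusion and late-enhancement maps, Hounsfield-band densitometry
    (LAA/NAA/HAA), per-patient quantification, and longitudinal cohort
    correlation statistics. Includes a synthetic digital thorax phantom with
    closed-form ground truth (deformation, Jacobian, ventilation, iodine
    fields) so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
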