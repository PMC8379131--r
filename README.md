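# vplct

Regional lung function from paired inspiration/expiration dual-energy CT,
for quantitative imaging research in fibrotic lung disease (IPF).

A contrast-enhanced dual-energy CT in full inspiration plus a
5-minute-delayed scan in maximum expiration can be processed into three
voxel-wise functional maps:

* **Regional ventilation** — fractional air-volume change between the two
  breathing phases, normalized to inspiration:
  `RV = 1 − S · α_exp / α_insp-warped`, where
  `S = 1 / det(I + ∇u)` is the inverse Jacobian (shrinkage) of the
  deformable registration field `u` and `α = clamp(−HU/1000, 0, 1)` is the
  air content of a virtual non-contrast (VNC) voxel. RV ranges from 0 (no
  volume change) to 1 (total expiratory collapse); healthy lungs average
  0.40–0.50.
* **Lung perfusion** — arterial-phase iodine (PBV) per voxel, as a
  percentage of the mean intravascular contrast (pulmonary artery trunk +
  ascending aorta).
* **Late enhancement** — delayed-phase iodine retention, same
  normalization; values above 100% occur in fibrosis and are preserved.

Quantification uses Hounsfield bands on the inspiration VNC: LAA
(< −950 HU), NAA ([−950, −600) HU), HAA ([−600, −250) HU), with ≥ −250 HU
excluded (vessels); NAA + HAA form the *functional lung tissue*. Cohort
statistics correlate baseline functional means with reference values
(FVC%, DLCO%, CT lung volume, mean lung density) at baseline and with
their follow-up/baseline ratios annualized to one year.

Because no patient data are deposited, the package includes a synthetic
digital thorax phantom with closed-form ground truth (deformation,
Jacobian, ventilation, iodine fields, masks) against which every stage is
validated — see `vignettes/vplct-methods.Rmd` for the model, its
assumptions, and what a green phantom test does and does not establish.

## Worked example

```r
library(vplct)

# a fibrotic-lung phantom: paired low/high-kV volumes in both phases,
# plus exact ground truth
ph  <- generate_phantom(phantom_spec(seed = 1))
dec <- pbv_pair(list(low = ph$insp_low_kv, high = ph$insp_high_kv),
                list(low = ph$exp_low_kv,  high = ph$exp_high_kv),
                ph$spec$basis)

# deformable registration (inspiration -> expiration), functional maps
field <- register(dec$vnc_exp, dec$vnc_insp)
maps  <- build_functional_maps(dec$vnc_insp, dec$vnc_exp, dec$pbv_insp,
                               dec$pbv_delayed, field,
                               ph$truth$vessel_roi_insp,
                               ph$truth$vessel_roi_exp)

# band classification on the warped inspiration VNC and per-patient summary
lungs <- segment_lungs(maps$vnc_insp_warped)
bands <- classify_bands(maps$vnc_insp_warped, lungs)
sm    <- patient_summary(maps, bands, dec$vnc_insp,
                         segment_lungs(dec$vnc_insp))

round(c(vent_functional = sm$mean_ventilation$functional,
        vent_NAA = sm$mean_ventilation$NAA,
        vent_HAA = sm$mean_ventilation$HAA,
        perfusion_pct = sm$mean_perfusion$functional,
        late_enh_pct = sm$mean_late_enhancement$functional,
        functional_fraction = sm$functional_fraction), 3)
#>     vent_functional            vent_NAA            vent_HAA
#>               0.448               0.438               0.513
#>       perfusion_pct        late_enh_pct functional_fraction
#>               9.547              43.308               1.000
```

Mean ventilation ~0.45 (this phantom breathes moderately; IPF cohorts
average higher with deeper inspiration-expiration excursions); all three
functional parameters are higher in HAA (fibrotic) than NAA (normal)
tissue, the ordering seen clinically; perfusion ~9.5% and late
enhancement ~43% of vascular contrast follow the phantom's iodine model.
Against the phantom's exact truth, the ventilation map's mean absolute
error is 0.028 with the package's own registration and ~0.010 with the
exact field.

Cohort analysis:

```r
co  <- generate_cohort(n_patients = 32, planted_r = -0.5, seed = 1)
tab <- correlation_table(co)
subset(tab, parameter == "ventilation" & reference == "lung_volume_ml")
#>     parameter      reference    timepoint      R        p  n available sig_05 sig_01
#> ventilation lung_volume_ml     baseline  0.271 0.133962 32      TRUE  FALSE  FALSE
#> ventilation lung_volume_ml annual_ratio -0.584 0.000446 32      TRUE   TRUE   TRUE
```

The planted relation (baseline ventilation vs annualized lung-volume
decline, population R = −0.5) is recovered at this cohort size
(sample R = −0.58, p < 0.001); the baseline column is independent by
construction (sample R = 0.27, n.s.).

## Command line

```sh
vplct phantom  --out phantom/ --seed 1
vplct decompose --low insp_low.nii.gz --high insp_high.nii.gz \
                --out-vnc vnc.nii.gz --out-pbv pbv.nii.gz
vplct mask     --vnc vnc.nii.gz --out bands.nii.gz
vplct register --fixed vnc_exp.nii.gz --moving vnc_insp.nii.gz --out field.nii.gz
vplct jacobian --field field.nii.gz --out invjac.nii.gz
vplct run-all  --insp-low ... --insp-high ... --exp-low ... --exp-high ... \
               --roi-insp ... --roi-exp ... --out-dir out/ [--landmarks lm.tsv]
vplct cohort   --cohort cohort.tsv --out-dir report/
```

(the `vplct` script is installed under `inst/cli/`; call it as
`Rscript $(Rscript -e 'cat(system.file("cli/vplct", package="vplct"))') ...`
or add it to PATH). Exit codes: 0 success, 2 usage error, 3 data error,
4 registration-QC exclusion (landmark misalignment strictly above 2 mm;
maps are still written, flagged `excluded`).

Cohort TSV contract: one row per patient, tab-separated, header row,
empty cells = missing. Columns: `patient_id`, `interval_days`,
`ventilation_baseline`, `ventilation_naa`, `ventilation_haa`,
`perfusion_baseline`, `perfusion_naa`, `perfusion_haa`,
`late_enhancement_baseline`, `late_enhancement_naa`,
`late_enhancement_haa`, and for each reference in `fvc_pct`, `dlco_pct`,
`lung_volume_ml`, `lung_density_hu` a `_baseline` and `_followup` column.

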