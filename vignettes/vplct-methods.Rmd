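---
title: "Methods: regional lung function from paired dual-energy CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional lung function from paired dual-energy CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Idiopathic pulmonary fibrosis progresses heterogeneously, and established
markers (FVC%, DLCO%, CT lung volume, mean lung density) change late.
A contrast-enhanced dual-energy CT protocol with an inspiration scan and a
5-minute-delayed expiration scan can be processed into three voxel-wise
functional maps — regional ventilation, lung perfusion, and late
enhancement — whose baseline means may precede structural progression.
`vplct` implements that processing chain end to end, and because no patient
data are deposited anywhere, it ships a synthetic digital thorax phantom
with closed-form ground truth against which every stage is validated.

## Models and procedures

### Two-material decomposition

Air-referenced enhancements are modelled as linear in two materials,

$$\begin{pmatrix} \mathrm{low} + 1000 \\ \mathrm{high} + 1000 \end{pmatrix}
 = B \begin{pmatrix} \mathrm{tissue} \\ \mathrm{iodine} \end{pmatrix},$$

with a configurable $2\times2$ basis $B$ (default: energy-independent
water-equivalent tissue, iodine responding twice as strongly at low kV).
Vendor coefficients are proprietary and unpublished, so VNC/PBV values are
defined only up to the declared basis; this is harmless because every
quantity the pipeline reports — ventilation (VNC-ratio based) and
perfusion/late enhancement (vessel-normalized percentages) — is invariant
to the basis, which the test suite verifies explicitly. Negative iodine
solutions (noise) are clipped to zero with the clipped fraction logged;
the voxel is refit as tissue-only at the low-kV reference energy.

### Regional ventilation and the density-ratio question

The ventilation model is

$$\mathrm{RV}(x) = 1 - S(x)\,
  \frac{\alpha_\mathrm{exp}(x)}{\alpha_\mathrm{insp\,warped}(x)},$$

where $S = 1/\det(I + \nabla u)$ is the inverse Jacobian (shrinkage) of the
expiration-to-inspiration displacement field $u$ and
$\alpha = \mathrm{clamp}(-\mathrm{HU}/1000, 0, 1)$ is the per-voxel air
content of a VNC image. A mass-conserved *tissue* density in that ratio
would cancel $S$ identically and make the formula constant zero; only the
air-content reading reproduces the intended endpoints — 0 for no volume
change, 1 for total expiratory collapse — and the "specific air volume
change" interpretation. The package therefore computes the ratio on
air-content maps. This is a modelling decision of this package, documented
here because the literature formulation is ambiguous on the meaning of
"lung density".

Voxels with near-airless warped inspiration ($\alpha < \varepsilon$,
default $\varepsilon = 0.01$) or folded Jacobians are masked (NA), never
clamped, and excluded from all means and histograms with their counts
reported. RV itself is not clamped: values above 0.75, and above 1 under
noise, are diagnostic information, not errors.

### Perfusion and late enhancement

Arterial-phase inspiration PBV is the perfusion surrogate; delayed-phase
expiration PBV carries late enhancement (slow contrast washout through a
leaky alveolar-capillary barrier and expanded interstitium). Both are
normalized to the same phase's vascular reference: the unweighted mean of
the two per-ROI means (pulmonary artery trunk, ascending aorta). The
mean-of-means is used rather than a pooled-voxel mean because it is
insensitive to ROI size imbalance. Outputs are percentages; values above
100% are preserved.

### Registration

The inspiration VNC is registered to the expiration VNC (pull-back
convention: the field lives on the expiration grid and maps into
inspiration space, so $S$ is directly the shrinkage the ventilation formula
needs). The built-in algorithm is deterministic and has three stages:

1. **Moments initialization.** Interior-air masks (threshold, one-voxel
   opening, border-component removal) give per-axis centroids and spreads;
   their ratios initialize a diagonal affine. This bridges the large global
   volume change (tens of mm) that demons alone cannot.
2. **Affine refinement.** Nelder-Mead on the mean squared difference of
   high-pass-filtered images at a shrink-2 grid refines the three scales
   and translations.
3. **Demons residual.** A Thirion-style update with per-iteration Gaussian
   smoothing of update and residual field, on a 4/2/1 pyramid. The affine
   part is frozen; only the residual is smoothed, so regularization cannot
   erode the global contraction. Smoothing sigmas and the step cap are
   constant in voxels across pyramid levels (specified in mm at the finest
   level).

Registration forces act on high-pass-filtered intensities
(`highpass_sigma`, default 15 mm). This is essential, not cosmetic: lung
density is *not* conserved between respiratory phases — parenchyma
densifies as it deflates — and the resulting smooth intensity offset,
combined with weak interior gradients, otherwise drags a
sum-of-squared-difference force model many millimetres along the density
slope while the image mismatch happily decreases. High-pass filtering
removes the offset and leaves edges (lung boundary, vessels, fibrotic
rims) to drive alignment. The residual limitation is the mirror image:
genuinely low-frequency deformation components in texture-poor parenchyma
are only partially recoverable (observed ~1.4 mm mean field error on
phantoms against a 2.1 mm best-affine floor). External fields (e.g. from
ANTs/SyN) can be imported as NIfTI vector volumes instead.

Fields with non-positive Jacobian determinants are masked and counted, not
clamped — folding indicates registration failure, which the protocol
handles by exclusion: landmark QC flags a study when the maximum target
registration error strictly exceeds 2 mm (exactly 2.0 mm is retained).

### Attenuation bands and functional tissue

On the inspiration VNC (warped to the analysis grid): LAA below −950 HU
(emphysema, honeycomb air), NAA in [−950, −600), HAA in [−600, −250)
(ground glass, septal thickening), and ≥ −250 HU excluded (vessels,
consolidation). The verbal band bounds in the literature overlap at the
edges; this package fixes half-open intervals $[\mathrm{lo}, \mathrm{hi})$,
so −600 HU belongs to HAA and −950 HU to NAA. Functional tissue is
NAA ∪ HAA. Vessel exclusion rides on the ≥ −250 HU rule; an explicit
PBV-based vessel mask was considered and left out of the default path
because the upper HU bound already removes contrast-filled vessels in the
phantom and keeps the module surface minimal.

### Longitudinal statistics

Follow-up/baseline ratios are annualized linearly,
$1 + (\mathrm{f}/\mathrm{b} - 1)\cdot 365.25/\Delta t_\mathrm{days}$,
accepting the linear-change-over-time assumption; the year length is a
config parameter. Correlations are Pearson with two-sided $t$-based
p-values ($t = R\sqrt{(n-2)/(1-R^2)}$, $n-2$ df), pairwise deletion for
missing values (DLCO is allowed to be missing), and no multiple-testing
correction by default (a `p_adjust` switch exists). NAA-vs-HAA contrasts
use a paired $t$ test; identical vectors return $t=0, p=1$ by convention
while a constant nonzero difference with zero spread is treated as
degenerate input.

## The phantom: what it emulates and what it does not

Inspiration anatomy is analytic: a soft-tissue body ellipsoid, two lung
ellipsoids, a smooth sinusoidal air-fraction field around a mean
inspiratory air content of 0.87, Gaussian fibrosis blobs placed
basally/peripherally (air-content depressions deep enough to reach the HAA
band and the high-ventilation regime above 0.75), one optional LAA blob,
intrapulmonary vessel capsules, and two mediastinal vascular reference
spheres. The expiration scan is the analytic pull-back through a smooth
parametric deformation (per-axis affine contraction, z-dominant like
diaphragm motion, plus a bounded sinusoid with closed-form Jacobian).
Lung parenchyma obeys tissue-mass conservation
($\tau_\mathrm{exp} = J\,\tau_\mathrm{insp}\circ\varphi$) with voxels
fully occupied by air + tissue, which makes the ventilation truth exact:
$\mathrm{RV} = (1 - S)/\alpha_\mathrm{insp}\circ\varphi$. Because the
expiration image is evaluated analytically rather than numerically warped,
truth carries no generator interpolation error.

Consequences worth noting:

* **Ventilation truth is derived, not dialled.** Deformation and air
  fraction are the free parameters; RV follows. The healthy-lung spec
  inverts the closed form ($J = 1/(1 - \mathrm{RV}\,\alpha_0)$) to target a
  drawn mean ventilation in [0.43, 0.47], inside the published healthy band
  of 0.40–0.50.
* **A reconstruction PSF (default sigma 0.7 voxel) blurs the emitted
  images.** Real CT has partial volume at tissue interfaces; an
  analytically crisp edge is an idealization that makes trilinear warping
  look worse than it is clinically, because the inspiration and expiration
  edge profiles are then inconsistently smeared. Composition truth stays
  crisp; the image truth fields carry the PSF (that is what an ideal
  decomposition returns).
* **Forced-collapse regions** (total expiratory collapse, RV = 1) break
  mass conservation by construction and are off by default.
* **Not emulated:** noise texture and beam hardening (default noise is 0 so
  algebraic round trips are exact; a Gaussian noise option exists), cardiac
  motion, gating, airways, lobar anatomy, and realistic vessel trees. A
  green phantom test therefore establishes algorithmic correctness and
  self-consistency, not clinical performance.
* **Scale.** Default grids are 96³ at 2.5 mm — a scaled-down thorax
  (~2 L inspiratory lung volume). All geometry is parametrized in fractions
  of the grid extent, so specs scale to clinical voxel sizes.

The cohort generator emits per-patient baseline functional means
(ventilation 0.63 ± 0.10, perfusion 9.02 ± 2.12%, late enhancement
38.0 ± 11.6%), NAA/HAA splits with a planted one-SD HAA excess, reference
values at baseline and follow-up (FVC% 69.75 ± 17.25, DLCO% 52.58 ± 14.55
with ~19% missing, lung volume 3942 ± 844 mL, density −742.23 ± 51.05 HU),
intervals around 15 months, and a planted linear relation (population
correlation `planted_r`) between baseline ventilation and the annualized
lung-volume ratio. With `noise_sd = 0` the ratio column is constant and
flagged degenerate.

## Numerical choices

* World coordinates: RAS+, `world = origin + index * spacing`, 0-based
  indices; displacements always in mm (anisotropic voxels make index-space
  gradients wrong).
* Gradients: central differences with spacing-aware stencils, one-sided at
  borders. For affine fields this makes the Jacobian exact to rounding.
* HU are clipped to the 12-bit range [−1024, 3071] on load.
* Resampling/warping: trilinear for scalars, nearest for labels; fill
  −1024 HU (HU volumes) or 0 (others) outside support.
* Ties and boundaries are fixed deterministically everywhere: half-open HU
  bands, strict inequality in the 2 mm QC rule, first-encounter ordering of
  connected-component labels.
* Determinism: phantoms and cohorts are pure functions of their seed;
  registration is deterministic by construction.

## Known limitations

* The built-in registration targets the smooth, large-amplitude
  breathing deformation; it is not a general-purpose registration suite,
  does not model sliding at the pleura, and recovers low-frequency
  residuals only partially (see above). Import an external field for
  demanding cases.
* The lung segmenter is threshold + morphology; it substitutes for a
  learned model and is validated only against phantom geometry
  (Dice > 0.95), not pathology with pleural effusions or dense
  consolidation.
* VNC/PBV values are basis-relative; only basis-invariant outputs should
  be compared across sites.
* Oblique NIfTI orientations are rejected rather than resampled.
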