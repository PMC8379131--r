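# Synthetic digital thorax phantom with closed-form ground truth.
#
# World model
# -----------
# Inspiration anatomy is defined analytically in world coordinates: a soft-
# tissue body ellipsoid containing two lung ellipsoids, a per-voxel air
# fraction alpha (base level + low-frequency sinusoid + Gaussian fibrosis /
# emphysema blobs), intrapulmonary vessel capsules and two mediastinal
# vascular reference spheres (PA trunk, ascending aorta).
#
# The expiration scan is the analytic pull-back through a smooth
# parametric deformation phi(x) = c + lambda (x - c) + a sin(...) mapping
# expiration to inspiration coordinates (lambda > 1: the lung was larger in
# inspiration). Lung parenchyma obeys tissue-mass conservation,
#     tissue_exp(x) = J(x) * tissue_insp(phi(x)),  J = det(grad phi),
# and voxels stay fully occupied (air + tissue = 1), which makes the
# ventilation truth closed-form: RV(x) = (1 - S(x)) / alpha_insp(phi(x))
# with S = 1/J. Vessels, the mediastinum and the body wall are treated as
# incompressible blood/soft tissue. Because the expiration image is
# evaluated analytically (never numerically warped), truth carries no
# generator interpolation error.
#
# Dual-energy forward model: tissue amount is defined at the low-kV
# reference (vnc = -1000 + B11 * t) and the kV images are
# -1000 + B %*% (t, iodine) with the same 2x2 basis the decomposition
# module inverts, so the round trip is exact for any basis.

HU_AIR <- -1000

ellipsoid_inside <- function(X, Y, Z, center, semi) {
  ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((Z - center[3]) / semi[3])^2 <= 1
}

gauss_blob <- function(X, Y, Z, center, sigma) {
  exp(-0.5 * ((X - center[1])^2 + (Y - center[2])^2 + (Z - center[3])^2) / sigma^2)
}

capsule_inside <- function(X, Y, Z, p0, p1, radius) {
  v <- p1 - p0
  vv <- sum(v^2)
  t <- ((X - p0[1]) * v[1] + (Y - p0[2]) * v[2] + (Z - p0[3]) * v[3]) / vv
  t <- pmin(pmax(t, 0), 1)
  d2 <- (X - p0[1] - t * v[1])^2 + (Y - p0[2] - t * v[2])^2 +
    (Z - p0[3] - t * v[3])^2
  d2 <= radius^2
}

#' Phantom specification
#'
#' All stochastic choices (blob placement jitter, sinusoid phases) are made
#' here from `seed` and frozen into the returned object, so
#' [generate_phantom()] is a pure function of its spec. Geometric
#' parameters are fractions of the grid extent so one spec family scales
#' from test grids (96^3 default) to demo grids.
#'
#' @param shape grid size, default c(96, 96, 96).
#' @param spacing voxel size in mm, default c(2.5, 2.5, 2.5) (a scaled-down
#'   desk-size thorax; clinical-resolution specs may use c(0.68, 0.68, 1)).
#' @param seed integer; fully determines the phantom.
#' @param alpha0 mean inspiration air fraction of lung parenchyma.
#' @param alpha_amp amplitude of the smooth spatial air-fraction variation.
#' @param lambda per-axis affine expansion factors of the
#'   expiration-to-inspiration map (> 1; z-dominant mimics diaphragm
#'   motion).
#' @param def_amp per-axis sinusoidal deformation amplitudes in mm.
#' @param hu_tissue,hu_blood soft-tissue and blood HU.
#' @param n_fibrosis number of fibrotic (HAA) blobs; 0 for a healthy lung.
#' @param fibrosis_depth peak air-fraction reduction inside a fibrosis blob.
#' @param fibrosis_sigma_mm Gaussian radius of fibrosis blobs.
#' @param laa TRUE to include one small emphysema-like (LAA) blob.
#' @param atelectasis_regions optional list of lists with `center` (mm,
#'   expiration frame) and `semi` (mm): regions forced to total expiratory
#'   collapse (air content 0, ventilation 1). Mass conservation is
#'   deliberately broken inside these regions.
#' @param iodine named list of iodine-model parameters (see defaults).
#' @param basis the shared [decomposition_basis()].
#' @param psf_sigma_vox Gaussian reconstruction point-spread sigma (voxels)
#'   applied to the emitted images, emulating the partial-volume blur of a
#'   soft reconstruction kernel consistently in both phases. Composition
#'   truth (air/tissue fractions, masks, ventilation) stays crisp and
#'   closed-form; the image truth fields (`vnc_*_true`, `iodine_*_true`)
#'   include the PSF, since that is what an ideal decomposition recovers.
#' @param noise_sd_hu Gaussian noise added to the emitted kV images (HU);
#'   default 0 keeps truth exact.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(96, 96, 96), spacing = c(2.5, 2.5, 2.5),
                         seed = 1L, alpha0 = 0.87, alpha_amp = 0.04,
                         lambda = c(1.10, 1.10, 1.30),
                         def_amp = c(1.5, 1.5, 2.0),
                         hu_tissue = 40, hu_blood = 40,
                         n_fibrosis = 4L, fibrosis_depth = 0.40,
                         fibrosis_sigma_mm = 18, laa = TRUE,
                         atelectasis_regions = list(),
                         iodine = list(), basis = decomposition_basis(),
                         psf_sigma_vox = 0.7, noise_sd_hu = 0) {
  if (any(lambda < 1)) stop("lambda must be >= 1 on every axis", call. = FALSE)
  shape <- as.integer(shape)
  extent <- (shape - 1) * spacing
  center <- extent / 2
  rng <- local_rng(seed)
  on.exit(rng())
  frac <- function(f) center + f * extent   # fractional offset from center
  lung_centers <- list(center + c(-0.20, -0.02, 0) * extent,
                       center + c(0.20, -0.02, 0) * extent)
  lung_semi <- c(0.165, 0.27, 0.36) * extent
  # fibrosis blobs: basal / peripheral, jittered per seed
  fib <- list()
  if (n_fibrosis > 0) {
    base_sites <- list(c(-0.22, 0.08, -0.26), c(0.24, 0.06, -0.24),
                       c(0.20, -0.10, 0.20), c(-0.18, -0.08, 0.22))
    for (b in seq_len(n_fibrosis)) {
      site <- base_sites[[(b - 1L) %% length(base_sites) + 1L]]
      jit <- runif(3, -0.02, 0.02)
      fib[[b]] <- list(center = center + (site + jit) * extent,
                       sigma = fibrosis_sigma_mm * runif(1, 0.9, 1.1),
                       depth = fibrosis_depth * runif(1, 0.95, 1.0))
    }
  }
  laa_blobs <- list()
  if (isTRUE(laa))
    laa_blobs[[1]] <- list(center = center + (c(-0.20, -0.12, 0.18) +
                                                runif(3, -0.01, 0.01)) * extent,
                           sigma = 6, boost = 0.16)
  # deformation: sinusoid phases/wave-vectors per seed
  W <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 1))   # cycles per extent
  phases <- runif(3, 0, 2 * pi)
  io_defaults <- list(
    perf_base = 45, perf_grad = 0.30, perf_haa_boost = 0.60,
    delayed_base = 25, delayed_haa_amp = 78,
    vessel_arterial = 350, vessel_delayed = 60, vessel_radius_mm = 2.6,
    roi_radius_mm = 9, roi_label_radius_mm = 5.5,
    roi_arterial = c(pa = 520, ao = 480),
    roi_delayed = c(pa = 70, ao = 90))
  io <- utils::modifyList(io_defaults, iodine)
  roi_centers <- list(pa = center + c(0, -0.05, 0.10) * extent,
                      ao = center + c(0, -0.05, -0.06) * extent)
  vessels <- list()
  for (lc in lung_centers) {
    vessels[[length(vessels) + 1L]] <-
      list(p0 = lc - c(0, 0, 0.22) * extent, p1 = lc + c(0, 0, 0.22) * extent,
           radius = io$vessel_radius_mm)
    vessels[[length(vessels) + 1L]] <-
      list(p0 = lc - c(0.05, 0.09, 0.18) * extent,
           p1 = lc + c(0.05, 0.09, 0.18) * extent,
           radius = 0.8 * io$vessel_radius_mm)
  }
  structure(list(
    shape = shape, spacing = as.numeric(spacing), seed = as.integer(seed),
    extent = extent, center = center,
    body_center = center, body_semi = c(0.46, 0.40, 0.48) * extent,
    lung_centers = lung_centers, lung_semi = lung_semi,
    alpha0 = alpha0, alpha_amp = alpha_amp,
    alpha_wave = c(0, 1, 1), alpha_phase = runif(1, 0, 2 * pi),
    fibrosis = fib, laa_blobs = laa_blobs,
    lambda = as.numeric(lambda), def_amp = as.numeric(def_amp),
    def_wave = W, def_phase = phases,
    hu_tissue = hu_tissue, hu_blood = hu_blood,
    atelectasis_regions = atelectasis_regions,
    iodine = io, roi_centers = roi_centers, vessels = vessels,
    basis = basis, psf_sigma_vox = psf_sigma_vox, noise_sd_hu = noise_sd_hu
  ), class = "phantom_spec")
}

# save/restore the global RNG state around seeded generation
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

# inspiration-frame field evaluators (vectorized over coordinate arrays)
phantom_fields <- function(spec) {
  in_body <- function(X, Y, Z)
    ellipsoid_inside(X, Y, Z, spec$body_center, spec$body_semi)
  in_lung <- function(X, Y, Z)
    ellipsoid_inside(X, Y, Z, spec$lung_centers[[1]], spec$lung_semi) |
    ellipsoid_inside(X, Y, Z, spec$lung_centers[[2]], spec$lung_semi)
  fib_bump <- function(X, Y, Z) {
    acc <- 0
    for (b in spec$fibrosis)
      acc <- acc + b$depth * gauss_blob(X, Y, Z, b$center, b$sigma)
    acc
  }
  fib_norm <- function(X, Y, Z) {   # 0..1 fibrosis weight for iodine boosts
    if (length(spec$fibrosis) == 0) return(array(0, dim(X)))
    acc <- array(0, dim(X))
    for (b in spec$fibrosis)
      acc <- pmax(acc, gauss_blob(X, Y, Z, b$center, b$sigma))
    acc
  }
  alpha <- function(X, Y, Z) {
    w <- spec$alpha_wave
    th <- 2 * pi * (w[1] * (X - spec$center[1]) / spec$extent[1] +
                    w[2] * (Y - spec$center[2]) / spec$extent[2] +
                    w[3] * (Z - spec$center[3]) / spec$extent[3]) + spec$alpha_phase
    a <- spec$alpha0 + spec$alpha_amp * sin(th) - fib_bump(X, Y, Z)
    for (b in spec$laa_blobs)
      a <- a + b$boost * gauss_blob(X, Y, Z, b$center, b$sigma)
    pmin(pmax(a, 0.02), 0.985)
  }
  in_vessel <- function(X, Y, Z) {
    m <- array(FALSE, dim(X))
    for (v in spec$vessels)
      m <- m | capsule_inside(X, Y, Z, v$p0, v$p1, v$radius)
    m
  }
  # iodine-filled vessel lumen (for images) vs the smaller reference-ROI
  # label drawn in the lumen core, away from partial-volume edges
  roi_sphere <- function(X, Y, Z, r) {
    lab <- array(0, dim(X))
    pa <- (X - spec$roi_centers$pa[1])^2 + (Y - spec$roi_centers$pa[2])^2 +
      (Z - spec$roi_centers$pa[3])^2 <= r^2
    ao <- (X - spec$roi_centers$ao[1])^2 + (Y - spec$roi_centers$ao[2])^2 +
      (Z - spec$roi_centers$ao[3])^2 <= r^2
    lab[pa] <- 1; lab[ao] <- 2
    lab
  }
  roi_lumen <- function(X, Y, Z) roi_sphere(X, Y, Z, spec$iodine$roi_radius_mm)
  roi_label <- function(X, Y, Z) roi_sphere(X, Y, Z, spec$iodine$roi_label_radius_mm)
  list(in_body = in_body, in_lung = in_lung, alpha = alpha,
       fib_norm = fib_norm, in_vessel = in_vessel,
       roi_lumen = roi_lumen, roi_label = roi_label)
}

# deformation phi (expiration -> inspiration) and analytic Jacobian det
phantom_deformation <- function(spec, X, Y, Z) {
  cc <- spec$center; E <- spec$extent
  lam <- spec$lambda; amp <- spec$def_amp
  W <- spec$def_wave; ph <- spec$def_phase
  dX <- X - cc[1]; dY <- Y - cc[2]; dZ <- Z - cc[3]
  th <- list()
  P <- list()
  rel <- list(dX / E[1], dY / E[2], dZ / E[3])
  d <- list(dX, dY, dZ)
  for (i in 1:3) {
    th[[i]] <- 2 * pi * (W[i, 1] * rel[[1]] + W[i, 2] * rel[[2]] +
                           W[i, 3] * rel[[3]]) + ph[i]
    P[[i]] <- cc[i] + lam[i] * d[[i]] + amp[i] * sin(th[[i]])
  }
  # gradient entries G[i, j] = d phi_i / d x_j
  G <- vector("list", 9)
  for (i in 1:3) for (j in 1:3) {
    g <- amp[i] * cos(th[[i]]) * 2 * pi * W[i, j] / E[j]
    if (i == j) g <- g + lam[i]
    G[[(i - 1) * 3 + j]] <- g
  }
  J <- G[[1]] * (G[[5]] * G[[9]] - G[[6]] * G[[8]]) -
       G[[2]] * (G[[4]] * G[[9]] - G[[6]] * G[[7]]) +
       G[[3]] * (G[[4]] * G[[8]] - G[[5]] * G[[7]])
  list(PX = P[[1]], PY = P[[2]], PZ = P[[3]], J = J)
}

#' Generate a paired inspiration/expiration dual-energy phantom
#'
#' Emits the four kV volumes (inspiration low/high, expiration low/high)
#' plus a `truth` list carrying the exact displacement field, inverse
#' Jacobian, ventilation, air/tissue fractions, iodine fields, lung masks,
#' band label maps and vessel ROIs in both frames.
#'
#' @param spec a [phantom_spec()].
#' @return list with `insp_low_kv`, `insp_high_kv`, `exp_low_kv`,
#'   `exp_high_kv` (`scalar_volume`s, HU) and `truth`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- grid_geometry(spec$shape, spec$spacing, c(0, 0, 0))
  f <- phantom_fields(spec)
  co <- grid_world_coords(geom)
  nx <- geom$shape[1]; ny <- geom$shape[2]; nz <- geom$shape[3]
  X <- array(rep(co$x, times = ny * nz), geom$shape)
  Y <- array(rep(rep(co$y, each = nx), times = nz), geom$shape)
  Z <- array(rep(co$z, each = nx * ny), geom$shape)
  vol <- function(data, unit) scalar_volume(data, spec$spacing, c(0, 0, 0), unit)

  ## ---- inspiration frame ----
  body_I <- f$in_body(X, Y, Z)
  lung_I <- f$in_lung(X, Y, Z)
  vess_I <- f$in_vessel(X, Y, Z) & lung_I
  roi_I <- f$roi_lumen(X, Y, Z)
  roi_I_lab <- f$roi_label(X, Y, Z)
  alpha_I <- f$alpha(X, Y, Z)
  parenchyma_I <- lung_I & !vess_I
  a_I <- array(0, geom$shape)
  a_I[parenchyma_I] <- alpha_I[parenchyma_I]
  a_I[vess_I] <- 0.05
  vnc_I <- array(HU_AIR, geom$shape)
  vnc_I[body_I] <- spec$hu_tissue
  vnc_I[parenchyma_I] <- HU_AIR * a_I[parenchyma_I] +
    spec$hu_tissue * (1 - a_I[parenchyma_I])
  vnc_I[vess_I] <- HU_AIR * 0.05 + spec$hu_blood * 0.95
  vnc_I[roi_I > 0] <- spec$hu_blood
  io <- spec$iodine
  fibw_I <- f$fib_norm(X, Y, Z)
  grad_I <- (Y - spec$center[2]) / spec$extent[2]   # anterior-posterior axis
  iod_art <- array(0, geom$shape)
  iod_art[parenchyma_I] <- io$perf_base *
    (1 + io$perf_grad * grad_I[parenchyma_I]) *
    (1 + io$perf_haa_boost * fibw_I[parenchyma_I])
  iod_art[vess_I] <- io$vessel_arterial
  iod_art[roi_I == 1] <- io$roi_arterial[["pa"]]
  iod_art[roi_I == 2] <- io$roi_arterial[["ao"]]

  ## ---- expiration frame (analytic pull-back) ----
  def <- phantom_deformation(spec, X, Y, Z)
  PX <- def$PX; PY <- def$PY; PZ <- def$PZ; J <- def$J
  S <- 1 / J
  body_E <- f$in_body(PX, PY, PZ)
  lung_E <- f$in_lung(PX, PY, PZ)
  vess_E <- f$in_vessel(PX, PY, PZ) & lung_E
  roi_E <- f$roi_lumen(PX, PY, PZ)
  roi_E_lab <- f$roi_label(PX, PY, PZ)
  alpha_IP <- f$alpha(PX, PY, PZ)
  parenchyma_E <- lung_E & !vess_E
  if (any(J[lung_E] <= 0))
    stop("degenerate deformation: non-positive Jacobian inside the lung",
         call. = FALSE)
  tis_E <- J * (1 - alpha_IP)
  a_E <- 1 - tis_E
  if (any(a_E[parenchyma_E] < 0.005))
    stop("phantom spec infeasible: expiration air content would be negative",
         call. = FALSE)
  # forced-collapse regions (expiration frame); break mass conservation
  collapse_E <- array(FALSE, geom$shape)
  for (r in spec$atelectasis_regions)
    collapse_E <- collapse_E | ellipsoid_inside(X, Y, Z, r$center, r$semi)
  collapse_E <- collapse_E & parenchyma_E
  a_E[collapse_E] <- 0
  tis_E[collapse_E] <- 1
  rv <- array(NA_real_, geom$shape)
  rv[parenchyma_E] <- 1 - S[parenchyma_E] * a_E[parenchyma_E] / alpha_IP[parenchyma_E]
  if (any(rv[parenchyma_E & !collapse_E] < -1e-9 |
          rv[parenchyma_E & !collapse_E] >= 1))
    stop("phantom spec infeasible: ventilation truth outside [0, 1)", call. = FALSE)
  a_E_full <- a_E
  a_E_full[!parenchyma_E] <- 0
  a_E_full[vess_E] <- 0.05
  vnc_E <- array(HU_AIR, geom$shape)
  vnc_E[body_E] <- spec$hu_tissue
  vnc_E[parenchyma_E] <- HU_AIR * a_E[parenchyma_E] +
    spec$hu_tissue * tis_E[parenchyma_E]
  vnc_E[collapse_E] <- spec$hu_tissue
  vnc_E[vess_E] <- HU_AIR * 0.05 + spec$hu_blood * 0.95
  vnc_E[roi_E > 0] <- spec$hu_blood
  fibw_E <- f$fib_norm(PX, PY, PZ)
  iod_del <- array(0, geom$shape)
  iod_del[parenchyma_E] <- io$delayed_base + io$delayed_haa_amp * fibw_E[parenchyma_E]
  iod_del[vess_E] <- io$vessel_delayed
  iod_del[roi_E == 1] <- io$roi_delayed[["pa"]]
  iod_del[roi_E == 2] <- io$roi_delayed[["ao"]]

  ## ---- reconstruction PSF + dual-energy forward model ----
  # the PSF acts on the material images before the (linear) energy mixing,
  # which is equivalent to blurring the kV images themselves
  psf <- function(arr) {
    if (spec$psf_sigma_vox <= 0) return(arr)
    array(c_gauss3(as.vector(arr), geom$shape, rep(spec$psf_sigma_vox, 3)),
          geom$shape)
  }
  vnc_I <- psf(vnc_I)
  vnc_E <- psf(vnc_E)
  iod_art <- psf(iod_art)
  iod_del <- psf(iod_del)
  # tissue amount is defined at the low-kV reference (vnc = -1000 + B11 * t),
  # so the forward model is exact for any basis, including energy-dependent
  # tissue responses
  B <- unclass(spec$basis)
  t_I <- (vnc_I + 1000) / B[1, 1]
  t_E <- (vnc_E + 1000) / B[1, 1]
  insp_low <- -1000 + B[1, 1] * t_I + B[1, 2] * iod_art
  insp_high <- -1000 + B[2, 1] * t_I + B[2, 2] * iod_art
  exp_low <- -1000 + B[1, 1] * t_E + B[1, 2] * iod_del
  exp_high <- -1000 + B[2, 1] * t_E + B[2, 2] * iod_del
  if (spec$noise_sd_hu > 0) {
    rng <- local_rng(spec$seed + 1000003L)
    on.exit(rng(), add = TRUE)
    n <- length(insp_low)
    insp_low <- insp_low + rnorm(n, 0, spec$noise_sd_hu)
    insp_high <- insp_high + rnorm(n, 0, spec$noise_sd_hu)
    exp_low <- exp_low + rnorm(n, 0, spec$noise_sd_hu)
    exp_high <- exp_high + rnorm(n, 0, spec$noise_sd_hu)
  }

  ## ---- truth bundle ----
  u <- array(c(PX - X, PY - Y, PZ - Z), c(geom$shape, 3L))
  field_true <- displacement_field(u, spec$spacing, c(0, 0, 0))
  band_insp <- classify_bands(vol(vnc_I, "HU"), lung_I)
  # expiration-frame bands: the (PSF-ed) inspiration VNC seen through the
  # exact field, mirroring the pipeline's warped-VNC band semantics
  vnc_IP <- warp(vol(vnc_I, "HU"), field_true, "linear")
  band_exp <- classify_bands(vnc_IP, lung_E)
  roi_vol <- function(lab) vol(array(as.numeric(lab), geom$shape), "label")
  truth <- list(
    displacement_true = field_true,
    inv_jacobian_true = vol(S, "dimensionless"),
    ventilation_true = vol(rv, "fraction"),
    air_insp_true = vol(a_I, "fraction"),
    air_exp_true = vol(a_E_full, "fraction"),
    air_insp_warped_true = vol(alpha_IP * ifelse(parenchyma_E, 1, NA), "fraction"),
    tissue_insp_true = vol(array(ifelse(parenchyma_I, 1 - alpha_I, NA),
                                 geom$shape), "fraction"),
    tissue_exp_true = vol(array(ifelse(parenchyma_E, tis_E, NA), geom$shape),
                          "fraction"),
    iodine_insp_true = vol(iod_art, "iodine_HU"),
    iodine_delayed_true = vol(iod_del, "iodine_HU"),
    vnc_insp_true = vol(vnc_I, "HU"),
    vnc_exp_true = vol(vnc_E, "HU"),
    lung_mask_insp = lung_I,
    lung_mask_exp = lung_E,
    parenchyma_insp = parenchyma_I,
    parenchyma_exp = parenchyma_E,
    collapse_exp = collapse_E,
    band_map_insp = band_insp,
    band_map_exp = band_exp,
    vessel_roi_insp = roi_vol(roi_I_lab),
    vessel_roi_exp = roi_vol(roi_E_lab),
    stats = list(
      mean_ventilation_functional =
        mean(rv[parenchyma_E & band_region_mask(band_exp, "functional")]),
      band_fractions_insp = c(
        LAA = mean(band_insp[lung_I] == 1L),
        NAA = mean(band_insp[lung_I] == 2L),
        HAA = mean(band_insp[lung_I] == 3L),
        excluded = mean(band_insp[lung_I] == 4L)),
      lung_volume_insp_mL = sum(lung_I) * prod(spec$spacing) / 1000,
      lung_volume_exp_mL = sum(lung_E) * prod(spec$spacing) / 1000)
  )
  list(insp_low_kv = vol(insp_low, "HU"), insp_high_kv = vol(insp_high, "HU"),
       exp_low_kv = vol(exp_low, "HU"), exp_high_kv = vol(exp_high, "HU"),
       truth = truth, spec = spec)
}

#' Healthy-lung phantom specification
#'
#' Draws a target mean ventilation in \[0.43, 0.47\] (the centre of the
#' published healthy band 0.40-0.50), converts it to the affine volume
#' factor via the closed form `J = 1 / (1 - RV * alpha0)` implied by the
#' air-content model, and disables fibrosis/emphysema blobs.
#'
#' @param seed integer seed.
#' @param shape,spacing grid, defaults as [phantom_spec()].
#' @return A `phantom_spec` whose truth mean ventilation lies in
#'   \[0.40, 0.50\].
#' @export
generate_healthy_spec <- function(seed, shape = c(96, 96, 96),
                                  spacing = c(2.5, 2.5, 2.5)) {
  rng <- local_rng(seed * 2L + 17L)
  target <- runif(1, 0.43, 0.47)
  rng()
  alpha0 <- 0.85
  Jv <- 1 / (1 - target * alpha0)
  lambda <- c(Jv^0.25, Jv^0.25, Jv^0.5)
  phantom_spec(shape = shape, spacing = spacing, seed = seed,
               alpha0 = alpha0, alpha_amp = 0.03, lambda = lambda,
               def_amp = c(1.0, 1.0, 1.5), n_fibrosis = 0L, laa = FALSE)
}

#' Generate a synthetic longitudinal cohort
#'
#' One row per patient with baseline functional means, NAA/HAA splits,
#' reference values (FVC%, DLCO%, lung volume, mean lung density) at
#' baseline and follow-up, and the scan interval. A linear relation with
#' population correlation `planted_r` is planted between baseline mean
#' ventilation and the annualized follow-up/baseline lung-volume ratio;
#' all other follow-up ratios are independent mild declines. Baseline
#' distributions follow the published cohort (mean ventilation
#' 0.63 +/- 0.10, perfusion 9.02 +/- 2.12, late enhancement 38.0 +/- 11.6,
#' FVC% 69.75 +/- 17.25, DLCO% 52.58 +/- 14.55, lung volume
#' 3942 +/- 844 mL, density -742.23 +/- 51.05 HU), with DLCO missing for
#' ~19% of patients (the study's 26/32). Scan intervals are drawn around
#' 15 months.
#'
#' @param n_patients cohort size (>= 4), default 32.
#' @param planted_r population correlation in (-1, 1), default -0.5.
#' @param noise_sd SD of the annualized lung-volume ratio, default 0.04;
#'   0 produces a degenerate constant ratio column (flagged).
#' @param seed integer seed.
#' @param haa_shift_sd planted HAA-minus-NAA shift of each functional
#'   parameter, in units of its between-patient SD; default 1.
#' @return data.frame; attribute `degenerate` is TRUE when `noise_sd = 0`.
#' @export
generate_cohort <- function(n_patients = 32L, planted_r = -0.5,
                            noise_sd = 0.04, seed = 1L, haa_shift_sd = 1) {
  if (n_patients < 4L) stop("n_patients must be >= 4", call. = FALSE)
  if (abs(planted_r) >= 1) stop("planted_r must lie strictly in (-1, 1)",
                                call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  rng <- local_rng(seed)
  on.exit(rng())
  n <- as.integer(n_patients)
  interval_days <- pmax(round(rnorm(n, 456, 80)), 183)
  draw2 <- function(mu, sdv) {   # baseline + NAA/HAA split with planted shift
    base <- rnorm(n, mu, sdv)
    naa <- base - 0.5 * haa_shift_sd * sdv + rnorm(n, 0, 0.5 * sdv)
    haa <- naa + haa_shift_sd * sdv + rnorm(n, 0, sdv)
    list(base = base, naa = naa, haa = haa)
  }
  vent <- draw2(0.63, 0.10)
  perf <- draw2(9.02, 2.12)
  late <- draw2(38.0, 11.6)
  fvc_b <- rnorm(n, 69.75, 17.25)
  dlco_b <- rnorm(n, 52.58, 14.55)
  lv_b <- rnorm(n, 3942, 844)
  dens_b <- rnorm(n, -742.23, 51.05)
  # planted relation: baseline ventilation vs annualized lung-volume ratio
  z <- as.numeric(scale(vent$base))
  eps <- rnorm(n)
  ratio_lv <- 0.944 + noise_sd * (planted_r * z + sqrt(1 - planted_r^2) * eps)
  deann <- function(ratio_annual) 1 + (ratio_annual - 1) * interval_days / 365.25
  lv_f <- lv_b * deann(ratio_lv)
  fvc_f <- fvc_b * deann(rnorm(n, 0.92, 0.06))
  dlco_f <- dlco_b * deann(rnorm(n, 0.83, 0.08))
  dens_f <- dens_b * deann(rnorm(n, 0.982, 0.015))
  n_missing <- round(0.1875 * n)
  if (n_missing > 0) {
    miss <- sample.int(n, n_missing)
    dlco_b[miss] <- NA; dlco_f[miss] <- NA
  }
  out <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    interval_days = interval_days,
    ventilation_baseline = vent$base, ventilation_naa = vent$naa,
    ventilation_haa = vent$haa,
    perfusion_baseline = perf$base, perfusion_naa = perf$naa,
    perfusion_haa = perf$haa,
    late_enhancement_baseline = late$base, late_enhancement_naa = late$naa,
    late_enhancement_haa = late$haa,
    fvc_pct_baseline = fvc_b, fvc_pct_followup = fvc_f,
    dlco_pct_baseline = dlco_b, dlco_pct_followup = dlco_f,
    lung_volume_ml_baseline = lv_b, lung_volume_ml_followup = lv_f,
    lung_density_hu_baseline = dens_b, lung_density_hu_followup = dens_f,
    stringsAsFactors = FALSE)
  attr(out, "degenerate") <- noise_sd == 0
  if (noise_sd == 0)
    warning("degenerate cohort: noise_sd = 0 makes the lung-volume ratio ",
            "column constant; downstream correlations are undefined")
  out
}
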