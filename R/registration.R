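# Deformable registration of inspiration to expiration and Jacobian math.
#
# Convention: the displacement field u lives on the fixed (expiration) grid
# and maps fixed world coordinates into the moving (inspiration) image,
# phi(x) = x + u(x). The inverse Jacobian S(x) = 1 / det(I + grad u) is the
# local shrinkage factor from inspiration to expiration: S < 1 where the
# lung was larger in inspiration.

#' Warp a moving volume through a displacement field (pull-back)
#'
#' `out(x) = moving(x + u(x))`, trilinear interpolation for scalars and
#' nearest neighbour for labels, -1024 fill for HU and 0 otherwise.
#'
#' @param moving `scalar_volume` in the moving (inspiration) frame.
#' @param field `displacement_field` on the fixed grid.
#' @param interpolation "linear" or "nearest".
#' @param fill optional out-of-support fill override.
#' @return `scalar_volume` on the fixed grid.
#' @export
warp <- function(moving, field, interpolation = c("linear", "nearest"), fill = NULL) {
  interpolation <- match.arg(interpolation)
  if (moving$unit == "label" && interpolation == "linear")
    stop("label volumes must be warped with nearest interpolation", call. = FALSE)
  if (is.null(fill)) fill <- if (moving$unit == "HU") -1024 else 0
  gf <- geometry_of(field)
  out <- c_warp(as.vector(moving$data), dim(moving$data), moving$spacing,
                moving$origin,
                as.vector(field$vectors[, , , 1]),
                as.vector(field$vectors[, , , 2]),
                as.vector(field$vectors[, , , 3]),
                gf$shape, gf$spacing, gf$origin,
                interpolation == "linear", fill)
  scalar_volume(array(out, gf$shape), gf$spacing, gf$origin, moving$unit)
}

#' Inverse Jacobian determinant (shrinkage) map of a displacement field
#'
#' Computes `S(x) = 1 / det(I + grad u(x))` with spacing-aware central
#' differences (one-sided at volume borders). `S` is the per-voxel ratio of
#' local expiration volume to local inspiration volume. Voxels where the
#' determinant is non-positive (folding) are set to NA and counted in
#' `attr(, "n_nonpositive")` rather than clamped.
#'
#' @param field a `displacement_field`.
#' @return `scalar_volume` (dimensionless) of S values, NA where folded.
#' @export
inverse_jacobian <- function(field) {
  stopifnot(is_displacement_field(field))
  g <- geometry_of(field)
  d3 <- g$shape
  J <- vector("list", 3)
  for (i in 1:3)
    J[[i]] <- c_grad3(as.vector(field$vectors[, , , i]), d3, g$spacing)
  # det(I + G) where G[i, j] = d u_i / d x_j
  a11 <- 1 + J[[1]][, 1]; a12 <- J[[1]][, 2]; a13 <- J[[1]][, 3]
  a21 <- J[[2]][, 1]; a22 <- 1 + J[[2]][, 2]; a23 <- J[[2]][, 3]
  a31 <- J[[3]][, 1]; a32 <- J[[3]][, 2]; a33 <- 1 + J[[3]][, 3]
  det <- a11 * (a22 * a33 - a23 * a32) -
         a12 * (a21 * a33 - a23 * a31) +
         a13 * (a21 * a32 - a22 * a31)
  bad <- det <= 0
  S <- 1 / det
  S[bad] <- NA_real_
  if (all(bad)) stop("degenerate field: non-positive Jacobian everywhere", call. = FALSE)
  out <- scalar_volume(array(S, d3), g$spacing, g$origin, "dimensionless")
  attr(out, "n_nonpositive") <- sum(bad)
  out
}

# Gaussian-smooth each field component; sigma in mm.
smooth_field <- function(vec_list, d3, spacing, sigma_mm) {
  if (sigma_mm <= 0) return(vec_list)
  sv <- sigma_mm / spacing
  lapply(vec_list, function(v) c_gauss3(v, d3, sv))
}

smooth_volume_array <- function(arr, spacing, sigma_mm) {
  if (sigma_mm <= 0) return(arr)
  array(c_gauss3(as.vector(arr), dim(arr), sigma_mm / spacing), dim(arr))
}

#' Deformable registration (affine + multi-resolution diffusing demons)
#'
#' Three deterministic stages tailored to the large but smooth
#' inspiration-to-expiration lung deformation: (1) a diagonal-affine
#' initialization from air-mask moments; (2) Nelder-Mead refinement of the
#' affine scales/translation on high-pass-filtered images at a coarse
#' level; (3) a Thirion-style demons residual with Gaussian (elastic)
#' regularization on a coarse-to-fine pyramid. Registration forces act on
#' high-pass-filtered intensities because lung density is not conserved
#' between respiratory phases (the parenchyma densifies as it deflates): a
#' smooth inter-phase intensity offset would otherwise drag the field along
#' weak gradients. External fields from other registration suites can be
#' imported with [read_field()] instead.
#'
#' @param fixed_exp fixed (expiration) `scalar_volume`, HU.
#' @param moving_insp moving (inspiration) `scalar_volume`, HU.
#' @param levels integer shrink factors, coarse to fine.
#' @param iters iterations per level (recycled to `length(levels)`).
#' @param smoothing Gaussian sigma (mm, at the finest level) applied to the
#'   demons residual each iteration; scales with level spacing.
#' @param update_smoothing Gaussian sigma (mm, finest level) applied to each
#'   force update (fluid-like regularization).
#' @param max_step per-iteration displacement cap in mm (finest level).
#' @param highpass_sigma sigma (mm) of the high-pass prefilter (image minus
#'   its Gaussian blur); 0 disables it.
#' @param symmetric_forces use the mean of the fixed and warped-moving
#'   gradients in the demons force (symmetric-forces variant).
#' @param affine_init initialize with a diagonal affine estimated from air
#'   (lung) mask centroids and second moments of both images; bridges the
#'   large global inspiration-expiration volume change before demons
#'   refines locally. Skipped automatically when no interior air is found.
#' @param seed accepted for interface symmetry; the algorithm is fully
#'   deterministic and does not consume randomness.
#' @return A `displacement_field` on the fixed grid with attribute `qc`
#'   (list: initial/final mean absolute intensity difference, converged flag).
#' @export
register <- function(fixed_exp, moving_insp, levels = c(4L, 2L, 1L),
                     iters = c(10L, 10L, 10L), smoothing = 10.0,
                     update_smoothing = 8.0, max_step = 0.5,
                     highpass_sigma = 15, affine_init = TRUE,
                     symmetric_forces = TRUE, seed = NULL) {
  stopifnot(is_scalar_volume(fixed_exp), is_scalar_volume(moving_insp))
  iters <- rep_len(as.integer(iters), length(levels))
  gf <- geometry_of(fixed_exp)
  aff <- if (affine_init) moments_affine(fixed_exp, moving_insp) else NULL
  # normalize intensities to O(1) so demons denominators are balanced,
  # then high-pass: the between-phase density change leaves a smooth
  # intensity offset that must not generate forces
  norm01 <- function(v) (pmin(pmax(v$data, -1024), 3071) + 1000) / 1000
  fx <- norm01(fixed_exp)
  mv <- norm01(moving_insp)
  if (highpass_sigma > 0) {
    fx <- fx - smooth_volume_array(fx, gf$spacing, highpass_sigma)
    mv <- mv - smooth_volume_array(mv, gf$spacing, highpass_sigma)
  }
  # the field is kept as frozen affine part + demons residual: smoothing
  # only the residual preserves the large global volume change exactly
  affine_u <- function(lev) {
    co <- grid_world_coords(lev)
    lx <- lev$shape[1]; ly <- lev$shape[2]; lz <- lev$shape[3]
    Xc <- rep(co$x, times = ly * lz)
    Yc <- rep(rep(co$y, each = lx), times = lz)
    Zc <- rep(co$z, each = lx * ly)
    if (is.null(aff)) {
      list(numeric(lx * ly * lz), numeric(lx * ly * lz), numeric(lx * ly * lz))
    } else {
      list(aff$mu_m[1] + aff$s[1] * (Xc - aff$mu_f[1]) - Xc,
           aff$mu_m[2] + aff$s[2] * (Yc - aff$mu_f[2]) - Yc,
           aff$mu_m[3] + aff$s[3] * (Zc - aff$mu_f[3]) - Zc)
    }
  }
  if (!is.null(aff)) aff <- refine_affine(fx, mv, gf, aff)
  v <- NULL   # residual components on the current level grid
  cur_geom <- NULL
  ua0 <- affine_u(gf)
  qc0 <- mean(abs(as.numeric(fx) -
                    c_warp(as.vector(mv), gf$shape, gf$spacing, gf$origin,
                           ua0[[1]], ua0[[2]], ua0[[3]],
                           gf$shape, gf$spacing, gf$origin, TRUE, 0)))
  for (li in seq_along(levels)) {
    f <- levels[li]
    shp <- pmax(4L, as.integer(floor((gf$shape - 1) / f)) + 1L)
    sp <- gf$spacing * (gf$shape - 1) / pmax(shp - 1, 1L)
    lev <- grid_geometry(shp, sp, gf$origin)
    # anti-alias then resample both images to the level grid
    pres <- if (f > 1) 0.5 * max(sp) else 0
    fl <- array(c_resample(as.vector(smooth_volume_array(fx, gf$spacing, pres)),
                           gf$shape, gf$spacing, gf$origin,
                           lev$shape, lev$spacing, lev$origin, TRUE, 0), lev$shape)
    ml_arr <- smooth_volume_array(mv, gf$spacing, pres)
    grad_f <- c_grad3(as.vector(fl), lev$shape, lev$spacing)
    ms2 <- mean(lev$spacing)^2
    # regularization is constant in voxels across the pyramid: the mm
    # parameters refer to the finest level and scale with level spacing
    lsc <- mean(lev$spacing) / mean(gf$spacing)
    smooth_mm <- smoothing * lsc
    upd_mm <- update_smoothing * lsc
    step_mm <- max_step * lsc
    ua <- affine_u(lev)
    if (is.null(v)) {
      v <- list(numeric(prod(lev$shape)), numeric(prod(lev$shape)),
                numeric(prod(lev$shape)))
    } else {
      v <- lapply(v, function(vc)
        c_resample(vc, cur_geom$shape, cur_geom$spacing, cur_geom$origin,
                   lev$shape, lev$spacing, lev$origin, TRUE, 0))
    }
    cur_geom <- lev
    for (it in seq_len(iters[li])) {
      wm <- c_warp(as.vector(ml_arr), gf$shape, gf$spacing, gf$origin,
                   ua[[1]] + v[[1]], ua[[2]] + v[[2]], ua[[3]] + v[[3]],
                   lev$shape, lev$spacing, lev$origin, TRUE, 0)
      diff <- as.numeric(fl) - wm
      g_use <- if (symmetric_forces) {
        0.5 * (grad_f + c_grad3(wm, lev$shape, lev$spacing))
      } else grad_f
      du <- c_demons_force(diff, g_use, ms2, step_mm)
      du <- smooth_field(list(du$x, du$y, du$z), lev$shape, lev$spacing,
                         upd_mm)
      v <- list(v[[1]] + du[[1]], v[[2]] + du[[2]], v[[3]] + du[[3]])
      v <- smooth_field(v, lev$shape, lev$spacing, smooth_mm)
    }
  }
  ua <- affine_u(gf)
  u <- list(ua[[1]] + v[[1]], ua[[2]] + v[[2]], ua[[3]] + v[[3]])
  # final residual on the full grid
  wm <- c_warp(as.vector(mv), gf$shape, gf$spacing, gf$origin,
               u[[1]], u[[2]], u[[3]],
               gf$shape, gf$spacing, gf$origin, TRUE, 0)
  qc1 <- mean(abs(as.numeric(fx) - wm))
  converged <- qc1 <= qc0 * 1.05 + 1e-6
  if (!converged)
    warning("registration did not reduce the intensity mismatch; inspect QC metrics")
  vec <- array(c(u[[1]], u[[2]], u[[3]]), c(gf$shape, 3L))
  out <- displacement_field(vec, gf$spacing, gf$origin)
  attr(out, "qc") <- list(initial_mad = qc0, final_mad = qc1, converged = converged)
  out
}

# Diagonal-affine initialization from interior-air-mask moments: matches
# centroids and per-axis spreads of the lung air between the two phases.
# Returns NULL when either image lacks a usable interior air component.
moments_affine <- function(fixed, moving, threshold_hu = -400) {
  stats_of <- function(vol) {
    d <- dim(vol$data)
    cand <- vol$data < threshold_hu
    if (sum(cand) < 50) return(NULL)
    core <- erode6(cand)   # drop one-voxel partial-volume bridges
    lab <- array(c_cc3d(as.vector(core), d), d)
    border <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])]))
    m <- core & !(lab %in% border[border != 0L])
    if (sum(m) < 50) return(NULL)
    idx <- which(m, arr.ind = TRUE)
    w <- sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
    list(mu = colMeans(w), sd = apply(w, 2, sd))
  }
  sf <- stats_of(fixed)
  sm <- stats_of(moving)
  if (is.null(sf) || is.null(sm) || any(sf$sd < 1e-6)) return(NULL)
  s <- pmin(pmax(sm$sd / sf$sd, 0.5), 2)
  list(mu_f = sf$mu, mu_m = sm$mu, s = s)
}

# Refine the diagonal affine (3 scales + 3 translations) by Nelder-Mead on
# the mean squared difference of the (high-passed, normalized) images at a
# coarse grid. Deterministic; typically a few hundred cheap evaluations.
refine_affine <- function(fx_arr, mv_arr, gf, aff, shrink = 2L, maxit = 300L) {
  shp <- pmax(8L, as.integer(floor((gf$shape - 1) / shrink)) + 1L)
  sp <- gf$spacing * (gf$shape - 1) / pmax(shp - 1, 1L)
  lev <- grid_geometry(shp, sp, gf$origin)
  pres <- 0.5 * max(sp)
  fl <- c_resample(as.vector(smooth_volume_array(fx_arr, gf$spacing, pres)),
                   gf$shape, gf$spacing, gf$origin,
                   lev$shape, lev$spacing, lev$origin, TRUE, 0)
  ml <- smooth_volume_array(mv_arr, gf$spacing, pres)
  co <- grid_world_coords(lev)
  lx <- lev$shape[1]; ly <- lev$shape[2]; lz <- lev$shape[3]
  Xc <- rep(co$x, times = ly * lz)
  Yc <- rep(rep(co$y, each = lx), times = lz)
  Zc <- rep(co$z, each = lx * ly)
  obj <- function(p) {
    s <- p[1:3]; t <- p[4:6]
    wm <- c_warp(as.vector(ml), gf$shape, gf$spacing, gf$origin,
                 aff$mu_m[1] + t[1] + s[1] * (Xc - aff$mu_f[1]) - Xc,
                 aff$mu_m[2] + t[2] + s[2] * (Yc - aff$mu_f[2]) - Yc,
                 aff$mu_m[3] + t[3] + s[3] * (Zc - aff$mu_f[3]) - Zc,
                 lev$shape, lev$spacing, lev$origin, TRUE, 0)
    mean((fl - wm)^2)
  }
  opt <- stats::optim(c(aff$s, 0, 0, 0), obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  aff$s <- opt$par[1:3]
  aff$mu_m <- aff$mu_m + opt$par[4:6]
  aff
}

# sample the field (mm vectors) at world points, trilinear; pts: n x 3 matrix
sample_field_at <- function(field, pts) {
  g <- geometry_of(field)
  # build a tiny resample per component by mapping points to voxel coords
  vox <- sweep(sweep(pts, 2, g$origin, "-"), 2, g$spacing, "/")
  comp <- matrix(0, nrow(pts), 3)
  for (i in 1:3) {
    arr <- field$vectors[, , , i]
    comp[, i] <- apply(vox, 1, function(p) {
      trilinear_r(arr, p[1], p[2], p[3])
    })
  }
  comp
}

# plain-R trilinear lookup on 0-based continuous voxel coordinates (clamped)
trilinear_r <- function(arr, x, y, z) {
  d <- dim(arr)
  x <- min(max(x, 0), d[1] - 1)
  y <- min(max(y, 0), d[2] - 1)
  z <- min(max(z, 0), d[3] - 1)
  i0 <- min(floor(x), d[1] - 2); j0 <- min(floor(y), d[2] - 2)
  k0 <- min(floor(z), d[3] - 2)
  fx <- x - i0; fy <- y - j0; fz <- z - k0
  i0 <- i0 + 1; j0 <- j0 + 1; k0 <- k0 + 1   # to 1-based
  c00 <- arr[i0, j0, k0] * (1 - fx) + arr[i0 + 1, j0, k0] * fx
  c10 <- arr[i0, j0 + 1, k0] * (1 - fx) + arr[i0 + 1, j0 + 1, k0] * fx
  c01 <- arr[i0, j0, k0 + 1] * (1 - fx) + arr[i0 + 1, j0, k0 + 1] * fx
  c11 <- arr[i0, j0 + 1, k0 + 1] * (1 - fx) + arr[i0 + 1, j0 + 1, k0 + 1] * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

#' Registration quality control against landmark pairs
#'
#' Evaluates the target registration error at each landmark: the field is
#' sampled at the fixed-frame landmark and the mapped point compared with
#' the known corresponding moving-frame landmark. A study is flagged for
#' exclusion when the maximum error strictly exceeds 2 mm.
#'
#' @param field a `displacement_field`.
#' @param landmarks data.frame or matrix with columns fixed_x, fixed_y,
#'   fixed_z, moving_x, moving_y, moving_z (mm, world coordinates).
#' @param exclude_threshold_mm exclusion threshold, default 2 mm (strict
#'   inequality: exactly 2.0 mm is retained).
#' @return list with `errors_mm`, `mean_error_mm`, `max_error_mm`, `exclude`.
#' @export
registration_qc <- function(field, landmarks, exclude_threshold_mm = 2) {
  lm <- as.matrix(as.data.frame(landmarks)[, 1:6])
  if (nrow(lm) < 1L) stop("at least one landmark pair is required", call. = FALSE)
  fixed <- lm[, 1:3, drop = FALSE]
  moving <- lm[, 4:6, drop = FALSE]
  u <- sample_field_at(field, fixed)
  mapped <- fixed + u
  err <- sqrt(rowSums((mapped - moving)^2))
  list(errors_mm = err, mean_error_mm = mean(err), max_error_mm = max(err),
       exclude = max(err) > exclude_threshold_mm)
}
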