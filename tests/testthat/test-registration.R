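# Warping, inverse Jacobian, demons registration, landmark QC.

test_that("warp with an identity field reproduces the image on its own grid", {
  set.seed(3)
  v <- scalar_volume(array(rnorm(10^3), c(10, 10, 10)), spacing = c(1, 2, 1.5))
  g <- geometry_of(v)
  zero <- field_from_fun(g, function(X, Y, Z) list(X * 0, Y * 0, Z * 0))
  w <- warp(v, zero, "linear")
  expect_equal(w$data, v$data, tolerance = 1e-12)
  expect_error(warp(scalar_volume(v$data, g$spacing, unit = "label"), zero,
                    "linear"), "nearest")
})

test_that("warp follows the pull-back convention", {
  # step image: 0 for x < 5.5 world-mm, 1 beyond
  g <- grid_geometry(c(12, 6, 6))
  step <- scalar_volume(eval_on_grid_test(g, function(X, Y, Z)
    list((X > 5.5) * 1.0, Y, Z))[, , , 1], g$spacing, g$origin)
  plus1 <- field_from_fun(g, function(X, Y, Z) list(X * 0 + 1, Y * 0, Z * 0))
  w <- warp(step, plus1, "linear")
  # out(x) = step(x + 1): the step edge appears one voxel earlier
  expect_equal(w$data[6, 3, 3], 1)
  expect_equal(step$data[6, 3, 3], 0)
})

test_that("inverse Jacobian matches analytic determinants", {
  g <- grid_geometry(c(24, 24, 24), c(1, 1, 1))
  # identity
  S0 <- inverse_jacobian(field_from_fun(g, function(X, Y, Z)
    list(X * 0, Y * 0, Z * 0)))
  expect_true(all(abs(S0$data - 1) < 1e-12))
  # u = 0.25 x per axis: det = 1.25^3
  S1 <- inverse_jacobian(field_from_fun(g, function(X, Y, Z)
    list(0.25 * X, 0.25 * Y, 0.25 * Z)))
  expect_true(all(abs(S1$data - 0.512) < 1e-9))
  # pure shear is volume-preserving
  S2 <- inverse_jacobian(field_from_fun(g, function(X, Y, Z)
    list(0.1 * Y, Y * 0, Z * 0)))
  expect_true(all(abs(S2$data - 1) < 1e-12))
  # random small affines vs matrix determinant (interior, < 0.5 %)
  set.seed(4)
  for (i in 1:5) {
    A <- matrix(rnorm(9, 0, 0.05), 3, 3)
    Sa <- inverse_jacobian(field_from_fun(g, function(X, Y, Z)
      list(A[1, 1] * X + A[1, 2] * Y + A[1, 3] * Z,
           A[2, 1] * X + A[2, 2] * Y + A[2, 3] * Z,
           A[3, 1] * X + A[3, 2] * Y + A[3, 3] * Z)))
    want <- 1 / det(diag(3) + A)
    interior <- Sa$data[2:23, 2:23, 2:23]
    expect_lt(max(abs(interior - want) / want), 0.005)
  }
})

test_that("folded fields are masked and counted, not clamped", {
  g <- grid_geometry(c(10, 10, 10), c(1, 1, 1))
  # u_x = -2x reverses orientation everywhere: det = -1 -> degenerate
  f <- field_from_fun(g, function(X, Y, Z) list(-2 * X, Y * 0, Z * 0))
  expect_error(inverse_jacobian(f), "degenerate")
  # a mixed field errors only when everything folds
  half <- field_from_fun(g, function(X, Y, Z) list(-2 * X * (X < 4.5), Y * 0, Z * 0))
  Sh <- inverse_jacobian(half)
  expect_gt(attr(Sh, "n_nonpositive"), 0)
  expect_true(any(is.na(Sh$data)) && any(!is.na(Sh$data)))
})

test_that("self-registration returns a near-zero field", {
  ph <- tiny_phantom(seed = 2)
  d <- decompose(ph$insp_low_kv, ph$insp_high_kv, ph$spec$basis)
  f <- register(d$vnc, d$vnc)
  mags <- sqrt(f$vectors[, , , 1]^2 + f$vectors[, , , 2]^2 + f$vectors[, , , 3]^2)
  expect_lt(max(mags), 0.1)
})

test_that("a 3-voxel translation is recovered within 10 %", {
  ph <- tiny_phantom(seed = 2)
  d <- decompose(ph$insp_low_kv, ph$insp_high_kv, ph$spec$basis)
  arr <- d$vnc$data
  n1 <- dim(arr)[1]
  shifted <- array(-1000, dim(arr))
  shifted[4:n1, , ] <- arr[1:(n1 - 3), , ]
  mv <- scalar_volume(shifted, d$vnc$spacing, d$vnc$origin, "HU")
  f <- suppressWarnings(register(d$vnc, mv))
  true_ux <- 3 * d$vnc$spacing[1]
  lung <- ph$truth$lung_mask_insp
  expect_lt(abs(mean(f$vectors[, , , 1][lung]) - true_ux) / true_ux, 0.10)
})

test_that("phantom deformation is recovered well below the affine floor", {
  ph <- tiny_phantom(seed = 1)
  d <- decompose(ph$insp_low_kv, ph$insp_high_kv, ph$spec$basis)
  de <- decompose(ph$exp_low_kv, ph$exp_high_kv, ph$spec$basis)
  f <- register(de$vnc, d$vnc)
  du <- f$vectors - ph$truth$displacement_true$vectors
  em <- sqrt(du[, , , 1]^2 + du[, , , 2]^2 + du[, , , 3]^2)
  # the best any diagonal affine can achieve on this deformation is
  # ~2.1 mm mean (the sinusoidal residual); demons must beat that floor
  expect_lt(mean(em[ph$truth$lung_mask_exp]), 2.0)
  # warped inspiration lung overlaps the expiration lung truth
  lm <- scalar_volume(array(as.numeric(ph$truth$lung_mask_insp),
                            dim(ph$truth$lung_mask_insp)),
                      ph$spec$spacing, c(0, 0, 0), "label")
  wl <- warp(lm, ph$truth$displacement_true, "nearest")
  inter <- sum(wl$data > 0.5 & ph$truth$lung_mask_exp)
  dice <- 2 * inter / (sum(wl$data > 0.5) + sum(ph$truth$lung_mask_exp))
  expect_gt(dice, 0.95)
})

test_that("global volume consistency: field-integrated ratio matches mask counts", {
  ph <- tiny_phantom(seed = 1)
  tr <- ph$truth
  S <- inverse_jacobian(tr$displacement_true)
  # sum of 1/S over expiration-lung voxels estimates the inspiration volume
  est_insp <- sum(1 / S$data[tr$lung_mask_exp])
  expect_lt(abs(est_insp - sum(tr$lung_mask_insp)) / sum(tr$lung_mask_insp), 0.02)
})

test_that("landmark QC applies the 2 mm exclusion rule with strict inequality", {
  g <- grid_geometry(c(12, 12, 12), c(2, 2, 2))
  zero <- field_from_fun(g, function(X, Y, Z) list(X * 0, Y * 0, Z * 0))
  lm <- data.frame(fx = c(4, 10), fy = c(4, 10), fz = c(4, 10),
                   mx = c(4, 10), my = c(4, 10), mz = c(4, 10))
  qc <- registration_qc(zero, lm)
  expect_equal(qc$errors_mm, c(0, 0))
  expect_false(qc$exclude)
  lm25 <- lm; lm25$mx[2] <- 12.5                 # 2.5 mm residual
  expect_true(registration_qc(zero, lm25)$exclude)
  lm20 <- lm; lm20$mx[2] <- 12.0                 # exactly 2.0 mm
  qc20 <- registration_qc(zero, lm20)
  expect_equal(qc20$max_error_mm, 2.0)
  expect_false(qc20$exclude)
  expect_error(registration_qc(zero, lm[0, ]), "landmark")
})
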