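# Phantom generator: determinism, analytic ground truth, physics invariants,
# cohort generator.

test_that("identical seeds give bit-identical phantoms; different seeds differ", {
  a <- generate_phantom(phantom_spec(shape = c(40, 40, 40), spacing = c(5, 5, 5),
                                     seed = 11))
  b <- generate_phantom(phantom_spec(shape = c(40, 40, 40), spacing = c(5, 5, 5),
                                     seed = 11))
  c <- generate_phantom(phantom_spec(shape = c(40, 40, 40), spacing = c(5, 5, 5),
                                     seed = 12))
  expect_identical(a$insp_low_kv$data, b$insp_low_kv$data)
  expect_identical(a$truth$ventilation_true$data, b$truth$ventilation_true$data)
  expect_false(identical(a$insp_low_kv$data, c$insp_low_kv$data))
})

test_that("identity deformation with unchanged air gives zero ventilation", {
  sp <- phantom_spec(shape = c(40, 40, 40), spacing = c(5, 5, 5), seed = 3,
                     lambda = c(1, 1, 1), def_amp = c(0, 0, 0))
  ph <- generate_phantom(sp)
  tr <- ph$truth
  rv <- tr$ventilation_true$data[tr$parenchyma_exp]
  expect_lt(max(abs(rv)), 1e-9)
  expect_true(all(abs(tr$inv_jacobian_true$data - 1) < 1e-12))
})

test_that("forced expiratory collapse yields ventilation exactly 1", {
  sp <- phantom_spec(shape = c(40, 40, 40), spacing = c(5, 5, 5), seed = 4,
                     n_fibrosis = 0, laa = FALSE)
  # expiration-frame location of the inspiration lung centre: invert the
  # affine part of the deformation about the domain centre
  centre_e <- sp$center + (sp$lung_centers[[1]] - sp$center) / sp$lambda
  sp2 <- phantom_spec(shape = c(40, 40, 40), spacing = c(5, 5, 5), seed = 4,
                      n_fibrosis = 0, laa = FALSE,
                      atelectasis_regions = list(
                        list(center = centre_e, semi = c(12, 12, 12))))
  ph <- generate_phantom(sp2)
  tr <- ph$truth
  inside <- tr$collapse_exp
  expect_gt(sum(inside), 20)
  expect_true(all(tr$ventilation_true$data[inside] == 1))
  expect_true(all(tr$air_exp_true$data[inside] == 0))
})

test_that("uniform 1.25x contraction gives analytic inverse Jacobian 0.512", {
  sp <- phantom_spec(shape = c(40, 40, 40), spacing = c(5, 5, 5), seed = 5,
                     alpha0 = 0.92, alpha_amp = 0, n_fibrosis = 0, laa = FALSE,
                     lambda = c(1.25, 1.25, 1.25), def_amp = c(0, 0, 0))
  ph <- generate_phantom(sp)
  S <- ph$truth$inv_jacobian_true$data
  expect_true(all(abs(S - 0.512) < 1e-12))
})

test_that("tissue mass conservation and the ventilation identity hold", {
  ph <- tiny_phantom(seed = 1)
  tr <- ph$truth
  par_e <- tr$parenchyma_exp
  # per-voxel: tissue_exp = J * tissue_insp(phi)  <=>  tissue_exp * S = tissue at phi
  tis_e <- tr$tissue_exp_true$data[par_e]
  S <- tr$inv_jacobian_true$data[par_e]
  tis_ip <- 1 - tr$air_insp_warped_true$data[par_e]
  expect_lt(max(abs(tis_e * S - tis_ip)), 1e-9)
  # voxel-integrated tissue of the two phases: the midpoint quadrature on
  # the two grids converges to equality (0.35 % at 48^3, 0.2 % at 96^3,
  # 0.03 % at 128^3); assert < 0.1 % where quadrature error no longer
  # dominates, plus monotone shrinkage with refinement
  rel_at <- function(ph2) {
    t2 <- ph2$truth
    ve <- sum(t2$tissue_exp_true$data[t2$parenchyma_exp])
    vi <- sum(t2$tissue_insp_true$data[t2$parenchyma_insp])
    (ve - vi) / vi
  }
  r48 <- rel_at(ph)
  r128 <- rel_at(generate_phantom(phantom_spec(shape = rep(128L, 3),
                                               spacing = rep(1.875, 3),
                                               seed = 1)))
  expect_lt(abs(r128), 1e-3)
  expect_lt(abs(r128), abs(r48))
  # ventilation identity: RV = 1 - S * air_exp / air_insp_warped
  rv <- tr$ventilation_true$data[par_e]
  ae <- tr$air_exp_true$data[par_e]
  ai <- tr$air_insp_warped_true$data[par_e]
  expect_lt(max(abs(rv - (1 - S * ae / ai))), 1e-6)
  expect_true(all(rv >= 0 & rv < 1))
})

test_that("infeasible specs are rejected", {
  # contraction so strong the fibrotic tissue cannot fit -> negative air
  expect_error(generate_phantom(
    phantom_spec(shape = c(40, 40, 40), spacing = c(5, 5, 5), seed = 6,
                 lambda = c(1.3, 1.3, 1.6), fibrosis_depth = 0.55)),
    "infeasible")
  expect_error(phantom_spec(lambda = c(0.9, 1, 1)), "lambda")
})

test_that("healthy specs are deterministic and land in the published band", {
  s1 <- generate_healthy_spec(1, shape = c(48, 48, 48), spacing = c(5, 5, 5))
  s2 <- generate_healthy_spec(1, shape = c(48, 48, 48), spacing = c(5, 5, 5))
  expect_identical(s1$lambda, s2$lambda)
  expect_identical(s1$def_phase, s2$def_phase)
  for (sd in 1:3) {
    hp <- generate_phantom(generate_healthy_spec(sd, shape = c(48, 48, 48),
                                                 spacing = c(5, 5, 5)))
    mv <- hp$truth$stats$mean_ventilation_functional
    expect_gte(mv, 0.40); expect_lte(mv, 0.50)
  }
})

test_that("cohort generator: determinism, planted correlation, degeneracy, size", {
  a <- generate_cohort(32, -0.5, 0.04, seed = 9)
  b <- generate_cohort(32, -0.5, 0.04, seed = 9)
  expect_identical(a, b)
  expect_equal(nrow(a), 32L)
  expect_equal(sum(is.na(a$dlco_pct_baseline)), 6L)   # 26 of 32 usable

  big <- generate_cohort(1000, -0.99, 0.04, seed = 1)
  ratio <- annualize_ratio(big$lung_volume_ml_baseline,
                           big$lung_volume_ml_followup, big$interval_days)
  expect_lt(cor(big$ventilation_baseline, ratio), -0.9)

  expect_warning(dg <- generate_cohort(8, 0, 0, seed = 2), "degenerate")
  expect_true(attr(dg, "degenerate"))
  r0 <- annualize_ratio(dg$lung_volume_ml_baseline, dg$lung_volume_ml_followup,
                        dg$interval_days)
  expect_lt(diff(range(r0)), 1e-12)

  expect_error(generate_cohort(3), ">= 4")
  expect_error(generate_cohort(10, planted_r = 1), "planted_r")
})
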