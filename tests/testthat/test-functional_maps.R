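# Air content, regional ventilation, vascular normalization, orchestration.

test_that("air content is the linear HU map with clamping", {
  v <- scalar_volume(array(c(-1000, 0, -742.23, -500, 100, -1024, -250, -800),
                           c(2, 2, 2)), unit = "HU")
  a <- air_content(v)
  expect_equal(a$data[1, 1, 1], 1)
  expect_equal(a$data[2, 1, 1], 0)
  expect_equal(a$data[1, 2, 1], 0.74223)
  expect_equal(a$data[2, 2, 1], 0.5)
  expect_equal(a$data[1, 1, 2], 0)        # positive HU clamps to 0
  expect_identical(a$unit, "fraction")
  # monotone decreasing in HU
  hu <- array(seq(-1000, 0, length.out = 20), c(20, 2, 2))
  av <- air_content(scalar_volume(hu, unit = "HU"))
  expect_true(all(diff(av$data[, 1, 1]) <= 0))
})

test_that("regional ventilation reproduces the equation endpoints and arithmetic", {
  g <- grid_geometry(c(4, 4, 4))
  mk <- function(x, unit = "fraction") scalar_volume(array(x, g$shape), unit = unit)
  S1 <- mk(1, "dimensionless")
  # S = 1, alpha_exp = alpha_insp -> 0
  rv0 <- regional_ventilation(S1, mk(0.8), mk(0.8))
  expect_lt(max(abs(rv0$data)), 1e-12)
  # alpha_exp = 0 -> 1 (total expiratory collapse)
  rv1 <- regional_ventilation(S1, mk(0), mk(0.8))
  expect_true(all(rv1$data == 1))
  # S = 0.6, 0.5 / 0.75 -> 0.6
  rv <- regional_ventilation(mk(0.6, "dimensionless"), mk(0.5), mk(0.75))
  expect_equal(rv$data[1], 0.6, tolerance = 1e-12)
  # masking: near-airless inspiration voxels and invalid S become NA
  ai <- array(0.8, g$shape); ai[1, 1, 1] <- 0.001
  Sna <- array(0.6, g$shape); Sna[2, 2, 2] <- NA
  rvm <- regional_ventilation(scalar_volume(Sna, unit = "dimensionless"),
                              mk(0.5), scalar_volume(ai, unit = "fraction"))
  expect_true(is.na(rvm$data[1, 1, 1]))
  expect_true(is.na(rvm$data[2, 2, 2]))
  expect_equal(attr(rvm, "fraction_masked"), 2 / 64)
  # no clamping: out-of-range values survive and are reported
  rvo <- regional_ventilation(mk(1.4, "dimensionless"), mk(0.8), mk(0.8))
  expect_lt(max(rvo$data), 0)
  expect_equal(attr(rvo, "fraction_outside_01"), 1)
})

test_that("vascular normalization is definitional, unclipped and scale-invariant", {
  g <- grid_geometry(c(6, 6, 6))
  pb <- array(10, g$shape)
  lab <- array(0, g$shape)
  lab[1:2, 1, 1] <- 1; lab[3:4, 1, 1] <- 2
  pb[1:2, 1, 1] <- 400; pb[3:4, 1, 1] <- 600    # mean-of-means reference 500
  pb[6, 6, 6] <- 500; pb[5, 5, 5] <- 250; pb[4, 4, 4] <- 650
  pbv <- scalar_volume(pb, unit = "iodine_HU")
  roi <- scalar_volume(lab, unit = "label")
  out <- normalize_to_vascular(pbv, roi)
  expect_equal(attr(out, "vascular_reference"), 500)
  expect_equal(out$data[6, 6, 6], 100)
  expect_equal(out$data[5, 5, 5], 50)
  expect_equal(out$data[4, 4, 4], 130)          # > 100 preserved
  # scale invariance
  pbv2 <- scalar_volume(pb * 3.7, unit = "iodine_HU")
  out2 <- normalize_to_vascular(pbv2, roi)
  expect_lt(max(abs(out2$data - out$data)), 1e-9)
  # guards
  lab_missing <- lab; lab_missing[lab_missing == 2] <- 0
  expect_error(normalize_to_vascular(pbv, scalar_volume(lab_missing, unit = "label")),
               "labels")
  expect_error(normalize_to_vascular(scalar_volume(pb * 0, unit = "iodine_HU"), roi),
               "non-positive")
})

test_that("end-to-end maps with the truth field recover ventilation (MAE < 0.02)", {
  ph <- tiny_phantom(seed = 1)
  tr <- ph$truth
  pp <- pbv_pair(list(low = ph$insp_low_kv, high = ph$insp_high_kv),
                 list(low = ph$exp_low_kv, high = ph$exp_high_kv), ph$spec$basis)
  maps <- build_functional_maps(pp$vnc_insp, pp$vnc_exp, pp$pbv_insp,
                                pp$pbv_delayed, tr$displacement_true,
                                tr$vessel_roi_insp, tr$vessel_roi_exp)
  fmask <- band_region_mask(tr$band_map_exp, "functional")
  err <- abs(maps$ventilation$data - tr$ventilation_true$data)
  expect_lt(mean(err[fmask], na.rm = TRUE), 0.02)
  # air-volume bookkeeping: 1 - RV = S * air_exp / air_insp where alpha > 0.05
  ok <- tr$parenchyma_exp & tr$air_insp_warped_true$data > 0.05 &
    is.finite(maps$ventilation$data)
  lhs <- 1 - tr$ventilation_true$data[ok]
  rhs <- tr$inv_jacobian_true$data[ok] * tr$air_exp_true$data[ok] /
    tr$air_insp_warped_true$data[ok]
  expect_lt(max(abs(lhs - rhs)), 1e-3)
  # late enhancement in fibrotic blobs exceeds 100 % and stays unclipped
  expect_gt(max(maps$late_enhancement$data[fmask]), 100)
})

test_that("ventilation is invariant to the shared decomposition basis", {
  rv_for_basis <- function(tissue, iodine) {
    B <- decomposition_basis(tissue, iodine)
    ph <- tiny_phantom(seed = 3, basis = B)
    pp <- pbv_pair(list(low = ph$insp_low_kv, high = ph$insp_high_kv),
                   list(low = ph$exp_low_kv, high = ph$exp_high_kv), B)
    maps <- build_functional_maps(pp$vnc_insp, pp$vnc_exp, pp$pbv_insp,
                                  pp$pbv_delayed, ph$truth$displacement_true,
                                  ph$truth$vessel_roi_insp, ph$truth$vessel_roi_exp)
    maps$ventilation$data
  }
  rv1 <- rv_for_basis(c(1, 1), c(2, 1))
  rv2 <- rv_for_basis(c(1, 0.9), c(2.4, 1.1))
  expect_lt(max(abs(rv1 - rv2), na.rm = TRUE), 1e-6)
})

test_that("zero-iodine phantom raises a normalization error", {
  sp <- phantom_spec(shape = c(40, 40, 40), spacing = c(5, 5, 5), seed = 8,
                     iodine = list(perf_base = 0, perf_grad = 0, perf_haa_boost = 0,
                                   delayed_base = 0, delayed_haa_amp = 0,
                                   vessel_arterial = 0, vessel_delayed = 0,
                                   roi_arterial = c(pa = 0, ao = 0),
                                   roi_delayed = c(pa = 0, ao = 0)))
  ph <- generate_phantom(sp)
  pp <- pbv_pair(list(low = ph$insp_low_kv, high = ph$insp_high_kv),
                 list(low = ph$exp_low_kv, high = ph$exp_high_kv), sp$basis)
  expect_error(
    build_functional_maps(pp$vnc_insp, pp$vnc_exp, pp$pbv_insp, pp$pbv_delayed,
                          ph$truth$displacement_true, ph$truth$vessel_roi_insp,
                          ph$truth$vessel_roi_exp),
    "non-positive")
})
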