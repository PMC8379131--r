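# NIfTI I/O, geometry and resampling.

test_that("volume round trip preserves data, spacing, origin and unit", {
  v <- scalar_volume(array(rnorm(16^3), c(16, 16, 16)),
                     spacing = c(0.68, 0.68, 1.0), origin = c(-5, 3, 12),
                     unit = "fraction")
  p <- tempfile(fileext = ".nii.gz")
  write_volume(v, p)
  r <- read_volume(p, "fraction")
  expect_equal(r$data, v$data, tolerance = 1e-6)       # float32 storage
  expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
  expect_equal(r$origin, v$origin, tolerance = 1e-6)
  expect_identical(r$unit, "fraction")
  # zero volume at unit spacing is exactly reproduced
  z <- scalar_volume(array(0, c(16, 16, 16)))
  pz <- tempfile(fileext = ".nii")
  write_volume(z, pz)
  expect_identical(read_volume(pz, "dimensionless")$data, z$data)
})

test_that("HU volumes are clipped to [-1024, 3071] on load", {
  arr <- array(-800, c(8, 8, 8))
  arr[3, 3, 3] <- -2000
  arr[4, 4, 4] <- 5000
  p <- tempfile(fileext = ".nii")
  write_volume(scalar_volume(arr, unit = "dimensionless"), p)   # write raw
  r <- read_volume(p, "HU")
  expect_equal(r$data[3, 3, 3], -1024)
  expect_equal(r$data[4, 4, 4], 3071)
  expect_equal(r$data[1, 1, 1], -800)
})

test_that("displacement field round trip keeps component order and labels stay integer", {
  g <- grid_geometry(c(10, 12, 14), c(1, 2, 3), c(0, 0, 0))
  u <- field_from_fun(g, function(X, Y, Z) list(X * 0.1, Y * 0.2, Z * 0.3))
  p <- tempfile(fileext = ".nii.gz")
  write_field(u, p)
  r <- read_field(p)
  expect_equal(r$vectors, u$vectors, tolerance = 1e-5)
  expect_equal(r$spacing, u$spacing, tolerance = 1e-6)
  # components must not be permuted
  expect_gt(max(r$vectors[, , , 3]), max(r$vectors[, , , 1]))

  lab <- scalar_volume(array(sample(0:4, 8^3, TRUE), c(8, 8, 8)), unit = "label")
  pl <- tempfile(fileext = ".nii")
  write_volume(lab, pl)
  rl <- read_volume(pl, "label")
  expect_identical(rl$data, lab$data)   # int32 storage: exact
})

test_that("read_volume rejects missing files, wrong rank and non-finite voxels", {
  expect_error(read_volume(tempfile(fileext = ".nii"), "HU"), "not found")
  # 4D image (a vector field) is not a scalar volume
  g <- grid_geometry(c(6, 6, 6))
  u <- field_from_fun(g, function(X, Y, Z) list(X * 0, Y * 0, Z * 0))
  p4 <- tempfile(fileext = ".nii")
  write_field(u, p4)
  expect_error(read_volume(p4, "HU"), "3D")
  # NaN voxels
  arr <- array(0, c(6, 6, 6)); arr[2, 2, 2] <- NaN
  pn <- tempfile(fileext = ".nii")
  vplct:::write_nifti_raw(arr, c(1, 1, 1), c(0, 0, 0), pn, 16L)
  expect_error(read_volume(pn, "fraction"), "non-finite")
})

test_that("nibabel reads our files and we read nibabel's (format oracle)", {
  skip_if(python_bin == "", "python not on PATH")
  v <- scalar_volume(array(seq_len(6^3) * 1.0, c(6, 6, 6)),
                     spacing = c(0.68, 0.68, 1.0), origin = c(1, 2, 3),
                     unit = "dimensionless")
  p <- tempfile(fileext = ".nii")
  write_volume(v, p)
  out <- system2(python_bin, c("-c", shQuote(sprintf(
    "import nibabel as nib, numpy as np; im = nib.load('%s'); d = np.asarray(im.dataobj); print(d.shape, float(d[1,2,3]), [round(float(z),4) for z in im.header.get_zooms()])",
    p))), stdout = TRUE)
  expect_match(out, "(6, 6, 6)", fixed = TRUE)
  expect_match(out, as.character(v$data[2, 3, 4]), fixed = TRUE)
  expect_match(out, "0.68", fixed = TRUE)
  # nibabel-written LPS-flipped volume is reoriented to RAS on read
  p2 <- tempfile(fileext = ".nii")
  code <- sprintf(paste0(
    "import nibabel as nib, numpy as np\n",
    "d = np.arange(24, dtype=np.float32).reshape(2, 3, 4, order='F')\n",
    "aff = np.diag([-1.0, 1.0, 2.0, 1.0]); aff[0, 3] = 1.0\n",
    "nib.save(nib.Nifti1Image(d, aff), '%s')\n"), p2)
  writeLines(code, f <- tempfile(fileext = ".py"))
  system2(python_bin, f)
  r <- read_volume(p2, "dimensionless")
  # x axis flipped: world-x increases along reversed first index
  expect_equal(dim(r$data), c(2L, 3L, 4L))
  expect_equal(r$spacing, c(1, 1, 2))
  ref <- array(as.numeric(0:23), c(2, 3, 4))
  expect_equal(r$data, ref[2:1, , ])
  expect_equal(r$origin[1], 0)   # world x of flipped first voxel
})

test_that("resampling: identity, constants, analytic ramp and label guard", {
  v <- scalar_volume(array(rnorm(12^3), c(12, 12, 12)), spacing = c(1, 1, 1))
  same <- resample_to_grid(v, geometry_of(v), "linear")
  expect_equal(same$data, v$data, tolerance = 1e-12)

  cst <- const_volume(7, c(9, 9, 9))
  tgt <- grid_geometry(c(5, 7, 11), c(1.7, 0.9, 0.6), c(0.3, 0.2, 0.1))
  rc <- resample_to_grid(cst, tgt, "linear")
  expect_true(all(abs(rc$data - 7) < 1e-9))

  # ramp f(x) = 2x along world-x, downsample by 2: interior exact
  g <- grid_geometry(c(16, 8, 8))
  ramp <- scalar_volume(eval_on_grid_test(g, function(X, Y, Z)
    list(2 * X, Y * 0, Z * 0))[, , , 1], g$spacing, g$origin)
  tgt2 <- grid_geometry(c(8, 8, 8), c(2, 1, 1))
  rr <- resample_to_grid(ramp, tgt2, "linear")
  want <- eval_on_grid_test(tgt2, function(X, Y, Z) list(2 * X, Y, Z))[, , , 1]
  expect_equal(rr$data[2:7, 2:7, 2:7], want[2:7, 2:7, 2:7], tolerance = 1e-6)
  # linear resampling never exceeds source bounds
  expect_gte(min(rr$data), min(ramp$data) - 1e-9)
  expect_lte(max(rr$data), max(ramp$data) + 1e-9)

  lab <- scalar_volume(array(1, c(8, 8, 8)), unit = "label")
  expect_error(resample_to_grid(lab, tgt, "linear"), "nearest")
  expect_silent(resample_to_grid(lab, geometry_of(lab), "nearest"))
})

test_that("phantom export carries the clinical header spacing", {
  # miniature grid at clinical voxel size; structure radii scaled to fit
  sp <- phantom_spec(shape = c(16, 16, 16), spacing = c(0.68, 0.68, 1.0),
                     seed = 2, n_fibrosis = 0, laa = FALSE,
                     def_amp = c(0.05, 0.05, 0.08),
                     iodine = list(vessel_radius_mm = 0.5, roi_radius_mm = 1.2,
                                   roi_label_radius_mm = 0.8))
  ph <- generate_phantom(sp)
  p <- tempfile(fileext = ".nii.gz")
  write_volume(ph$insp_low_kv, p)
  r <- read_volume(p, "HU")
  expect_equal(r$spacing, c(0.68, 0.68, 1.0), tolerance = 1e-6)
})
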