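test_that("resampling onto the source grid is the identity", {
  set.seed(3)
  g <- voxel_grid(c(-2, -1, 0), c(0.5, 0.7, 1), c(8, 7, 6))
  vol <- image_volume(g, array(runif(8 * 7 * 6, 0, 10), c(8, 7, 6)), "dose_gy")
  expect_lt(max(abs(resample(vol, g)$values - vol$values)), 1e-12)
  m <- array(0L, c(8, 7, 6)); m[3:5, 2:4, 1:3] <- 1L
  sm <- structure_mask(g, list(body = m))
  expect_identical(resample(sm, g)$labels$body, sm$labels$body * 1)
})

test_that("resampling preserves constants, bounds and mask binarity", {
  g1 <- voxel_grid(c(0, 0, 0), 1, c(10, 10, 10))
  g2 <- voxel_grid(c(1.3, 2.1, 0.7), 0.6, c(9, 9, 9))  # interior of g1
  const <- image_volume(g1, array(7, c(10, 10, 10)), "dose_gy")
  expect_equal(resample(const, g2)$values, array(7, c(9, 9, 9)),
               tolerance = 1e-12)
  set.seed(4)
  v <- image_volume(g1, array(runif(1000, 2, 9), c(10, 10, 10)), "dose_gy")
  rv <- resample(v, g2)$values
  expect_gte(min(rv), min(v$values))  # trilinear never overshoots
  expect_lte(max(rv), max(v$values))
  m <- array((runif(1000) < 0.4) * 1, c(10, 10, 10))
  rm_ <- resample(structure_mask(g1, list(PTV = m)), g2)$labels$PTV
  expect_true(all(rm_ %in% c(0, 1)))
  # nearest never invents labels: an empty mask stays empty
  rm0 <- resample(structure_mask(g1, list(PTV = m * 0)), g2)$labels$PTV
  expect_true(all(rm0 == 0))
  # trilinear is refused for masks
  expect_error(resample(structure_mask(g1, list(PTV = m)), g2, "trilinear"),
               "nearest")
})

test_that("out-of-grid points take kind-specific fill values", {
  g1 <- voxel_grid(c(0, 0, 0), 1, c(4, 4, 4))
  far <- voxel_grid(c(20, 20, 20), 1, c(3, 3, 3))
  ct <- image_volume(g1, array(100, c(4, 4, 4)), "ct_hu")
  expect_true(all(resample(ct, far)$values == -1000))
  dd <- image_volume(g1, array(5, c(4, 4, 4)), "dose_gy")
  expect_true(all(resample(dd, far)$values == 0))
})

test_that("assemble_sample builds a cubic co-registered sample", {
  case <- tiny_case()
  ph <- case$phantom
  smp <- case$sample
  expect_identical(smp$ct$grid$dims, rep(24L, 3))
  expect_true(logdoseqa:::same_grid(smp$ct$grid, smp$projected$grid))
  expect_true(logdoseqa:::same_grid(smp$ct$grid, smp$masks$grid))
  # desk-scale n: different cube size on request
  smp32 <- assemble_sample(ph$ct, ph$masks, case$projected, case$reference,
                           case$plan$prescription_dose, n = 32)
  expect_identical(smp32$ct$grid$dims, rep(32L, 3))
  # PTV volume approximately conserved when resampling from a fine source
  # (desk-scale 1-cm voxels quantize a 2-cm sphere too coarsely for this)
  ph96 <- make_phantom(phantom_spec(dims = 96, spacing = 0.25))
  z96 <- image_volume(ph96$ct$grid, array(0, ph96$ct$grid$dims), "projected")
  r96 <- image_volume(ph96$ct$grid, array(1, ph96$ct$grid$dims), "dose_gy")
  smp48 <- assemble_sample(ph96$ct, ph96$masks, z96, r96, 60, n = 48)
  expect_identical(smp48$ct$grid$dims, rep(48L, 3))
  vox_vol <- prod(smp48$masks$grid$spacing)
  analytic <- 4 / 3 * pi * 2^3
  expect_lt(abs(sum(smp48$masks$labels$PTV) * vox_vol - analytic) / analytic, 0.1)
  # idempotent: re-assembling an assembled sample changes nothing
  again <- assemble_sample(smp$ct, smp$masks, smp$projected,
                           smp$reference_dose, smp$prescription_dose, n = 24)
  expect_identical(again$ct$values, smp$ct$values)
  expect_identical(again$reference_dose$values, smp$reference_dose$values)
  # a missing body mask is fatal
  nb <- structure_mask(ph$masks$grid, list(PTV = ph$masks$labels$PTV))
  expect_error(assemble_sample(ph$ct, nb, case$projected, case$reference,
                               60, n = 24), "body")
})

test_that("model normalization maps endpoints correctly and inverts exactly", {
  case <- tiny_case()
  nz <- normalize_for_model(case$sample)
  expect_gte(min(nz$ct), 0); expect_lte(max(nz$ct), 1)
  # CT endpoint mapping on a minimal cubic sample
  g <- voxel_grid(0, 1, c(2, 2, 2))
  s <- model_sample(
    image_volume(g, array(c(-1000, 1000, rep(0, 6)), c(2, 2, 2)), "ct_hu"),
    image_volume(g, array(0, c(2, 2, 2)), "projected"),
    image_volume(g, array(60, c(2, 2, 2)), "dose_gy"),
    structure_mask(g, list(body = array(1, c(2, 2, 2)))), 60)
  nz2 <- normalize_for_model(s)
  expect_equal(as.numeric(nz2$ct)[1:2], c(0, 1))
  expect_true(all(nz2$dose == 1))  # dose == prescription -> 1
  expect_true(all(nz2$projected == 0))         # all-zero projected stays 0
  back <- denormalize_dose(nz$dose, case$sample$prescription_dose)
  expect_lt(max(abs(back - case$sample$reference_dose$values)), 1e-12)
})

test_that("NIfTI volumes round-trip bitwise with grid geometry", {
  set.seed(9)
  g <- voxel_grid(c(-3.2, 0.4, 1.0), c(0.4, 0.5, 0.6), c(7, 6, 5))
  vol <- image_volume(g, array(runif(210, 0, 70), c(7, 6, 5)), "dose_gy")
  for (ext in c(".nii", ".nii.gz")) {
    f <- tempfile(fileext = ext)
    write_nifti(vol, f)
    back <- read_nifti(f, kind = "dose_gy")
    expect_identical(back$values, vol$values)
    expect_equal(back$grid$spacing, g$spacing, tolerance = 1e-6)
    expect_equal(back$grid$origin, g$origin, tolerance = 1e-5)
    unlink(f)
  }
  # mask sets round-trip through per-ROI files
  m <- array((runif(210) < 0.5) * 1, c(7, 6, 5))
  masks <- structure_mask(g, list(PTV = m, body = array(1, c(7, 6, 5))))
  d <- tempfile()
  write_mask_set(masks, d)
  back <- read_mask_set(d)
  expect_identical(back$labels$PTV, m)
  expect_setequal(names(back$labels), c("PTV", "body"))
  unlink(d, recursive = TRUE)
})

test_that("written NIfTI is readable by an independent implementation", {
  # nibabel (Python) acts as the format oracle on a tiny fixture
  g <- voxel_grid(c(-1, 0, 2.5), c(0.4, 0.4, 0.8), c(4, 3, 2))
  vals <- array(seq_len(24) * 1.5, c(4, 3, 2))
  f <- tempfile(fileext = ".nii.gz")
  write_nifti(image_volume(g, vals, "dose_gy"), f)
  script <- paste0(
    "import nibabel, numpy as np, json\n",
    "img = nibabel.load('", f, "')\n",
    "a = np.asarray(img.dataobj)\n",
    "print(json.dumps({'shape': list(img.shape),",
    " 'sum': float(a.sum()), 'v210': float(a[1, 0, 1]),",
    " 'diag': np.diag(img.affine)[:3].tolist(),",
    " 'origin': img.affine[:3, 3].tolist()}))\n")
  out <- system2("python", "-", input = script, stdout = TRUE, stderr = TRUE)
  info <- jsonlite::fromJSON(out[length(out)])
  expect_equal(info$shape, c(4, 3, 2))
  expect_equal(info$sum, sum(vals))
  expect_equal(info$v210, vals[2, 1, 2])        # Fortran-order agreement
  expect_equal(info$diag, g$spacing * 10, tolerance = 1e-6)   # cm -> mm
  expect_equal(info$origin, g$origin * 10, tolerance = 1e-5)
  unlink(f)
})
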