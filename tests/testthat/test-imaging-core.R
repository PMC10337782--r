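test_that("decay correction follows the half-life law", {
  expect_equal(decay_correct(100, 0, 67.71), 100)
  expect_equal(decay_correct(100, 67.71, 67.71), 50)
  # independent oracle: exp(-ln2 * t / T)
  expect_equal(decay_correct(173, 32, 67.71),
               173 * exp(-log(2) * 32 / 67.71), tolerance = 1e-12)
  expect_equal(decay_correct(173, 32, 67.71), 124.67, tolerance = 1e-4)
  expect_error(decay_correct(100, 10, 0), "half_life")
  expect_error(decay_correct(100, -1), ">= 0")
})

test_that("SUV conversion is definitional and linear", {
  meta <- injection_meta(173, 70, injection_to_scan_min = 32)
  conc <- array(10e3, dim = c(4, 4, 4))   # 10 kBq/ml
  vol <- pet_volume(conc, c(4, 4, 4), value_kind = "BQML")
  suv <- to_suv(vol, meta)
  expect_equal(suv$value_kind, "SUV")
  expect_equal(suv$values[1], 10e3 * 70e3 / 173e6, tolerance = 1e-9)
  expect_equal(suv$values[1], 4.046, tolerance = 1e-3)

  # uniform body: activity A in weight kg at 1 g/ml -> SUV 1 everywhere
  a_bq <- 173e6
  conc_uniform <- a_bq / (70 * 1000)   # Bq per ml over the whole body mass
  volu <- pet_volume(array(conc_uniform, dim = c(3, 3, 3)), c(2, 2, 2),
                     value_kind = "BQML")
  expect_equal(max(abs(to_suv(volu, meta)$values - 1)), 0, tolerance = 1e-6)

  # zero concentration stays zero; linear in concentration, inverse in activity
  vol0 <- pet_volume(array(0, dim = c(2, 2, 2)), c(2, 2, 2), value_kind = "BQML")
  expect_equal(unique(as.vector(to_suv(vol0, meta)$values)), 0)
  v2 <- pet_volume(2 * conc, c(4, 4, 4), value_kind = "BQML")
  expect_equal(to_suv(v2, meta)$values, 2 * suv$values)
  meta2 <- injection_meta(2 * 173, 70)
  expect_equal(to_suv(vol, meta2)$values, suv$values / 2)

  # SCAN reference divides by the decayed (smaller) activity -> larger SUV
  suv_scan <- to_suv(vol, meta, decay_reference = "SCAN")
  expect_equal(suv_scan$values[1],
               suv$values[1] / 2^(-32 / 67.71), tolerance = 1e-12)
  expect_error(to_suv(suv, meta), "BQML")
})

test_that("NIfTI round-trip preserves values, spacing and origin", {
  set.seed(42)
  vals <- array(rnorm(32^3), dim = c(32, 32, 32))
  vol <- pet_volume(vals, spacing = c(4, 4, 2), origin = c(10, -5, 2.5))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f, "SUV")
  expect_equal(back$values, vals, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$spacing, c(4, 4, 2))
  expect_equal(back$origin, c(10, -5, 2.5))

  m <- voi_mask(array(vals > 0, dim = dim(vals)), "AORTA")
  fm <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(m, fm, spacing = c(4, 4, 2))
  back_m <- read_mask(fm, "AORTA")
  expect_identical(back_m$mask, m$mask)
})

test_that("mask volume uses physical voxel size and grids must align", {
  # 1000 voxels at 4x4x2 mm = 32 ml
  m <- array(FALSE, dim = c(20, 20, 20))
  m[seq_len(1000)] <- TRUE
  expect_equal(mask_volume_ml(voi_mask(m), c(4, 4, 2)), 32)

  vol <- pet_volume(array(6, dim = c(8, 8, 8)), c(2, 2, 2))
  bad <- voi_mask(array(TRUE, dim = c(8, 8, 4)), "LEFT_KIDNEY")
  expect_error(segment_parenchyma(vol, bad), "alignment")
})

test_that("injection metadata round-trips through its JSON sidecar", {
  meta <- injection_meta(173, 69.3, body_height_cm = 166.4,
                         injection_to_scan_min = 32)
  f <- withr::local_tempfile(fileext = ".json")
  write_injection_meta(meta, f)
  back <- read_injection_meta(f)
  expect_equal(back, meta)
  expect_error(injection_meta(0, 70), "positive")
  expect_error(injection_meta(100, 70, injection_to_scan_min = -1), ">= 0")
})
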