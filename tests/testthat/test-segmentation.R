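test_that("segmentation equals brute-force per-voxel filtering (oracle)", {
  for (seed in 1:5) {
    fx <- random_suv_volume(n = 12, seed = seed)
    km <- segment_parenchyma(fx$volume, fx$voi)
    # brute force: explicit loop over every voxel
    d <- dim(fx$volume$values)
    expected <- array(FALSE, dim = d)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      s <- fx$volume$values[i, j, k]
      expected[i, j, k] <- fx$voi$mask[i, j, k] && s >= 5 && s <= 15
    }
    expect_identical(km$mask$mask, expected)
    expect_equal(km$voxel_count, sum(expected))
    if (any(expected))
      expect_equal(km$suv_mean, mean(fx$volume$values[expected]),
                   tolerance = 1e-12)
  }
})

test_that("both thresholds are inclusive at exactly 5.0 and 15.0", {
  v <- array(1, dim = c(5, 5, 1))
  v[1:4] <- c(4.999, 5.0, 15.0, 15.001)
  vol <- pet_volume(v, c(2, 2, 2))
  voi <- voi_mask(array(TRUE, dim = dim(v)), "LEFT_KIDNEY")
  km <- segment_parenchyma(vol, voi)
  expect_identical(which(km$mask$mask), c(2L, 3L))
})

test_that("noiseless phantom parenchyma is recovered, urine and background excluded", {
  ph <- clean_phantom()
  tr <- ph$truth
  for (side in c("left", "right")) {
    km <- segment_parenchyma(ph$volume, ph$vois[[side]])
    expect_equal(km$parenchymal_volume_ml,
                 tr$kidneys[[side]]$parenchymal_volume_ml, tolerance = 0.05)
    expect_equal(km$suv_mean, tr$kidneys[[side]]$suv_mean, tolerance = 0.01)
    # no pelvicocaliceal (SUV > 15) and no background voxels selected
    expect_equal(sum(km$mask$mask & tr$masks[[paste0(side, "_core")]]), 0)
    expect_equal(sum(km$mask$mask &
                       !tr$masks[[paste0(side, "_parenchyma")]]), 0)
  }
})

test_that("segmentation properties: subset, monotonicity, idempotence", {
  fx <- random_suv_volume(n = 14, seed = 9)
  base <- segment_parenchyma(fx$volume, fx$voi)
  expect_true(all(!base$mask$mask | fx$voi$mask))   # mask subset of VOI
  # raising lower / lowering upper never adds voxels
  tighter1 <- segment_parenchyma(fx$volume, fx$voi, isocontour_params(7, 15))
  tighter2 <- segment_parenchyma(fx$volume, fx$voi, isocontour_params(5, 12))
  expect_lte(tighter1$voxel_count, base$voxel_count)
  expect_lte(tighter2$voxel_count, base$voxel_count)
  # idempotence: re-segmenting with the output mask as VOI is identical
  again <- segment_parenchyma(fx$volume, base$mask)
  expect_identical(again$mask$mask, base$mask$mask)
})

test_that("degenerate kidney VOIs are flagged, not zero-filled", {
  vol <- pet_volume(array(1, dim = c(6, 6, 6)), c(2, 2, 2))
  voi <- voi_mask(array(TRUE, dim = c(6, 6, 6)), "RIGHT_KIDNEY")
  km <- segment_parenchyma(vol, voi)
  expect_equal(km$voxel_count, 0)
  expect_true(is.na(km$suv_mean))
  expect_true("EMPTY_SEGMENTATION" %in% km$flags)

  # constant field inside the band: SUVmean exact, volume = k * voxel vol
  vol10 <- pet_volume(array(10, dim = c(6, 6, 6)), c(2, 2, 2))
  km10 <- segment_parenchyma(vol10, voi)
  expect_equal(km10$suv_mean, 10)
  expect_equal(km10$parenchymal_volume_ml, 216 * voxel_volume_ml(c(2, 2, 2)))

  expect_error(segment_parenchyma(
    pet_volume(array(1, dim = c(2, 2, 2)), c(1, 1, 1), value_kind = "BQML"),
    voi_mask(array(TRUE, dim = c(2, 2, 2)))), "unit")
  expect_error(isocontour_params(15, 5), "strictly below")
})

test_that("blood-pool measurement enforces the 5 ml protocol minimum", {
  ph <- clean_phantom()
  bp <- measure_blood_pool(ph$volume, ph$vois$aorta)
  expect_equal(bp$suv_mean, 2.5, tolerance = 0.01)
  expect_gte(bp$volume_ml, 5)

  # 4 ml VOI at 2 mm spacing = 500 voxels
  small <- array(FALSE, dim = dim(ph$volume$values))
  small[seq_len(500)] <- TRUE
  sm <- voi_mask(small, "AORTA")
  expect_error(measure_blood_pool(ph$volume, sm), "protocol")
  ok <- measure_blood_pool(ph$volume, sm, allow_small = TRUE)
  expect_true("SUB_MINIMAL_VOI" %in% ok$flags)
})

test_that("noisy blood-pool SUVmean stays within Monte-Carlo error", {
  devs <- sapply(1:50, function(s) {
    ph <- build_phantom(default_phantom_spec(psf_fwhm = 0, noise_sd = 0.2,
                                             seed = s, spacing = c(4, 4, 4)))
    bp <- measure_blood_pool(ph$volume, ph$vois$aorta)
    n <- sum(ph$vois$aorta$mask)
    (bp$suv_mean - 2.5) / (0.2 / sqrt(n))   # z-score vs true blood SUV
  })
  expect_true(mean(abs(devs) <= 3) >= 0.98)
})

test_that("tumor isocontour is background-referenced and strict", {
  ph <- cached_phantom("tumor", function() build_phantom(
    default_phantom_spec(psf_fwhm = 0, noise_sd = 0,
                         tumors = list(list(center = c(60, 140, 240),
                                            radius = 15, suv = 12)))))
  tu <- segment_tumor(ph$volume, ph$vois$tumor1, background_suvmax = 3)
  analytic <- 4 * pi / 3 * 15^3 / 1000
  expect_lt(abs(tu$volume_ml / analytic - 1), 0.05)
  expect_equal(tu$suv_mean, 12, tolerance = 1e-9)
  # threshold above the lesion -> empty, MTV 0
  none <- segment_tumor(ph$volume, ph$vois$tumor1, background_suvmax = 13)
  expect_equal(none$volume_ml, 0)
  expect_true("EMPTY_SEGMENTATION" %in% none$flags)
  expect_equal(compute_mtv(0, none$volume_ml), 0)
})

test_that("disjoint lesions in one VOI are all retained by default", {
  v <- array(1, dim = c(10, 10, 3))
  v[2, 2, 2] <- 12; v[8, 8, 2] <- 11
  vol <- pet_volume(v, c(2, 2, 2))
  voi <- voi_mask(array(TRUE, dim = dim(v)), "TUMOR")
  tu <- segment_tumor(vol, voi, background_suvmax = 3)
  expect_equal(tu$voxel_count, 2)
  # largest-component pruning is available but off by default
  sel <- renalpet:::largest_component(tu$mask$mask, 26L)
  expect_equal(sum(sel), 1)
})

test_that("connected-component labelling respects the connectivity model", {
  m <- array(FALSE, dim = c(4, 4, 4))
  m[1, 1, 1] <- TRUE; m[2, 2, 1] <- TRUE   # diagonal in-plane neighbors
  m[4, 4, 4] <- TRUE
  # 26-connectivity joins the diagonal pair; 6 does not
  expect_equal(sum(renalpet:::largest_component(m, 26L)), 2)
  expect_equal(sum(renalpet:::largest_component(m, 6L)), 1)
})
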