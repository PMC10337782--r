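test_that("voxelized shell volume matches the analytic ellipsoid oracle", {
  ph <- clean_phantom()
  # analytic: 4pi/3 * (prod outer - prod core) / 1000 with the default
  # semi-axes 50x30x30 (outer) and 25x15x15 (core)
  analytic <- 4 * pi / 3 * (50 * 30 * 30 - 25 * 15 * 15) / 1000
  expect_equal(analytic, 164.9, tolerance = 1e-3)
  expect_equal(ph$truth$kidneys$left$parenchymal_volume_ml, analytic,
               tolerance = 1e-12)
  vox <- sum(ph$truth$masks$left_parenchyma) *
    voxel_volume_ml(ph$volume$spacing)
  expect_lt(abs(vox / analytic - 1), 0.05)
})

test_that("a symmetric two-kidney phantom has true split 50", {
  ph <- clean_phantom()
  expect_equal(ph$truth$split_left_pct, 50)
})

test_that("phantom truth satisfies the index identities exactly", {
  ph <- clean_phantom()
  for (k in ph$truth$kidneys) {
    expect_equal(k$aci * k$suv_mean, k$parenchymal_volume_ml,
                 tolerance = 1e-12)
    expect_equal(k$tka, k$suv_mean * k$parenchymal_volume_ml,
                 tolerance = 1e-12)
  }
})

test_that("noise is reproducible under the seed and differs across seeds", {
  spec_a <- default_phantom_spec(noise_sd = 0.3, seed = 11, spacing = c(4, 4, 4))
  spec_b <- default_phantom_spec(noise_sd = 0.3, seed = 12, spacing = c(4, 4, 4))
  v1 <- build_phantom(spec_a)$volume$values
  v2 <- build_phantom(spec_a)$volume$values
  v3 <- build_phantom(spec_b)$volume$values
  expect_identical(v1, v2)
  expect_false(identical(v1, v3))
})

test_that("phantom construction does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(build_phantom(default_phantom_spec(noise_sd = 0.3, seed = 5,
                                               spacing = c(4, 4, 4))))
  expect_identical(runif(1), a)
})

test_that("PSF blur preserves a constant field and total uptake", {
  const <- array(3, dim = c(16, 16, 16))
  blurred <- renalpet:::gaussian_blur3d(const, c(2, 2, 2), fwhm = 4)
  expect_equal(blurred, const, tolerance = 1e-9)

  set.seed(9)
  v <- array(runif(16^3), dim = c(16, 16, 16))
  b <- renalpet:::gaussian_blur3d(v, c(2, 2, 2), fwhm = 4)
  # interior mass is redistributed, not created: blur lies within range
  expect_gte(min(b), min(v) - 1e-9)
  expect_lte(max(b), max(v) + 1e-9)
})

test_that("geometry outside the grid is rejected", {
  spec <- phantom_spec(
    shape = c(20, 20, 20), spacing = c(2, 2, 2),
    kidneys = list(left = list(center = c(5, 20, 20),
                               outer_semi_axes = c(10, 10, 10),
                               parenchyma_suv = 8)))
  expect_error(build_phantom(spec), "geometry")
  expect_error(
    phantom_spec(shape = c(20, 20, 20), spacing = c(2, 2, 2),
                 kidneys = list(left = list(
                   center = c(20, 20, 20), outer_semi_axes = c(8, 8, 8),
                   core_semi_axes = c(9, 9, 9), parenchyma_suv = 8,
                   core_suv = 20))),
    "strictly inside")
})
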