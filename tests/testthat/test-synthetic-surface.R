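test_that("generator is deterministic and validates its spec", {
  sp <- surface_spec(n_rows = 64, n_cols = 64, noise_sd = 0.05, seed = 42)
  a <- generate_surface(sp)
  b <- generate_surface(sp)
  expect_identical(a$heights, b$heights)

  expect_error(surface_spec(base_wavelength_x = 1.5, step = 1),
               class = "oatopo_nyquist")
  expect_error(surface_spec(n_rows = 8), class = "oatopo_validation")
  expect_error(surface_spec(amplitude = 0), class = "oatopo_validation")
  expect_error(surface_spec(noise_sd = -1), class = "oatopo_validation")
  expect_error(pair_spec(surface_spec(), stretch_x = 0),
               class = "oatopo_validation")
})

test_that("noise-free surfaces carry their requested dominant wavelength", {
  hm <- generate_surface(surface_spec(base_wavelength_x = 16,
                                      base_wavelength_y = 16,
                                      noise_sd = 0, seed = 1))
  wp <- surface_wavelengths(hm)
  expect_lt(abs(wp$lambda_x - 16), 1)
  expect_lt(abs(wp$lambda_y - 16), 1)
})

test_that("wavelength band endpoints 8 and 28 um are distinguished", {
  lo <- surface_wavelengths(generate_surface(
    surface_spec(base_wavelength_x = 8, base_wavelength_y = 8,
                 noise_sd = 0, seed = 2)))
  hi <- surface_wavelengths(generate_surface(
    surface_spec(base_wavelength_x = 28, base_wavelength_y = 28,
                 noise_sd = 0, seed = 2)))
  expect_gt(lo$lambda_x, 7)
  expect_lt(lo$lambda_x, 9)
  expect_gt(hi$lambda_x, 26)
  expect_lt(hi$lambda_x, 30)
  expect_lt(lo$lambda_y, hi$lambda_y)
})

test_that("identity pair reproduces the healthy member exactly", {
  pr <- generate_pair(pair_spec(surface_spec(n_rows = 96, n_cols = 96,
                                             seed = 5),
                                stretch_x = 1, stretch_y = 1,
                                sector_imbalance = 0))
  expect_identical(pr$oa$heights, pr$healthy$heights)
  wp <- surface_wavelengths(pr$healthy)
  eps <- deformation_ratio(wp, wp)
  expect_identical(eps$eps_x, 0)
  expect_identical(eps$eps_y, 0)
})

test_that("pair stretch factors are recovered as wavelength ratios", {
  for (k in c(0.7, 1.25, 1.5)) {
    pr <- generate_pair(pair_spec(
      surface_spec(n_rows = 256, n_cols = 256, noise_sd = 0, seed = 9),
      stretch_x = k, stretch_y = k))
    wh <- surface_wavelengths(pr$healthy)
    wo <- surface_wavelengths(pr$oa)
    expect_lt(abs(wo$lambda_x / wh$lambda_x - k) / k, 0.05)
    expect_lt(abs(wo$lambda_y / wh$lambda_y - k) / k, 0.05)
  }
})

test_that("sector imbalance raises the cohesion index of the OA member", {
  for (s in 1:3) {
    base <- surface_spec(n_rows = 256, n_cols = 256, seed = s)
    flat <- generate_pair(pair_spec(base, sector_imbalance = 0))
    imb <- generate_pair(pair_spec(base, sector_imbalance = 0.5))
    i0 <- cohesion_index(sector_wavelengths(flat$oa))
    i1 <- cohesion_index(sector_wavelengths(imb$oa))
    expect_gt(i1$I_x, i0$I_x)
  }
})
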