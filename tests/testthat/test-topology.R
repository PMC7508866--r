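test_that("gradient is exact on affine surfaces and accurate on sinusoids", {
  n <- 32
  plane <- height_map(outer((0:(n - 1)) * 3, (0:(n - 1)) * 2, `+`), step = 1)
  g <- compute_gradient(plane)
  expect_equal(unique(as.vector(g$dz_dx)), 2)
  expect_equal(unique(as.vector(g$dz_dy)), 3)

  flat <- compute_gradient(height_map(matrix(5, 16, 16)))
  expect_true(all(flat$dz_dx == 0) && all(flat$dz_dy == 0))

  lambda0 <- 16
  x <- 0:255
  hm <- height_map(matrix(sin(2 * pi * x / lambda0), 64, 256, byrow = TRUE))
  g <- compute_gradient(hm)
  expected <- (2 * pi / lambda0) * cos(2 * pi * x / lambda0)
  err <- abs(sweep(g$dz_dx[, 2:255], 2, expected[2:255]))
  # central differences attenuate a sinusoid's derivative by sinc(2*pi*h/lambda):
  # at lambda = 16, h = 1 the closed-form error bound is 1 - sinc = 2.551% of peak
  bound <- 1 - sin(2 * pi / lambda0) / (2 * pi / lambda0)
  expect_lt(max(err) / (2 * pi / lambda0), bound + 1e-4)

  expect_error(compute_gradient(height_map(matrix(0, 2, 8))),
               class = "oatopo_validation")
})

test_that("signed-derivative maxima spacing recovers the period", {
  # derivative rows are a pure cosine of period 16: one maximum per period
  x <- 0:191
  dz <- matrix(cos(2 * pi * x / 16), 4, 192, byrow = TRUE)
  ls <- extract_line_spacings(gradient_fixture(dz, t(dz)))
  expect_true(all(abs(unlist(ls$spacings_x) - 16) < 1e-9))
  wp <- mean_wavelengths(ls)
  expect_equal(wp$lambda_x, 16)
  expect_equal(wp$lambda_y, 16)
})

test_that("monotone and two-peak derivative lines behave per contract", {
  ramp <- matrix(seq(0, 1, length.out = 64), 3, 64, byrow = TRUE)
  ls <- extract_line_spacings(gradient_fixture(ramp, t(ramp)))
  expect_identical(ls$n_maxima_x, 0L)
  expect_true(all(lengths(ls$spacings_x) == 0))
  expect_error(mean_wavelengths(ls), class = "oatopo_undefined_wavelength")

  two <- matrix(0, 2, 60)
  two[, 10] <- 1
  two[, 42] <- 1
  ls2 <- extract_line_spacings(gradient_fixture(two, t(two)), step = 1)
  expect_equal(unlist(ls2$spacings_x), c(32, 32))
})

test_that("plateau maxima contribute their midpoint", {
  v <- c(0, 1, 2, 2, 2, 1, 0, 1, 3, 1, 0)
  line <- matrix(v, 1, length(v))
  ls <- extract_line_spacings(gradient_fixture(line, t(line)))
  # plateau spans indices 3..5 (midpoint 4); second peak at index 9
  expect_equal(unlist(ls$spacings_x), 5)
})

test_that("minimum prominence suppresses shallow maxima", {
  v <- c(0, 5, 0, 0.4, 0.5, 0.4, 0, 5, 0)
  line <- matrix(v, 1, length(v))
  raw <- extract_line_spacings(gradient_fixture(line, t(line)))
  expect_length(unlist(raw$spacings_x), 2L)
  pruned <- extract_line_spacings(gradient_fixture(line, t(line)),
                                  min_prominence = 1)
  expect_equal(unlist(pruned$spacings_x), 6)
})

test_that("per-line averaging defines the wavelength", {
  ls <- spacings_fixture(list(c(10, 10), c(20)), list(c(16)))
  wp <- mean_wavelengths(ls)
  expect_equal(wp$lambda_x, 15)   # mean of line means 10 and 20
  expect_equal(wp$lambda_y, 16)
})

test_that("deformation ratio follows the OA-over-healthy contract", {
  eps <- deformation_ratio(wavelength_pair(14.17, 14.17),
                           wavelength_pair(10, 10))
  expect_equal(eps$eps_y, 0.417)
  comp <- deformation_ratio(wavelength_pair(8, 8), wavelength_pair(10, 10))
  expect_equal(comp$eps_x, -0.2)
  expect_lt(comp$eps_x, 0)      # negative = compression
  same <- wavelength_pair(12.3, 9.7)
  z <- deformation_ratio(same, same)
  expect_identical(c(z$eps_x, z$eps_y), c(0, 0))
})

test_that("non-finite heights and zero wavelengths are rejected", {
  expect_error(height_map(matrix(c(1, NA, 2, 3), 2, 2)),
               class = "oatopo_validation")
  expect_error(wavelength_pair(0, 10), class = "oatopo_validation")
})
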