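test_that("sector partition conserves the surface, including odd sizes", {
  set.seed(1)
  dims <- cbind(sample(c(31, 32, 33, 48, 64), 20, replace = TRUE),
                sample(c(31, 32, 33, 48, 64), 20, replace = TRUE))
  for (k in 1:20) {
    z <- matrix(rnorm(dims[k, 1] * dims[k, 2]), dims[k, 1], dims[k, 2])
    hm <- height_map(z)
    dec <- sector_decompose(hm)
    recon <- dec$s1$heights + dec$s2$heights + dec$mean
    expect_lt(max(abs(recon - z)), 1e-9 * diff(range(z)))
    expect_lt(abs(mean(dec$s1$heights)), 1e-9)
    expect_lt(abs(mean(dec$s2$heights)), 1e-9)
  }
})

test_that("axis-aligned energy lands in the sector the convention dictates", {
  n <- 64
  x <- 0:(n - 1)
  along_x <- height_map(matrix(sin(2 * pi * x / 16), n, n, byrow = TRUE))
  dx <- sector_decompose(along_x)   # theta = 0 -> sector 1
  expect_lt(sum(dx$s2$heights^2), 1e-12 * sum(dx$s1$heights^2))

  along_y <- height_map(matrix(sin(2 * pi * x / 16), n, n))
  dy <- sector_decompose(along_y)   # theta = 90 deg -> sector 2
  expect_lt(sum(dy$s1$heights^2), 1e-12 * sum(dy$s2$heights^2))
})

test_that("a 90-degree-symmetric surface splits its energy evenly", {
  set.seed(3)
  rot90 <- function(m) t(m)[, nrow(m):1]
  for (k in 1:5) {
    g <- matrix(rnorm(64 * 64), 64, 64)
    z <- g + rot90(g) + rot90(rot90(g)) + rot90(rot90(rot90(g)))
    dec <- sector_decompose(height_map(z))
    e1 <- sum(dec$s1$heights^2)
    e2 <- sum(dec$s2$heights^2)
    expect_lt(abs(e1 - e2) / max(e1, e2), 0.01)
  }
})

test_that("cohesion index follows its closed form and is swap-invariant", {
  sw <- structure(list(lambda_x_s1 = 12, lambda_x_s2 = 10,
                       lambda_y_s1 = 14, lambda_y_s2 = 14),
                  class = "oat_sector_wavelengths")
  ci <- cohesion_index(sw)
  expect_equal(ci$I_x, 0.2)
  expect_identical(ci$I_y, 0)
  expect_equal(ci$lambda_min_x, 10)

  swapped <- structure(list(lambda_x_s1 = 10, lambda_x_s2 = 12,
                            lambda_y_s1 = 14, lambda_y_s2 = 14),
                       class = "oat_sector_wavelengths")
  ci2 <- cohesion_index(swapped)
  expect_identical(ci$I_x, ci2$I_x)
  expect_identical(ci$I_y, ci2$I_y)
  expect_gte(ci$I_x, 0)
})

test_that("a zero-energy sector raises a typed undefined-wavelength error", {
  n <- 128
  x <- 0:(n - 1)
  pure <- height_map(matrix(sin(2 * pi * x / 16), n, n, byrow = TRUE))
  err <- tryCatch(sector_wavelengths(pure), condition = function(e) e)
  expect_s3_class(err, "oatopo_undefined_wavelength")
  expect_match(conditionMessage(err), "sector")
  expect_match(conditionMessage(err), "axis")
})

test_that("sector wavelengths of a balanced synthetic surface agree", {
  hm <- generate_surface(surface_spec(n_rows = 256, n_cols = 256, seed = 8))
  sw <- sector_wavelengths(hm)
  expect_lt(abs(sw$lambda_x_s1 - sw$lambda_x_s2) /
              min(sw$lambda_x_s1, sw$lambda_x_s2), 0.1)
  ci <- cohesion_index(sw)
  expect_lt(ci$I_x, 0.1)
})
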