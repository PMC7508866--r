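test_that("segmentation recovers the planted cartilage area", {
  sl <- generate_slide(slide_spec(mask_fraction = 0.4, n_cells = 80, seed = 4))
  m <- segment_cartilage(sl$image)
  expect_lt(abs(m$area_um2 - sl$ground_truth$mask_area_um2) /
              sl$ground_truth$mask_area_um2, 0.02)

  # user-supplied mask bypasses segmentation
  pass <- segment_cartilage(sl$image, user_mask = sl$mask)
  expect_identical(pass$mask, sl$mask$mask)

  black <- slide_image(array(0, c(32, 32, 3)), pixel_size = 1)
  expect_error(segment_cartilage(black), class = "oatopo_empty_segmentation")
})

test_that("mask AND-application blacks out exactly the outside", {
  sl <- generate_slide(slide_spec(n_cells = 10, width = 96, height = 96,
                                  color_fractions = c(red = 0.1, yellow = 0.1,
                                                      green = 0.1),
                                  seed = 2))
  full <- cartilage_mask(matrix(TRUE, 96, 96), 1)
  expect_identical(apply_mask(sl$image, full)$rgb, sl$image$rgb)

  empty <- cartilage_mask(matrix(FALSE, 96, 96), 1)
  expect_true(all(apply_mask(sl$image, empty)$rgb == 0))

  wrong <- cartilage_mask(matrix(TRUE, 50, 50), 1)
  expect_error(apply_mask(sl$image, wrong), class = "oatopo_validation")
})

test_that("birefringence fractions recover planted values and edge cases", {
  sl <- generate_slide(slide_spec(
    color_fractions = c(red = 0.2, yellow = 0.3, green = 0.3), seed = 5))
  m <- segment_cartilage(sl$image)
  bf <- birefringence_fractions(apply_mask(sl$image, m), m)
  expect_lt(abs(bf$red_fraction - 0.2), 0.01)
  expect_lt(abs(bf$yellow_fraction - 0.3), 0.01)
  expect_lt(abs(bf$green_fraction - 0.3), 0.01)

  # all-black region has no colour at all
  dark <- slide_image(array(0, c(40, 40, 3)), pixel_size = 1)
  mk <- cartilage_mask(matrix(TRUE, 40, 40), 1)
  bd <- birefringence_fractions(dark, mk)
  expect_identical(c(bd$red_fraction, bd$yellow_fraction, bd$green_fraction),
                   c(0, 0, 0))

  # pure green over exactly half the mask
  a <- array(0, c(40, 40, 3))
  a[1:20, , 2] <- 255
  bg <- birefringence_fractions(slide_image(a, 1), mk)
  expect_identical(bg$green_fraction, 0.5)
  expect_identical(bg$red_fraction, 0)

  expect_error(birefringence_fractions(dark, cartilage_mask(matrix(FALSE, 40, 40), 1)),
               class = "oatopo_division")
})

test_that("planted cells are counted exactly and densities recovered", {
  sl <- generate_slide(slide_spec(n_cells = 100, seed = 4))
  cc <- count_cells(sl$image, sl$mask)
  expect_identical(cc$cell_count, 100)
  expect_equal(cc$cellularity, sl$ground_truth$cellularity)

  for (s in 1:2) {
    dens <- 500
    sp <- slide_spec(n_cells = round(dens * 0.2048),
                     color_fractions = c(red = 0, yellow = 0, green = 0),
                     seed = s)
    sl <- generate_slide(sp)
    m <- segment_cartilage(sl$image)
    cc <- count_cells(sl$image, m)
    expect_lt(abs(cc$cellularity - sl$ground_truth$cellularity) /
                sl$ground_truth$cellularity, 0.05)
  }

  expect_error(count_cells(sl$image, cartilage_mask(matrix(FALSE, 640, 640), 1)),
               class = "oatopo_division")
})

test_that("manual-count entry path divides the mean count by the area", {
  r <- cellularity_from_counts(c(98, 100, 102), area_um2 = 1e5)
  expect_equal(r$cell_count, 100)
  expect_equal(r$cellularity, 1000)   # 0.1 mm^2 holding 100 cells
})

test_that("Mankin aggregation gives operator mean and sample SD", {
  a <- aggregate_mankin(c(4, 4, 4))
  expect_equal(a$mean, 4)
  expect_identical(a$sd, 0)
  b <- aggregate_mankin(c(3, 4, 5))
  expect_equal(b$mean, 4)
  expect_equal(b$sd, 1)
  expect_identical(aggregate_mankin(8)$sd, NA_real_)   # worst case in range
  expect_error(aggregate_mankin(c(4, 15)), class = "oatopo_validation")
  expect_error(aggregate_mankin(c(4, -1)), class = "oatopo_validation")
  ok <- aggregate_mankin(c(6, 7), subscores = rbind(c(2, 2, 1, 1),
                                                    c(2, 2, 2, 1)))
  expect_equal(ok$mean, 6.5)
  expect_error(aggregate_mankin(c(6, 7), subscores = rbind(c(1, 1, 1, 1),
                                                           c(2, 2, 2, 1))),
               class = "oatopo_validation")
})

test_that("profile line intensity is the mean of the rasterized samples", {
  grey <- slide_image(array(128, c(20, 20, 3)), 1)
  p <- profile_line_intensity(grey, c(1, 1), c(20, 20))
  expect_equal(p$mean_intensity, 128)

  half <- array(0, c(10, 10, 3))
  half[, 6:10, ] <- 255
  ph <- profile_line_intensity(slide_image(half, 1), c(5, 1), c(5, 10))
  expect_equal(ph$mean_intensity, 127.5)

  adj <- profile_line_intensity(slide_image(half, 1), c(5, 5), c(5, 6))
  expect_equal(adj$mean_intensity, 127.5)   # one black + one white pixel

  expect_error(profile_line_intensity(grey, c(0, 1), c(5, 5)),
               class = "oatopo_validation")
  expect_error(profile_line_intensity(grey, c(3, 3), c(3, 3)),
               class = "oatopo_validation")
})
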