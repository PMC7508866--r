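#' Specification of a synthetic histology slide
#'
#' Describes a seeded synthetic stained-slice image with exactly known
#' ground truth: a rectangular cartilage region on a dark background,
#' colour patches whose hue-band area fractions are planted to the pixel,
#' and non-overlapping disc "chondrocytes" whose count and density are
#' exact. Colour patches fill the top of the cartilage region; cells are
#' placed below a guard band so detection components can never merge with
#' a patch.
#'
#' @param width,height Image size in pixels.
#' @param pixel_size Pixel edge length in micrometres per pixel.
#' @param n_cells Number of planted cells (>= 0).
#' @param cell_radius Cell radius in micrometres (chondrocytes are ~10 um
#'   across, hence the default 5).
#' @param mask_fraction Fraction (0, 1] of the image covered by the
#'   cartilage region.
#' @param color_fractions Named triple `(red, yellow, green)` in [0, 1],
#'   summing to at most 1: target area fractions of the cartilage region.
#' @param background_intensity Background grey level in [0, 255].
#' @param seed Integer seed.
#' @return A validated `oat_slide_spec` list.
#' @export
slide_spec <- function(width = 640, height = 640, pixel_size = 1,
                       n_cells = 150, cell_radius = 5, mask_fraction = 0.5,
                       color_fractions = c(red = 0.2, yellow = 0.3, green = 0.3),
                       background_intensity = 30, seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               pixel_size = pixel_size, n_cells = as.integer(n_cells),
               cell_radius = cell_radius, mask_fraction = mask_fraction,
               color_fractions = color_fractions,
               background_intensity = background_intensity,
               seed = as.integer(seed))
  oat_check(spec$width >= 32 && spec$height >= 32, "slide must be >= 32 px")
  oat_check(pixel_size > 0, "'pixel_size' must be positive")
  oat_check(spec$n_cells >= 0, "'n_cells' must be non-negative")
  oat_check(cell_radius > 0, "'cell_radius' must be positive")
  oat_check(mask_fraction > 0 && mask_fraction <= 1,
            "'mask_fraction' must lie in (0, 1]")
  oat_check(length(color_fractions) == 3L && all(color_fractions >= 0) &&
              all(color_fractions <= 1) && sum(color_fractions) <= 1,
            "'color_fractions' must be three values in [0, 1] summing to <= 1")
  if (is.null(names(color_fractions))) {
    names(spec$color_fractions) <- c("red", "yellow", "green")
  }
  oat_check(background_intensity >= 0 && background_intensity <= 255,
            "'background_intensity' must lie in [0, 255]")
  structure(spec, class = "oat_slide_spec")
}

# band-centre paint colours (HSV); hues sit inside the default bands, the
# neutral tone is unsaturated (excluded by the saturation floor) and the
# cell tone is a dark blue outside every band
.paint <- list(red = c(h = 0, s = 0.9, v = 0.95),
               yellow = c(h = 45 / 360, s = 0.9, v = 0.95),
               green = c(h = 115 / 360, s = 0.9, v = 0.9),
               neutral = c(h = 0, s = 0, v = 200 / 255),
               cell = c(h = 240 / 360, s = 0.8, v = 0.35))

paint_rgb <- function(name) {
  p <- .paint[[name]]
  255 * as.vector(grDevices::col2rgb(grDevices::hsv(p["h"], p["s"], p["v"]))) / 255
}

#' Generate a synthetic histology slide
#'
#' Deterministic for a fixed spec. The returned ground truth carries the
#' exact painted colour-pixel fractions (within one pixel of the requested
#' ones), the planted cell count and centres, the mask area and the
#' implied cellularity.
#'
#' @param spec An [slide_spec()].
#' @return A list: `image` (`oat_slide_image`), `mask`
#'   (`oat_cartilage_mask`) and `ground_truth` (list with `n_cells`,
#'   `cell_centers`, `color_fractions`, `mask_area_um2`, `mask_fraction`,
#'   `cellularity`).
#' @section Errors: if the requested cells cannot be packed without
#'   overlap into the available region, an `oatopo_packing` error is
#'   raised rather than silently planting fewer cells.
#' @export
generate_slide <- function(spec) {
  oat_check(inherits(spec, "oat_slide_spec"), "'spec' must come from slide_spec()")
  withr::with_seed(spec$seed, slide_build(spec))
}

slide_build <- function(spec) {
  H <- spec$height; W <- spec$width
  img <- array(spec$background_intensity, c(H, W, 3))
  # centred rectangular cartilage region with the requested area fraction
  hm <- max(16L, round(H * sqrt(spec$mask_fraction)))
  wm <- max(16L, round(W * sqrt(spec$mask_fraction)))
  r0 <- floor((H - hm) / 2) + 1L; r1 <- r0 + hm - 1L
  c0 <- floor((W - wm) / 2) + 1L; c1 <- c0 + wm - 1L
  mask <- matrix(FALSE, H, W)
  mask[r0:r1, c0:c1] <- TRUE
  n_mask <- sum(mask)

  paint <- function(rows, cols, name) {
    col <- paint_rgb(name)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[cbind(rows, cols)] <- col[ch]
      img[, , ch] <<- plane
    }
  }
  # neutral fill of the whole cartilage region first
  idx <- which(mask, arr.ind = TRUE)
  paint(idx[, 1], idx[, 2], "neutral")

  # colour patches: fill mask pixels in raster (row-major) order from the top
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  n_col <- round(spec$color_fractions * n_mask)
  at <- 0L
  planted <- c(red = 0, yellow = 0, green = 0)
  for (nm in c("red", "yellow", "green")) {
    n_i <- min(n_col[[nm]], n_mask - at)
    if (n_i > 0) {
      sel <- idx[(at + 1L):(at + n_i), , drop = FALSE]
      paint(sel[, 1], sel[, 2], nm)
      planted[nm] <- n_i / n_mask
      at <- at + n_i
    }
  }
  colored_last_row <- if (at > 0L) idx[at, 1] else r0 - 1L

  # cell region: below the colour block plus a one-diameter guard band
  r_px <- spec$cell_radius / spec$pixel_size
  guard <- ceiling(2 * r_px) + 2L
  cr0 <- max(r0, colored_last_row + guard)
  centers <- NULL
  if (spec$n_cells > 0) {
    rad <- ceiling(r_px)
    lo_r <- cr0 + rad; hi_r <- r1 - rad
    lo_c <- c0 + rad; hi_c <- c1 - rad
    if (lo_r > hi_r || lo_c > hi_c) {
      oat_stop("no room to place cells below the colour patches",
               "oatopo_packing")
    }
    centers <- matrix(0, spec$n_cells, 2)
    min_d2 <- (2 * r_px + 2)^2
    placed <- 0L
    attempts <- 0L
    max_attempts <- 2000L + 500L * spec$n_cells
    while (placed < spec$n_cells && attempts < max_attempts) {
      attempts <- attempts + 1L
      cand <- c(stats::runif(1, lo_r, hi_r), stats::runif(1, lo_c, hi_c))
      if (placed > 0L) {
        d2 <- (centers[seq_len(placed), 1] - cand[1])^2 +
          (centers[seq_len(placed), 2] - cand[2])^2
        if (min(d2) < min_d2) next
      }
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
    if (placed < spec$n_cells) {
      oat_stop(sprintf(
        "could not pack %d non-overlapping cells (placed %d); enlarge the region or reduce n_cells",
        spec$n_cells, placed), "oatopo_packing")
    }
    # paint discs
    rr <- -rad:rad
    disc <- expand.grid(dr = rr, dc = rr)
    disc <- disc[disc$dr^2 + disc$dc^2 <= r_px^2, ]
    for (i in seq_len(spec$n_cells)) {
      rows <- round(centers[i, 1]) + disc$dr
      cols <- round(centers[i, 2]) + disc$dc
      paint(rows, cols, "cell")
    }
  }

  area_um2 <- n_mask * spec$pixel_size^2
  list(image = slide_image(img, pixel_size = spec$pixel_size,
                           modality = "synthetic"),
       mask = cartilage_mask(mask, pixel_size = spec$pixel_size),
       ground_truth = list(
         n_cells = spec$n_cells,
         cell_centers = centers,
         color_fractions = planted,
         mask_area_um2 = area_um2,
         mask_fraction = n_mask / (H * W),
         cellularity = spec$n_cells / (area_um2 / 1e6)))
}
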