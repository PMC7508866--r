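#' Histology slide image
#'
#' An RGB slide photograph with its physical pixel size. Channels are
#' stored as numeric values in [0, 255]; `rgb[i, j, ]` is the pixel at row
#' i (image y), column j (image x).
#'
#' @param rgb Numeric array `height x width x 3` with values in [0, 255].
#' @param pixel_size Pixel edge length in micrometres (> 0).
#' @param modality One of `"white_light"`, `"polarized"` or `"synthetic"`.
#' @return An `oat_slide_image` object.
#' @export
slide_image <- function(rgb, pixel_size,
                        modality = c("white_light", "polarized", "synthetic")) {
  modality <- match.arg(modality)
  oat_check(is.array(rgb) && length(dim(rgb)) == 3L && dim(rgb)[3] == 3L,
            "'rgb' must be a height x width x 3 array")
  oat_check(all(is.finite(rgb)) && min(rgb) >= 0 && max(rgb) <= 255,
            "channel values must lie in [0, 255]")
  oat_check(pixel_size > 0, "'pixel_size' must be positive")
  structure(list(rgb = rgb, pixel_size = pixel_size, modality = modality),
            class = "oat_slide_image")
}

is_slide_image <- function(x) inherits(x, "oat_slide_image")

#' @export
print.oat_slide_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<slide image> %d x %d px, %g um/px, %s\n",
              d[1], d[2], x$pixel_size, x$modality))
  invisible(x)
}

#' Binary cartilage mask
#'
#' @param mask Logical matrix (TRUE = cartilage) aligned to a slide image.
#' @param pixel_size Pixel edge length in micrometres.
#' @return An `oat_cartilage_mask` with the derived `area_um2`.
#' @export
cartilage_mask <- function(mask, pixel_size) {
  oat_check(is.matrix(mask) && is.logical(mask), "'mask' must be a logical matrix")
  oat_check(pixel_size > 0, "'pixel_size' must be positive")
  structure(list(mask = mask, pixel_size = pixel_size,
                 area_um2 = sum(mask) * pixel_size^2),
            class = "oat_cartilage_mask")
}

is_cartilage_mask <- function(x) inherits(x, "oat_cartilage_mask")

#' Slide and mask PNG I/O
#'
#' Slides are written as 8-bit RGB PNG, masks as 8-bit single-band PNG with
#' values 0/255; pixel size travels in a JSON sidecar `<path>.json`.
#'
#' @param x Slide or mask object.
#' @param path PNG file path.
#' @return `path` invisibly (writers); the object (readers).
#' @export
write_slide <- function(x, path) {
  oat_check(is_slide_image(x), "'x' must be an oat_slide_image")
  png::writePNG(x$rgb / 255, path)
  jsonlite::write_json(list(pixel_size = x$pixel_size, modality = x$modality),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_slide
#' @export
read_slide <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L && dim(a)[3] >= 3L) a <- a[, , 1:3] else
    a <- array(rep(a, 3L), c(dim(a), 3L))
  slide_image(round(a * 255), pixel_size = side$pixel_size,
              modality = side$modality)
}

#' @rdname write_slide
#' @export
write_mask <- function(x, path) {
  oat_check(is_cartilage_mask(x), "'x' must be an oat_cartilage_mask")
  png::writePNG(x$mask * 1, path)
  jsonlite::write_json(list(pixel_size = x$pixel_size), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_slide
#' @export
read_mask <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  cartilage_mask(a > 0.5, pixel_size = side$pixel_size)
}

slide_grey <- function(img, channel = c("luminance", "value")) {
  channel <- match.arg(channel)
  if (channel == "luminance") {
    0.299 * img$rgb[, , 1] + 0.587 * img$rgb[, , 2] + 0.114 * img$rgb[, , 3]
  } else {
    pmax(img$rgb[, , 1], pmax(img$rgb[, , 2], img$rgb[, , 3]))
  }
}

#' Segment the cartilage region of a white-light slide
#'
#' Thresholds a grey projection of the image (by default the HSV value
#' channel, robust to strongly coloured stain), keeps the largest connected
#' component and fills its interior holes (chondrocytes and stain voids).
#' The bench procedure this emulates is semi-automatic, so a user-supplied
#' mask bypasses segmentation entirely.
#'
#' @param white An `oat_slide_image`.
#' @param threshold Grey-level threshold in [0, 255]; `NULL` (default)
#'   picks it by Otsu's method.
#' @param channel `"value"` (default) or `"luminance"` projection.
#' @param close_radius Radius in pixels of the morphological closing brush
#'   applied before hole filling; set it near the expected cell radius so
#'   dark cells lying on the tissue border do not notch the mask. 0
#'   disables closing.
#' @param user_mask Optional `oat_cartilage_mask` returned unchanged.
#' @return An `oat_cartilage_mask`.
#' @section Errors: an all-background image raises
#'   `oatopo_empty_segmentation`.
#' @export
segment_cartilage <- function(white, threshold = NULL, channel = "value",
                              close_radius = 5, user_mask = NULL) {
  if (!is.null(user_mask)) {
    oat_check(is_cartilage_mask(user_mask), "'user_mask' must be an oat_cartilage_mask")
    return(user_mask)
  }
  oat_check(is_slide_image(white), "'white' must be an oat_slide_image")
  g <- slide_grey(white, channel)
  if (is.null(threshold)) {
    threshold <- 255 * EBImage::otsu(EBImage::Image(g / 255), range = c(0, 1))
  }
  bin <- g > threshold
  if (!any(bin)) {
    oat_stop("segmentation produced an empty mask", "oatopo_empty_segmentation")
  }
  lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
  counts <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  keep <- which.max(counts)
  comp <- matrix(as.integer(lab) == keep, nrow(bin), ncol(bin))
  if (close_radius > 0) {
    brush <- EBImage::makeBrush(2 * close_radius + 1, shape = "disc")
    comp <- EBImage::closing(EBImage::Image(comp * 1), brush) > 0.5
  }
  filled <- EBImage::fillHull(EBImage::Image(comp * 1))
  cartilage_mask(matrix(as.numeric(filled) > 0.5, nrow(bin), ncol(bin)),
                 pixel_size = white$pixel_size)
}

#' Apply a cartilage mask to a slide (AND operation)
#'
#' Pixels outside the mask are set to black; pixels inside are unchanged.
#'
#' @param polarized An `oat_slide_image` (any modality).
#' @param mask An `oat_cartilage_mask` of the same shape.
#' @return The masked `oat_slide_image`.
#' @export
apply_mask <- function(polarized, mask) {
  oat_check(is_slide_image(polarized), "'polarized' must be an oat_slide_image")
  oat_check(is_cartilage_mask(mask), "'mask' must be an oat_cartilage_mask")
  oat_check(all(dim(polarized$rgb)[1:2] == dim(mask$mask)),
            "slide and mask shapes differ")
  out <- polarized$rgb
  m <- !mask$mask
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[m] <- 0
    out[, , ch] <- plane
  }
  slide_image(out, pixel_size = polarized$pixel_size,
              modality = polarized$modality)
}

#' Default hue bands for birefringence colours
#'
#' HSV hue intervals in degrees, half-open `[lo, hi)`: red wraps around 0.
#' The bench colour thresholds are not standardized; these defaults are
#' explicit configuration, not a claim of equivalence to any particular
#' software's presets.
#'
#' @return Named list of interval matrices.
#' @export
default_hue_bands <- function() {
  list(red = rbind(c(0, 20), c(340, 360)),
       yellow = rbind(c(20, 70)),
       green = rbind(c(70, 160)))
}

#' Birefringence colour area fractions
#'
#' Fraction of the cartilage mask whose hue falls in each configured band.
#' Near-black pixels (HSV value below `value_floor`) and near-grey pixels
#' (saturation below `saturation_floor`) carry no meaningful hue under the
#' black-background polarized acquisition and are excluded from every band;
#' they still count in the denominator, which is the full mask area, so the
#' three fractions need not sum to 1.
#'
#' @param masked An `oat_slide_image`, typically from [apply_mask()].
#' @param mask The `oat_cartilage_mask` defining the denominator.
#' @param hue_bands Band list as from [default_hue_bands()].
#' @param value_floor,saturation_floor HSV floors in [0, 1].
#' @return An `oat_birefringence` list with `red_fraction`,
#'   `yellow_fraction`, `green_fraction`.
#' @export
birefringence_fractions <- function(masked, mask,
                                    hue_bands = default_hue_bands(),
                                    value_floor = 0.15,
                                    saturation_floor = 0.2) {
  oat_check(is_slide_image(masked), "'masked' must be an oat_slide_image")
  oat_check(is_cartilage_mask(mask), "'mask' must be an oat_cartilage_mask")
  oat_check(all(dim(masked$rgb)[1:2] == dim(mask$mask)),
            "slide and mask shapes differ")
  n_mask <- sum(mask$mask)
  if (n_mask == 0L) {
    oat_stop("empty mask: colour fractions undefined", "oatopo_division")
  }
  sel <- which(mask$mask)
  rgbm <- rbind(masked$rgb[, , 1][sel], masked$rgb[, , 2][sel],
                masked$rgb[, , 3][sel])
  hsv <- grDevices::rgb2hsv(rgbm, maxColorValue = 255)
  hue <- hsv[1, ] * 360
  ok <- hsv[3, ] >= value_floor & hsv[2, ] >= saturation_floor
  frac <- vapply(hue_bands, function(band) {
    inb <- rep(FALSE, length(hue))
    for (r in seq_len(nrow(band))) {
      inb <- inb | (hue >= band[r, 1] & hue < band[r, 2])
    }
    sum(inb & ok) / n_mask
  }, numeric(1))
  structure(list(red_fraction = unname(frac["red"]),
                 yellow_fraction = unname(frac["yellow"]),
                 green_fraction = unname(frac["green"])),
            class = "oat_birefringence")
}

#' Count chondrocytes and compute cellularity
#'
#' Automated stand-in for the bench's manual three-operator count: cells
#' are detected as dark blobs inside the mask (grey threshold at Otsu's
#' level over the in-mask intensities, connected components, component area
#' gated to 25%-400% of the expected cell area). Cellularity is the count
#' divided by the cartilage area in mm^2. For manually counted slides use
#' [cellularity_from_counts()].
#'
#' @param image An `oat_slide_image`.
#' @param mask Non-empty `oat_cartilage_mask`.
#' @param expected_cell_radius_um Expected chondrocyte radius (um); sets
#'   the area gate centre.
#' @param threshold Grey threshold in [0, 255]; `NULL` = Otsu over in-mask
#'   pixels.
#' @param area_gate Two multipliers of the expected cell area accepted as
#'   a cell.
#' @return An `oat_cellularity` list: `cell_count`, `cartilage_area_um2`,
#'   `cellularity` (cells/mm^2).
#' @export
count_cells <- function(image, mask, expected_cell_radius_um = 5,
                        threshold = NULL, area_gate = c(0.25, 4)) {
  oat_check(is_slide_image(image), "'image' must be an oat_slide_image")
  oat_check(is_cartilage_mask(mask), "'mask' must be an oat_cartilage_mask")
  if (!any(mask$mask)) {
    oat_stop("empty mask: cellularity undefined", "oatopo_division")
  }
  g <- slide_grey(image, "luminance")
  if (is.null(threshold)) {
    v <- g[mask$mask] / 255
    threshold <- 255 * EBImage::otsu(EBImage::Image(matrix(v, 1)),
                                     range = c(0, 1))
  }
  bin <- (g < threshold) & mask$mask
  count <- 0L
  if (any(bin)) {
    lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
    areas <- tabulate(as.integer(lab)[as.integer(lab) > 0])
    exp_area_px <- pi * (expected_cell_radius_um / image$pixel_size)^2
    count <- sum(areas >= area_gate[1] * exp_area_px &
                   areas <= area_gate[2] * exp_area_px)
  }
  cellularity_from_counts(count, mask$area_um2)
}

#' Cellularity from typed operator counts
#'
#' @param counts One or more cell counts (e.g. one per operator); their
#'   mean is used.
#' @param area_um2 Cartilage area in square micrometres (> 0).
#' @return An `oat_cellularity` list (cellularity in cells/mm^2).
#' @export
cellularity_from_counts <- function(counts, area_um2) {
  oat_check(length(counts) >= 1L && all(counts >= 0),
            "'counts' must be non-negative")
  oat_check(area_um2 > 0, "'area_um2' must be positive", "oatopo_division")
  structure(list(cell_count = mean(counts), cartilage_area_um2 = area_um2,
                 cellularity = mean(counts) / (area_um2 / 1e6)),
            class = "oat_cellularity")
}

#' Aggregate Mankin-modified scores across operators
#'
#' The Mankin-modified score grades structure, cells, tidemark integrity
#' and matrix staining on a combined 0 (healthy) to 14 (most severe) scale;
#' each slide is scored independently by several operators and the mean and
#' sample standard deviation are reported.
#'
#' @param operator_scores Numeric vector of per-operator totals, each in
#'   [0, 14].
#' @param subscores Optional matrix (operators x components) whose row sums
#'   must equal the totals.
#' @return An `oat_mankin` list: `operator_scores`, `mean`, `sd` (NA for a
#'   single operator), `subscores`.
#' @examples
#' aggregate_mankin(c(3, 4, 5))
#' @export
aggregate_mankin <- function(operator_scores, subscores = NULL) {
  oat_check(length(operator_scores) >= 1L && all(is.finite(operator_scores)),
            "at least one finite operator total required")
  if (any(operator_scores < 0 | operator_scores > 14)) {
    oat_stop("Mankin totals must lie in [0, 14]", "oatopo_validation")
  }
  if (!is.null(subscores)) {
    subscores <- as.matrix(subscores)
    oat_check(nrow(subscores) == length(operator_scores),
              "one subscore row per operator required")
    oat_check(all(abs(rowSums(subscores) - operator_scores) < 1e-9),
              "subscores must sum to the operator totals")
  }
  structure(list(operator_scores = operator_scores,
                 mean = mean(operator_scores),
                 sd = if (length(operator_scores) > 1L)
                   stats::sd(operator_scores) else NA_real_,
                 subscores = subscores),
            class = "oat_mankin")
}

#' Mean grey intensity along a profile line
#'
#' Samples the grey-converted image along the rasterized segment between
#' two pixel coordinates (unit spacing along the longer axis, nearest-pixel
#' lookup, no sub-pixel interpolation) and reports the sampled intensities
#' and their mean. Used on the major defect of a slide.
#'
#' @param image An `oat_slide_image`.
#' @param start,end Pixel coordinates `c(row, col)`, 1-based, inside the
#'   image; `start` must differ from `end`.
#' @return An `oat_profile` list: `start`, `end`, `intensities`,
#'   `mean_intensity`.
#' @export
profile_line_intensity <- function(image, start, end) {
  oat_check(is_slide_image(image), "'image' must be an oat_slide_image")
  d <- dim(image$rgb)
  inb <- function(p) length(p) == 2L && all(p >= 1) &&
    p[1] <= d[1] && p[2] <= d[2]
  oat_check(inb(start) && inb(end), "profile endpoints must lie inside the image")
  if (all(start == end)) {
    oat_stop("zero-length profile line", "oatopo_validation")
  }
  n <- max(abs(end - start)) + 1
  rows <- round(seq(start[1], end[1], length.out = n))
  cols <- round(seq(start[2], end[2], length.out = n))
  g <- slide_grey(image, "luminance")
  intensities <- g[cbind(rows, cols)]
  structure(list(start = start, end = end, intensities = intensities,
                 mean_intensity = mean(intensities)),
            class = "oat_profile")
}
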