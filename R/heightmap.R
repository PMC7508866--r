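#' Height map of a cartilage surface
#'
#' A height map is the primary measurement of confocal white-light
#' profilometry: a rectangular grid of surface elevations z(x, y) sampled at
#' a constant lateral step. Rows index the y (antero-posterior) axis and
#' columns the x (medio-lateral) axis, so `heights[i, j]` is the elevation at
#' y = (i - 1) * step, x = (j - 1) * step.
#'
#' @param heights Numeric matrix of elevations in micrometres; all values
#'   must be finite.
#' @param step Lateral sampling step in micrometres (> 0). The study regime
#'   is 512 x 512 points at 1 um.
#' @param axes Named character vector tagging the axis convention.
#' @return An object of class `oat_height_map` with fields `heights`, `step`
#'   and `axes`.
#' @examples
#' hm <- height_map(outer(1:8, 1:8), step = 1)
#' dim(hm$heights)
#' @export
height_map <- function(heights, step = 1,
                       axes = c(x = "medio-lateral", y = "antero-posterior")) {
  oat_check(is.matrix(heights) && is.numeric(heights),
            "'heights' must be a numeric matrix")
  oat_check(all(is.finite(heights)), "height map contains non-finite values")
  oat_check(is.numeric(step) && length(step) == 1L && step > 0,
            "'step' must be a single positive number")
  structure(list(heights = heights, step = as.numeric(step), axes = axes),
            class = "oat_height_map")
}

#' @export
print.oat_height_map <- function(x, ...) {
  d <- dim(x$heights)
  cat(sprintf("<height map> %d x %d points, step %g um, z range [%.3g, %.3g] um\n",
              d[1], d[2], x$step, min(x$heights), max(x$heights)))
  invisible(x)
}

#' @export
dim.oat_height_map <- function(x) dim(x$heights)

is_height_map <- function(x) inherits(x, "oat_height_map")

#' Write a height map to disk
#'
#' Writes the grid as a headerless CSV (row-major, one CSV row per grid row)
#' or as a single-band 32-bit float TIFF, plus a JSON sidecar
#' (`<path>.json`) recording the step, the axis convention and -- for TIFF
#' -- the affine normalization applied, since float TIFF storage is defined
#' on [0, 1] only. CSV is lossless and is the canonical interchange format.
#'
#' @param hm An [height_map()] object.
#' @param path Output file path; format chosen by extension (`.csv`, `.tif`
#'   or `.tiff`).
#' @return `path`, invisibly.
#' @export
write_height_map <- function(hm, path) {
  oat_check(is_height_map(hm), "'hm' must be an oat_height_map")
  ext <- tolower(tools::file_ext(path))
  side <- list(step = hm$step, axes = as.list(hm$axes),
               n_rows = nrow(hm$heights), n_cols = ncol(hm$heights),
               format = ext)
  if (ext == "csv") {
    utils::write.table(hm$heights, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else if (ext %in% c("tif", "tiff")) {
    zmin <- min(hm$heights); zmax <- max(hm$heights)
    scale <- if (zmax > zmin) zmax - zmin else 1
    tiff::writeTIFF((hm$heights - zmin) / scale, path,
                    bits.per.sample = 32L, reduce = FALSE)
    side$z_offset <- zmin
    side$z_scale <- scale
  } else {
    oat_stop(sprintf("unsupported height map format '%s'", ext),
             "oatopo_validation")
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a height map written by [write_height_map()]
#'
#' @param path File path (`.csv`, `.tif` or `.tiff`); the JSON sidecar
#'   `<path>.json` must sit next to it.
#' @return An [height_map()] object.
#' @export
read_height_map <- function(path) {
  sidecar <- paste0(path, ".json")
  oat_check(file.exists(path), sprintf("no such file: %s", path))
  oat_check(file.exists(sidecar), sprintf("missing sidecar: %s", sidecar))
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    z <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
    dimnames(z) <- NULL
  } else if (ext %in% c("tif", "tiff")) {
    z <- tiff::readTIFF(path)
    if (length(dim(z)) == 3L) z <- z[, , 1L]
    z <- z * side$z_scale + side$z_offset
  } else {
    oat_stop(sprintf("unsupported height map format '%s'", ext),
             "oatopo_validation")
  }
  height_map(z, step = side$step)
}

#' Gaussian low-pass filter for height maps
#'
#' Separable Gaussian smoothing with mirror-reflection boundary handling,
#' the standard denoising step of surface metrology applied at the scale of
#' the instrument's lateral resolution. White measurement roughness splits
#' gradient maxima into spurious doublets and biases inter-maxima
#' wavelengths low; a kernel of a few micrometres removes that noise while
#' leaving the 8-28 um morphological band essentially untouched (a pure
#' sinusoid's maxima positions are invariant under linear filtering).
#'
#' @param hm An [height_map()] object.
#' @param sigma Kernel standard deviation in micrometres; 0 returns the
#'   input unchanged.
#' @return A smoothed [height_map()].
#' @export
smooth_height_map <- function(hm, sigma = 1.5) {
  oat_check(is_height_map(hm), "'hm' must be an oat_height_map")
  oat_check(is.numeric(sigma) && length(sigma) == 1L && sigma >= 0,
            "'sigma' must be a single non-negative number")
  if (sigma == 0) return(hm)
  height_map(gauss_smooth(hm$heights, sigma / hm$step), step = hm$step,
             axes = hm$axes)
}

#' Remove the best-fit plane from a height map
#'
#' Least-squares planar detrend, for acquisitions where the sample was not
#' level under the objective. Off by default throughout the package: the
#' wavelength estimators act on the gradient, which a planar tilt shifts
#' only by a constant.
#'
#' @param hm An [height_map()].
#' @return The detrended [height_map()].
#' @export
detrend_height_map <- function(hm) {
  oat_check(is_height_map(hm), "'hm' must be an oat_height_map")
  n <- nrow(hm$heights); m <- ncol(hm$heights)
  x <- rep((seq_len(m) - 1) * hm$step, each = n)
  y <- rep((seq_len(n) - 1) * hm$step, times = m)
  fit <- stats::lm.fit(cbind(1, x, y), as.vector(hm$heights))
  height_map(matrix(fit$residuals, n, m), step = hm$step, axes = hm$axes)
}

# separable gaussian convolution, reflect padding; sigma in pixels
gauss_smooth <- function(z, sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(-r:r, 0, sigma_px)
  k <- k / sum(k)
  smooth_rows <- function(m) {
    n <- nrow(m)
    ri <- pmin(pmax(seq(1L - r, n + r), 1L), n)   # indices with padding slots
    # reflect: positions below 1 map to 2 - i, above n to 2n - i
    lo <- seq_len(r); hi <- seq(n + 1L, n + r)
    ri[lo] <- pmin(1L + (r:1), n)
    ri[hi] <- pmax(n - (1:r), 1L)
    p <- m[ri, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * p[i:(i + n - 1L), , drop = FALSE]
    }
    out
  }
  t(smooth_rows(t(smooth_rows(z))))
}
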