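#' Gradient field of a height map
#'
#' Finite-difference gradient of the surface elevations: central
#' differences in the interior, one-sided differences at the borders. The
#' in-plane components del z / del x and del z / del y carry all the
#' wavelength information; the constant third component of the full
#' gradient operator plays no role in maxima extraction.
#'
#' @param hm An [height_map()] with at least 3 points per axis.
#' @return An `oat_gradient` object with matrices `dz_dx`, `dz_dy`
#'   (dimensionless, um/um) of the same shape as the input, plus `step`.
#' @examples
#' hm <- height_map(outer(1:8, 1:8, function(i, j) 2 * j + 3 * i))
#' g <- compute_gradient(hm)
#' unique(as.vector(g$dz_dx))
#' @export
compute_gradient <- function(hm) {
  oat_check(is_height_map(hm), "'hm' must be an oat_height_map")
  d <- dim(hm$heights)
  oat_check(all(d >= 3), "gradient needs at least 3 points per axis")
  g <- pracma::gradient(hm$heights, h1 = hm$step, h2 = hm$step)
  structure(list(dz_dx = g$X, dz_dy = g$Y, step = hm$step),
            class = "oat_gradient")
}

#' Inter-maxima spacings of the gradient, per scan line
#'
#' Locates strict local maxima of the signed derivative along every scan
#' line -- rows of dz/dx for the x axis, columns of dz/dy for the y axis --
#' and records the distances between successive maxima. A plateau of equal
#' values flanked by strictly lower neighbours contributes its midpoint.
#' Signed (not absolute) derivatives are essential: |dz/dx| of a sinusoid
#' peaks twice per period and would halve every wavelength, whereas the
#' signed derivative peaks exactly once per period.
#'
#' Line endpoints cannot host a maximum, which also keeps the one-sided
#' border stencils out of the detection. Lines whose derivative range is
#' below 1e-10 (numerically flat, e.g. a zero-energy spectral sector) are
#' treated as featureless and contribute no maxima.
#'
#' @param gf An `oat_gradient` from [compute_gradient()].
#' @param step Sampling step in micrometres; defaults to the one recorded
#'   in `gf`.
#' @param min_prominence Optional minimum peak prominence (derivative
#'   units): a maximum is kept only if it rises at least this much above
#'   the higher of its two adjacent valleys. Default 0 keeps every strict
#'   maximum.
#' @return An `oat_line_spacings` object: `spacings_x` (list, one numeric
#'   vector of spacings in um per row), `spacings_y` (per column), counts
#'   `n_maxima_x`, `n_maxima_y`, and `step`.
#' @export
extract_line_spacings <- function(gf, step = gf$step, min_prominence = 0) {
  oat_check(inherits(gf, "oat_gradient"), "'gf' must come from compute_gradient()")
  oat_check(min_prominence >= 0, "'min_prominence' must be non-negative")
  sx <- apply(gf$dz_dx, 1L, function(v) diff(line_maxima(v, min_prominence)) * step,
              simplify = FALSE)
  sy <- apply(gf$dz_dy, 2L, function(v) diff(line_maxima(v, min_prominence)) * step,
              simplify = FALSE)
  structure(list(spacings_x = sx, spacings_y = sy,
                 n_maxima_x = sum(lengths(sx) + (lengths(sx) > 0)),
                 n_maxima_y = sum(lengths(sy) + (lengths(sy) > 0)),
                 step = step),
            class = "oat_line_spacings")
}

# strict local maxima of one line, plateau midpoints, optional prominence;
# returns (possibly fractional) 1-based positions
line_maxima <- function(v, min_prominence = 0) {
  n <- length(v)
  if (n < 3L || diff(range(v)) < 1e-10) return(numeric(0))
  d <- sign(diff(v))
  idx <- which(d != 0)
  if (length(idx) < 2L) return(numeric(0))
  dd <- d[idx]
  ch <- which(dd[-length(dd)] == 1 & dd[-1] == -1)   # rise followed by fall
  if (length(ch) == 0L) return(numeric(0))
  pos <- vapply(ch, function(k) (idx[k] + 1 + idx[k + 1]) / 2, numeric(1))
  if (min_prominence > 0) {
    lo <- floor(pos); peaks <- v[lo]
    bounds <- c(1L, lo, n)
    keep <- vapply(seq_along(pos), function(i) {
      left <- min(v[bounds[i]:lo[i]])
      right <- min(v[lo[i]:bounds[i + 2L]])
      peaks[i] - max(left, right) >= min_prominence
    }, logical(1))
    pos <- pos[keep]
  }
  pos
}

#' Mean inter-maxima wavelengths of a surface
#'
#' The per-axis wavelength is the average over scan lines of each line's
#' mean inter-maxima spacing; lines with fewer than two maxima contribute
#' nothing. Averaging per line first (rather than pooling all spacings and
#' dividing by the image size) makes the estimator equal the physical
#' period on a pure sinusoid.
#'
#' @param ls An `oat_line_spacings` from [extract_line_spacings()].
#' @return An `oat_wavelength_pair` with `lambda_x` and `lambda_y` in
#'   micrometres.
#' @section Errors: if an axis has no spacings at all, an
#'   `oatopo_undefined_wavelength` error naming the axis is raised.
#' @export
mean_wavelengths <- function(ls) {
  oat_check(inherits(ls, "oat_line_spacings"),
            "'ls' must come from extract_line_spacings()")
  wavelength_pair(axis_wavelength(ls$spacings_x, "x"),
                  axis_wavelength(ls$spacings_y, "y"))
}

axis_wavelength <- function(spacings, axis) {
  per_line <- vapply(spacings, function(s) if (length(s)) mean(s) else NA_real_,
                     numeric(1))
  per_line <- per_line[!is.na(per_line)]
  if (length(per_line) == 0L) {
    oat_stop(sprintf("wavelength undefined along axis %s: no gradient maxima",
                     axis),
             "oatopo_undefined_wavelength", axis = axis)
  }
  mean(per_line)
}

#' @rdname mean_wavelengths
#' @param lambda_x,lambda_y Wavelengths in micrometres (> 0).
#' @export
wavelength_pair <- function(lambda_x, lambda_y) {
  oat_check(lambda_x > 0 && lambda_y > 0, "wavelengths must be positive")
  structure(list(lambda_x = lambda_x, lambda_y = lambda_y),
            class = "oat_wavelength_pair")
}

#' @export
print.oat_wavelength_pair <- function(x, ...) {
  cat(sprintf("<wavelengths> lambda_x = %.3f um, lambda_y = %.3f um\n",
              x$lambda_x, x$lambda_y))
  invisible(x)
}

#' Wavelengths of a height map in one call
#'
#' Convenience chain: optional Gaussian denoising ([smooth_height_map()]),
#' gradient, signed-maxima spacing extraction and per-line averaging.
#'
#' @param hm An [height_map()].
#' @param smooth_sigma Gaussian sigma in micrometres passed to
#'   [smooth_height_map()]; 0 disables denoising. Default 1.5, i.e. 1.5x
#'   the study's 1 um lateral resolution.
#' @param min_prominence Passed to [extract_line_spacings()].
#' @return An `oat_wavelength_pair`.
#' @export
surface_wavelengths <- function(hm, smooth_sigma = 1.5, min_prominence = 0) {
  hm <- smooth_height_map(hm, smooth_sigma)
  mean_wavelengths(extract_line_spacings(compute_gradient(hm),
                                         min_prominence = min_prominence))
}

#' Deformation ratio between an OA surface and its healthy reference
#'
#' Relative change of the mean inter-maxima wavelength per axis,
#' `eps = (lambda_OA - lambda_Healthy) / lambda_Healthy`, reported as a
#' fraction (0.417, not 41.7). A negative value indicates cartilage
#' compression, a positive value extension.
#'
#' @param oa,healthy `oat_wavelength_pair` objects.
#' @return An `oat_deformation_ratio` with fields `eps_x`, `eps_y`.
#' @examples
#' deformation_ratio(wavelength_pair(14.17, 14.17), wavelength_pair(10, 10))
#' @export
deformation_ratio <- function(oa, healthy) {
  oat_check(inherits(oa, "oat_wavelength_pair") &&
              inherits(healthy, "oat_wavelength_pair"),
            "both arguments must be oat_wavelength_pair objects")
  if (healthy$lambda_x <= 0 || healthy$lambda_y <= 0) {
    oat_stop("healthy reference wavelength must be positive",
             "oatopo_division")
  }
  structure(list(eps_x = (oa$lambda_x - healthy$lambda_x) / healthy$lambda_x,
                 eps_y = (oa$lambda_y - healthy$lambda_y) / healthy$lambda_y),
            class = "oat_deformation_ratio")
}

#' @export
print.oat_deformation_ratio <- function(x, percent = FALSE, ...) {
  f <- if (percent) 100 else 1
  u <- if (percent) " %" else ""
  cat(sprintf("<deformation ratio> eps_x = %.3f%s, eps_y = %.3f%s\n",
              f * x$eps_x, u, f * x$eps_y, u))
  invisible(x)
}
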