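#' Angular-sector decomposition of a height map
#'
#' Partitions the 2D Fourier coefficients of the surface by the polar angle
#' of their spatial-frequency vector into the 0-90 degree and 90-180 degree
#' sectors and inverse-transforms each part, yielding two direction-filtered
#' surfaces. Because a real surface's spectrum is conjugate-symmetric, the
#' angle is taken modulo 180 degrees, which assigns every conjugate pair to
#' one sector and keeps both reconstructions real.
#'
#' Conventions: theta = 0 (pure x frequency) belongs to sector 1, theta =
#' 90 degrees (pure y) to sector 2. The DC bin is excluded from both, so
#' both reconstructions are zero-mean and `s1 + s2 + mean(hm)` restores the
#' input to floating precision. On even-sized grids the Nyquist row/column
#' frequencies are sign-ambiguous (+1/2 and -1/2 cycles/sample coincide);
#' their bins are assigned by the same angle rule after canonicalizing the
#' ambiguous component to its absolute value, which keeps conjugate pairs
#' together there too.
#'
#' @param hm An [height_map()].
#' @return List with `s1` and `s2`, zero-mean [height_map()]s of the same
#'   shape and step as the input, and `mean`, the excluded surface mean.
#' @export
sector_decompose <- function(hm) {
  oat_check(is_height_map(hm), "'hm' must be an oat_height_map")
  z <- hm$heights
  nr <- nrow(z); nc <- ncol(z)
  F <- stats::fft(z)
  msk <- sector_masks(nr, nc)
  s1 <- Re(stats::fft(F * msk$s1, inverse = TRUE)) / (nr * nc)
  s2 <- Re(stats::fft(F * msk$s2, inverse = TRUE)) / (nr * nc)
  list(s1 = height_map(s1, step = hm$step, axes = hm$axes),
       s2 = height_map(s2, step = hm$step, axes = hm$axes),
       mean = mean(z))
}

# signed DFT frequencies in cycles/sample; the Nyquist bin (even n) maps to +1/2
dft_freqs <- function(n) {
  k <- 0:(n - 1)
  ifelse(k <= n / 2, k, k - n) / n
}

sector_masks <- function(nr, nc) {
  fx <- dft_freqs(nc); fy <- dft_freqs(nr)
  FX <- matrix(fx, nr, nc, byrow = TRUE)
  FY <- matrix(fy, nr, nc)
  FXc <- FX; FYc <- FY
  flip <- FYc < 0 | (FYc == 0 & FXc < 0)
  FXc[flip] <- -FXc[flip]; FYc[flip] <- -FYc[flip]
  # Nyquist lines (even sizes): +1/2 and -1/2 cycles/sample coincide, so the
  # conjugate of a bin on such a line stays on the line with the other
  # component negated. Canonicalize per line -- the x-Nyquist column to
  # angles below 90 deg (sector 1), the y-Nyquist row to angles above
  # (sector 2) -- which keeps conjugate pairs together and, unlike sending
  # both lines to one sector, preserves the energy balance of isotropic
  # surfaces under 90-degree rotation.
  ny_row <- abs(FY) == 0.5   # y-Nyquist row
  ny_col <- abs(FX) == 0.5   # x-Nyquist column
  FYc[ny_row] <- 0.5
  FXc[ny_row & !ny_col] <- -abs(FX[ny_row & !ny_col])
  FXc[ny_col] <- 0.5
  FYc[ny_col & !ny_row] <- abs(FY[ny_col & !ny_row])
  theta <- atan2(FYc, FXc) * 180 / pi
  s1 <- theta < 90
  s1[1, 1] <- FALSE                      # DC excluded from both sectors
  s2 <- !s1
  s2[1, 1] <- FALSE
  list(s1 = s1, s2 = s2)
}

#' Sector wavelengths of a height map
#'
#' Applies the full wavelength chain (denoise, gradient, signed-maxima
#' spacings, per-line means) to each angular-sector reconstruction of the
#' surface, yielding the four sector wavelength means that feed the
#' cohesion indices.
#'
#' @inheritParams surface_wavelengths
#' @return An `oat_sector_wavelengths` object with fields `lambda_x_s1`,
#'   `lambda_x_s2`, `lambda_y_s1`, `lambda_y_s2` (micrometres; s1 = 0-90
#'   degrees, s2 = 90-180 degrees) and an `audit` list holding the
#'   per-sector wavelength pairs.
#' @section Errors: a sector reconstruction with no detectable maxima on
#'   some axis (e.g. a zero-energy sector of a pure axis-aligned sinusoid)
#'   raises an `oatopo_undefined_wavelength` error naming sector and axis.
#' @export
sector_wavelengths <- function(hm, smooth_sigma = 1.5, min_prominence = 0) {
  dec <- sector_decompose(hm)
  wp <- lapply(c(s1 = "s1", s2 = "s2"), function(s) {
    tryCatch(
      surface_wavelengths(dec[[s]], smooth_sigma = smooth_sigma,
                          min_prominence = min_prominence),
      oatopo_undefined_wavelength = function(e) {
        oat_stop(sprintf("sector %s (%s): %s", s,
                         if (s == "s1") "0-90 deg" else "90-180 deg",
                         conditionMessage(e)),
                 "oatopo_undefined_wavelength", axis = e$axis, sector = s)
      })
  })
  structure(list(lambda_x_s1 = wp$s1$lambda_x, lambda_x_s2 = wp$s2$lambda_x,
                 lambda_y_s1 = wp$s1$lambda_y, lambda_y_s2 = wp$s2$lambda_y,
                 audit = wp),
            class = "oat_sector_wavelengths")
}

#' Cohesion indices
#'
#' Normalized absolute imbalance between the mean wavelengths of the two
#' angular sectors, per axis:
#' `I = |lambda_s1 - lambda_s2| / min(lambda_s1, lambda_s2)`,
#' reported as a fraction. The denominator convention (the smaller of the
#' two sector means, recorded in the output for audit) keeps the index
#' dimensionless, non-negative, zero at perfect balance and symmetric
#' under swapping the sector labels. The more cohesive and isotropic the
#' collagen network, the closer both indices are to zero.
#'
#' @param sw An `oat_sector_wavelengths` from [sector_wavelengths()].
#' @return An `oat_cohesion_index` with `I_x`, `I_y` and the denominators
#'   `lambda_min_x`, `lambda_min_y`.
#' @examples
#' sw <- structure(list(lambda_x_s1 = 12, lambda_x_s2 = 10,
#'                      lambda_y_s1 = 10, lambda_y_s2 = 10),
#'                 class = "oat_sector_wavelengths")
#' cohesion_index(sw)$I_x   # 0.2
#' @export
cohesion_index <- function(sw) {
  oat_check(inherits(sw, "oat_sector_wavelengths"),
            "'sw' must come from sector_wavelengths()")
  lmx <- min(sw$lambda_x_s1, sw$lambda_x_s2)
  lmy <- min(sw$lambda_y_s1, sw$lambda_y_s2)
  if (lmx <= 0 || lmy <= 0) {
    oat_stop("cohesion index undefined: non-positive sector wavelength",
             "oatopo_division")
  }
  structure(list(I_x = abs(sw$lambda_x_s1 - sw$lambda_x_s2) / lmx,
                 I_y = abs(sw$lambda_y_s1 - sw$lambda_y_s2) / lmy,
                 lambda_min_x = lmx, lambda_min_y = lmy),
            class = "oat_cohesion_index")
}

#' @export
print.oat_cohesion_index <- function(x, percent = FALSE, ...) {
  f <- if (percent) 100 else 1
  u <- if (percent) " %" else ""
  cat(sprintf("<cohesion index> I_x = %.3f%s, I_y = %.3f%s\n",
              f * x$I_x, u, f * x$I_y, u))
  invisible(x)
}
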