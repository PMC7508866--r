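#' Specification of a synthetic cartilage surface
#'
#' Describes a seeded random surface emulating confocal height maps of
#' articular cartilage: a small bank of sinusoids per axis with wavelengths
#' drawn tightly around a controllable dominant wavelength, a mirrored pair
#' of oblique plane waves that places comparable spectral content in both
#' angular sectors (so a healthy surface is approximately isotropic and its
#' cohesion indices are near zero), and white Gaussian roughness.
#'
#' @param n_rows,n_cols Grid size in points (>= 16); the study regime is
#'   512 x 512.
#' @param step Lateral sampling step in micrometres (> 0); study value 1.
#' @param base_wavelength_x,base_wavelength_y Dominant inter-maxima
#'   wavelength along each axis, micrometres. Must be at least `2 * step`
#'   (Nyquist). The study's observed band is 8-28 um.
#' @param amplitude Height amplitude scale in micrometres (> 0). Real
#'   cartilage roughness amplitude is not reported by profilometry studies
#'   at this scale; 1 um is a free default.
#' @param phase_jitter Fraction in [0, 1] of the full 2*pi range over which
#'   component phases are randomized; 1 = fully random phases.
#' @param noise_sd Standard deviation of the white roughness, micrometres
#'   (>= 0). Default 0.05, i.e. 5% of the default amplitude.
#' @param seed Integer seed; all randomness of the generator flows from it.
#' @return A validated `oat_surface_spec` list.
#' @export
surface_spec <- function(n_rows = 512, n_cols = 512, step = 1,
                         base_wavelength_x = 15, base_wavelength_y = 15,
                         amplitude = 1, phase_jitter = 1, noise_sd = 0.05,
                         seed = 1L) {
  spec <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
               step = step, base_wavelength_x = base_wavelength_x,
               base_wavelength_y = base_wavelength_y, amplitude = amplitude,
               phase_jitter = phase_jitter, noise_sd = noise_sd,
               seed = as.integer(seed))
  oat_check(spec$n_rows >= 16 && spec$n_cols >= 16,
            "grid must be at least 16 x 16 points")
  oat_check(step > 0, "'step' must be positive")
  if (base_wavelength_x < 2 * step || base_wavelength_y < 2 * step) {
    oat_stop(sprintf(
      "base wavelength below the Nyquist limit 2 * step = %g um", 2 * step),
      "oatopo_nyquist")
  }
  oat_check(amplitude > 0, "'amplitude' must be positive")
  oat_check(phase_jitter >= 0 && phase_jitter <= 1,
            "'phase_jitter' must lie in [0, 1]")
  oat_check(noise_sd >= 0, "'noise_sd' must be non-negative")
  structure(spec, class = "oat_surface_spec")
}

# number of sinusoids per axis and their relative weights; off-dominant
# components are drawn within +/- 4% of the base wavelength
.bank_weights <- c(1, 0.2, 0.2, 0.15, 0.15)
.bank_spread <- 0.04
.oblique_weight <- 0.5

#' Generate a synthetic cartilage height map
#'
#' Deterministic for a fixed spec: the same seed yields a bit-identical
#' grid. With `noise_sd = 0` the dominant spacing of the signed-derivative
#' maxima along x (resp. y) equals `base_wavelength_x` (resp. `_y`) to
#' within one sampling step.
#'
#' @param spec An [surface_spec()].
#' @return An [height_map()]; the generating spec is attached as attribute
#'   `"spec"`.
#' @examples
#' hm <- generate_surface(surface_spec(n_rows = 64, n_cols = 64, seed = 3))
#' @export
generate_surface <- function(spec) {
  oat_check(inherits(spec, "oat_surface_spec"),
            "'spec' must come from surface_spec()")
  z <- withr::with_seed(spec$seed, surface_field(spec))
  hm <- height_map(z, step = spec$step)
  attr(hm, "spec") <- spec
  hm
}

surface_field <- function(spec) {
  n <- spec$n_rows; m <- spec$n_cols
  x <- (seq_len(m) - 1) * spec$step
  y <- (seq_len(n) - 1) * spec$step
  K <- length(.bank_weights)
  A <- spec$amplitude
  dlx <- c(0, stats::runif(K - 1, -.bank_spread, .bank_spread))
  dly <- c(0, stats::runif(K - 1, -.bank_spread, .bank_spread))
  phx <- spec$phase_jitter * stats::runif(K, 0, 2 * pi)
  phy <- spec$phase_jitter * stats::runif(K, 0, 2 * pi)
  z <- matrix(0, n, m)
  for (k in seq_len(K)) {
    lx <- spec$base_wavelength_x * (1 + dlx[k])
    ly <- spec$base_wavelength_y * (1 + dly[k])
    z <- z + A * .bank_weights[k] *
      matrix(sin(2 * pi * x / lx + phx[k]), n, m, byrow = TRUE)
    z <- z + A * .bank_weights[k] *
      matrix(sin(2 * pi * y / ly + phy[k]), n, m)
  }
  # mirrored oblique pair: one wavevector in each angular sector, with the
  # same per-axis periods as the banks, keeps the two sectors balanced
  pho <- spec$phase_jitter * stats::runif(2, 0, 2 * pi)
  fo <- sqrt(1 / spec$base_wavelength_x^2 + 1 / spec$base_wavelength_y^2)
  if (fo <= 0.5 / spec$step) {
    X <- matrix(x, n, m, byrow = TRUE)
    Y <- matrix(y, n, m)
    z <- z + .oblique_weight * A *
      sin(2 * pi * (X / spec$base_wavelength_x + Y / spec$base_wavelength_y) + pho[1])
    z <- z + .oblique_weight * A *
      sin(2 * pi * (X / spec$base_wavelength_x - Y / spec$base_wavelength_y) + pho[2])
  }
  if (spec$noise_sd > 0) {
    z <- z + matrix(stats::rnorm(n * m, 0, spec$noise_sd), n, m)
  }
  z
}

#' Specification of a paired healthy/OA surface
#'
#' The OA member is derived from the healthy member's grid, not drawn
#' independently: its coordinates are stretched by the given factors, so
#' the downstream deformation ratio has an exact ground truth
#' (`eps = stretch - 1` per axis), and an angular-sector wavelength
#' imbalance can be planted with a known magnitude.
#'
#' @param healthy An [surface_spec()] for the healthy reference surface.
#' @param stretch_x,stretch_y Wavelength stretch factors (> 0) applied to
#'   the OA member; values > 1 emulate extension, < 1 compression.
#' @param sector_imbalance Fraction in [0, 1]; dilates the OA member's
#'   90-180 degree spectral sector along the x axis only, multiplying that
#'   sector's x wavelengths by `1 + sector_imbalance`. This drives the
#'   cohesion index I_x up monotonically while leaving the surface's
#'   y-direction content (and hence the y deformation ratio) untouched:
#'   the planted anisotropy is a sector-selective effect, as a loss of
#'   biaxial tension balance would be.
#' @param seed Integer seed (reserved for imbalance randomization; the pair
#'   itself is fully determined by the healthy spec and the factors).
#' @return A validated `oat_pair_spec` list.
#' @export
pair_spec <- function(healthy, stretch_x = 1, stretch_y = 1,
                      sector_imbalance = 0, seed = healthy$seed) {
  oat_check(inherits(healthy, "oat_surface_spec"),
            "'healthy' must come from surface_spec()")
  oat_check(stretch_x > 0 && stretch_y > 0, "stretch factors must be positive")
  oat_check(sector_imbalance >= 0 && sector_imbalance <= 1,
            "'sector_imbalance' must lie in [0, 1]")
  structure(list(healthy = healthy, stretch_x = stretch_x,
                 stretch_y = stretch_y, sector_imbalance = sector_imbalance,
                 seed = as.integer(seed)),
            class = "oat_pair_spec")
}

#' Generate a healthy/OA surface pair
#'
#' @param pair An [pair_spec()].
#' @return A list with elements `healthy` and `oa` (both [height_map()]s)
#'   and the ground-truth factors `stretch_x`, `stretch_y`,
#'   `sector_imbalance`.
#' @export
generate_pair <- function(pair) {
  oat_check(inherits(pair, "oat_pair_spec"), "'pair' must come from pair_spec()")
  healthy <- generate_surface(pair$healthy)
  z <- resample_stretch(healthy$heights, pair$stretch_x, pair$stretch_y)
  if (pair$sector_imbalance > 0) {
    hm0 <- height_map(z, step = healthy$step)
    dec <- sector_decompose(hm0)
    s2d <- resample_stretch(dec$s2$heights, 1 + pair$sector_imbalance, 1)
    z <- dec$s1$heights + s2d + mean(z)
  }
  list(healthy = healthy, oa = height_map(z, step = healthy$step),
       stretch_x = pair$stretch_x, stretch_y = pair$stretch_y,
       sector_imbalance = pair$sector_imbalance)
}

# evaluate z at (x / sx, y / sy) by bilinear interpolation; coordinates
# beyond the grid (stretch < 1) are folded back by mirror reflection
resample_stretch <- function(z, sx, sy) {
  n <- nrow(z); m <- ncol(z)
  xi <- mirror_fold((seq_len(m) - 1) / sx, m)
  yi <- mirror_fold((seq_len(n) - 1) / sy, n)
  x0 <- pmin(floor(xi), m - 2); y0 <- pmin(floor(yi), n - 2)
  fx <- xi - x0; fy <- yi - y0
  FX <- matrix(fx, n, m, byrow = TRUE); FY <- matrix(fy, n, m)
  i0 <- matrix(y0 + 1, n, m); j0 <- matrix(x0 + 1, n, m, byrow = TRUE)
  pick <- function(di, dj) z[cbind(as.vector(i0 + di), as.vector(j0 + dj))]
  out <- (1 - FX) * (1 - FY) * pick(0, 0) + FX * (1 - FY) * pick(0, 1) +
    (1 - FX) * FY * pick(1, 0) + FX * FY * pick(1, 1)
  matrix(out, n, m)
}

# fold a continuous 0-based coordinate into [0, n - 1] by reflection
mirror_fold <- function(t, n) {
  p <- abs(t)
  period <- 2 * (n - 1)
  r <- p %% period
  ifelse(r > (n - 1), period - r, r)
}
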