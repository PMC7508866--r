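# Independent oracles and fixture builders used across the suite.

# plaid surface: independent sinusoids along x and y, so each axis carries a
# pure period; amplitude in um
plaid_surface <- function(lambda_x, lambda_y = lambda_x, n = 256, step = 1,
                          amplitude = 1) {
  x <- (seq_len(n) - 1) * step
  y <- (seq_len(n) - 1) * step
  z <- amplitude * (matrix(sin(2 * pi * x / lambda_x), n, n, byrow = TRUE) +
                      matrix(sin(2 * pi * y / lambda_y), n, n))
  height_map(z, step = step)
}

# Kruskal-Wallis H by the textbook rank formula with tie correction,
# independent of stats::kruskal.test
kw_H_oracle <- function(values_list) {
  x <- unlist(values_list)
  N <- length(x)
  r <- rank(x)
  off <- 0L
  ssq <- 0
  for (v in values_list) {
    ri <- r[(off + 1):(off + length(v))]
    ssq <- ssq + length(v) * mean(ri)^2
    off <- off + length(v)
  }
  H <- 12 / (N * (N + 1)) * ssq - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# hue in degrees from 8-bit RGB, written out from first principles so the
# band-count oracle does not share code with the implementation
hue_oracle <- function(r, g, b) {
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- mx - mn
  h <- ifelse(d == 0, 0,
              ifelse(mx == r, ((g - b) / d) %% 6,
                     ifelse(mx == g, (b - r) / d + 2, (r - g) / d + 4)))
  (h * 60) %% 360
}

# brute-force band fraction over an RGB array restricted to a mask
band_fraction_oracle <- function(rgb, mask, lo, hi, value_floor = 0.15,
                                 sat_floor = 0.2) {
  sel <- which(mask)
  r <- rgb[, , 1][sel]; g <- rgb[, , 2][sel]; b <- rgb[, , 3][sel]
  h <- hue_oracle(r, g, b)
  v <- pmax(r, g, b) / 255
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  s <- ifelse(mx == 0, 0, (mx - mn) / mx)
  inb <- rep(FALSE, length(h))
  for (k in seq_along(lo)) inb <- inb | (h >= lo[k] & h < hi[k])
  sum(inb & v >= value_floor & s >= sat_floor) / length(sel)
}

# small helper: line-spacings object from explicit per-line spacing lists
spacings_fixture <- function(sx, sy, step = 1) {
  structure(list(spacings_x = sx, spacings_y = sy,
                 n_maxima_x = sum(lengths(sx) + (lengths(sx) > 0)),
                 n_maxima_y = sum(lengths(sy) + (lengths(sy) > 0)),
                 step = step),
            class = "oat_line_spacings")
}

# gradient-field object from explicit derivative matrices
gradient_fixture <- function(dz_dx, dz_dy, step = 1) {
  structure(list(dz_dx = dz_dx, dz_dy = dz_dy, step = step),
            class = "oat_gradient")
}

# a reduced study configuration that keeps pipeline tests fast
small_config <- function(dir, seed = 7L) {
  cfg <- default_config(out_dir = dir, seed = seed)
  cfg$simulate$n_per_model <- 2L
  cfg$simulate$surface$n_rows <- 128L
  cfg$simulate$surface$n_cols <- 128L
  cfg$simulate$slide$width <- 320L
  cfg$simulate$slide$height <- 320L
  for (g in names(cfg$simulate$slide_groups)) {
    cfg$simulate$slide_groups[[g]]$n_cells <-
      round(cfg$simulate$slide_groups[[g]]$n_cells / 4)
  }
  cfg
}
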