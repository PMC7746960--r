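# Lattice and map fixtures, all generated in code.

# triangular (hexagonal-packing) lattice covering [0, width] x [0, height]
# with margin on all sides so window-interior cells see a full neighbour ring
hex_points <- function(s, width, height, margin = 3 * s) {
  ny <- ceiling((height + 2 * margin) / (s * sqrt(3) / 2))
  nx <- ceiling((width + 2 * margin) / s) + 1
  pts <- do.call(rbind, lapply(0:ny, function(j) {
    x <- (0:nx) * s + (j %% 2) * s / 2 - margin
    cbind(x, j * s * sqrt(3) / 2 - margin)
  }))
  pts[pts[, 1] > -margin & pts[, 1] < width + margin &
      pts[, 2] > -margin & pts[, 2] < height + margin, , drop = FALSE]
}

hex_mosaic <- function(s, width = 100, height = 100, scale = 1,
                       jitter_sd = 0, seed = NULL) {
  pts <- hex_points(s, width, height)
  if (jitter_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    pts <- pts + matrix(rnorm(length(pts), 0, jitter_sd), ncol = 2)
  }
  off <- 4 * s
  pts <- pts + off
  cone_mosaic(pts / scale, scale = scale,
              extent = (c(width, height) + 2 * off + 4 * s) / scale)
}

square_mosaic <- function(s, width = 100, height = 100, scale = 1) {
  pts <- as.matrix(expand.grid(x = seq(0, width + 6 * s, by = s),
                               y = seq(0, height + 6 * s, by = s)))
  cone_mosaic(pts / scale, scale = scale,
              extent = (c(width, height) + 12 * s) / scale)
}

# analytic anisotropic Gaussian density surface as a scalar_map
gaussian_map <- function(peak = 180000, sx = 40, sy = 40, extent = 300,
                         scale = 1, center = c(extent / 2, extent / 2)) {
  n <- round(extent / scale)
  xc <- (seq_len(n) - 0.5) * scale
  yc <- (seq_len(n) - 0.5) * scale
  v <- outer(yc, xc, function(y, x)
    peak * exp(-((x - center[1])^2 / (2 * sx^2) +
                 (y - center[2])^2 / (2 * sy^2))))
  scalar_map(v, scale = scale, quantity = "density")
}

# compact low-eccentricity-falloff spec: fast to generate and to map, with
# all five contours well inside the 300-um region
small_spec <- function(seed = 1, peak = 150000, jitter = 0.27, boost = 0,
                       sx = 52, sy = 42) {
  synthetic_fovea_spec(peak_density = peak, falloff_sigma_x = sx,
                       falloff_sigma_y = sy, jitter = jitter,
                       center_jitter_boost = boost, seed = seed)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / abs(expected), tol)
}
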