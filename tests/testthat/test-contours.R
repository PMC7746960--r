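# analytic Gaussian surfaces: level set at fraction f of the peak is an
# ellipse with semi-axes sigma * sqrt(2 log(1/f)); centres are placed
# slightly off the pixel-grid symmetry point so the discrete peak is unique

test_that("isodensity contours of a Gaussian surface match the closed form", {
  sx <- 30
  g <- gaussian_map(peak = 2e5, sx = sx, sy = sx, extent = 300, scale = 1,
                    center = c(150.3, 150.2))
  ct <- extract_contour(g, 0.80)
  r_exp <- sx * sqrt(2 * log(1 / 0.8))   # ~0.668 * sigma
  rad <- sqrt((ct$polygon[, 1] - 150.3)^2 + (ct$polygon[, 2] - 150.2)^2)
  expect_lt(max(abs(rad - r_exp)) / r_exp, 0.01)
  expect_true(ct$complete)
  expect_equal(ct$level, 0.8 * extract_peak(g)$value, tolerance = 1e-12)
  expect_rel(ct$area_mm2, pi * r_exp^2 / 1e6, 0.01)
  expect_rel(ct$roundness, 1, 0.02)
  expect_error(extract_contour(g, 1.2), class = "invalid_parameter")
  # a flat map never crosses a sub-peak level: no contour exists
  flat <- scalar_map(matrix(10, 50, 50), scale = 1)
  pk_flat <- suppressWarnings(extract_peak(flat))
  expect_error(suppressWarnings(extract_contour(flat, 0.8, peak = pk_flat)),
               class = "contour_not_found")
})

test_that("contours nest and enclosed area decreases with the fraction", {
  g <- gaussian_map(peak = 1.8e5, sx = 45, sy = 34, extent = 300, scale = 1,
                    center = c(150.3, 150.2))
  fr <- c(0.70, 0.75, 0.80, 0.85, 0.90)
  cts <- lapply(fr, function(f) extract_contour(g, f))
  areas <- sapply(cts, `[[`, "area_mm2")
  expect_true(all(diff(areas) < 0))
  for (k in 2:length(cts)) {
    inner <- cts[[k]]$polygon
    outer <- cts[[k - 1]]$polygon
    expect_true(all(mgcv::in.out(rbind(outer, outer[1, ]), inner)))
  }
})

test_that("anisotropic Gaussian contours report roundness sigma_y / sigma_x", {
  k <- 1.5
  g <- gaussian_map(peak = 2e5, sx = 40 * k, sy = 40, extent = 300, scale = 1,
                    center = c(150.3, 150.2))
  cs <- summarize_contours(g)
  expect_true(cs$usable)
  expect_rel(cs$mean_roundness, 1 / k, 0.02)
  # the major axis is horizontal: check via the 80% contour's x/y extents
  ct <- cs$contours$f80
  expect_gt(diff(range(ct$polygon[, 1])), diff(range(ct$polygon[, 2])))
})

test_that("equivalent ellipse reproduces shape moments", {
  th <- seq(0, 2 * pi, length.out = 513)[-513]
  circ <- cbind(10 + 7 * cos(th), -3 + 7 * sin(th))
  ax <- equivalent_ellipse(circ, method = "polygon")
  expect_rel(ax["major"], 14, 0.005)
  expect_rel(ax["minor"], 14, 0.005)

  ell <- cbind(4 * cos(th), 2 * sin(th))   # semi-axes (2a, a), a = 2
  axe <- equivalent_ellipse(ell, method = "polygon")
  expect_rel(axe[["major"]] / axe[["minor"]], 2, 0.005)
  # rotation invariance of the axes
  phi <- 0.7
  rot <- cbind(ell %*% c(cos(phi), -sin(phi)), ell %*% c(sin(phi), cos(phi)))
  axr <- equivalent_ellipse(rot, method = "polygon")
  expect_equal(unname(axr), unname(axe), tolerance = 1e-9)

  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  axs <- equivalent_ellipse(sq, method = "polygon")
  expect_equal(unname(axs[["major"]] / axs[["minor"]]), 1, tolerance = 1e-9)

  # raster path agrees with the analytic path
  axp <- equivalent_ellipse(ell, method = "raster", pixel = 0.02)
  expect_equal(unname(axp), unname(axe), tolerance = 0.01)
  expect_error(equivalent_ellipse(rbind(c(0, 0), c(1, 1), c(2, 2))),
               class = "degenerate_shape")
})

test_that("roundness is minor/major and obeys the area identity", {
  expect_equal(roundness(2, 2), 1)
  expect_equal(roundness(2, 1), 0.5)
  expect_error(roundness(1, 2), class = "invalid_axis")
  expect_error(roundness(1, -1), class = "invalid_axis")
  # 4 * EllipseArea / (pi * Major^2) == Minor / Major for equivalent ellipses
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  for (ab in list(c(5, 5), c(8, 3), c(11, 7))) {
    P <- cbind(ab[1] * cos(th), ab[2] * sin(th))
    ax <- equivalent_ellipse(P, method = "polygon")
    ell_area <- pi * ax[["major"]] * ax[["minor"]] / 4
    expect_equal(4 * ell_area / (pi * ax[["major"]]^2),
                 ax[["minor"]] / ax[["major"]], tolerance = 1e-12)
  }
})

test_that("contour areas follow the shoelace formula", {
  sqp <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(contour_area(sqp), 1e-6, tolerance = 1e-15)
  expect_equal(contour_area(sqp[4:1, ]), 1e-6, tolerance = 1e-15)
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  circ <- cbind(20 * cos(th), 20 * sin(th))
  expect_rel(contour_area(circ), pi * 400 / 1e6, 0.005)
  bow <- rbind(c(0, 0), c(2, 2), c(2, 0), c(0, 2))
  expect_error(contour_area(bow), class = "invalid_polygon")
})

test_that("contours leaving the region are flagged incomplete and excluded", {
  # peak close to the crop edge: outer contours cross the boundary
  g <- gaussian_map(peak = 2e5, sx = 40, sy = 40, extent = 300, scale = 1,
                    center = c(24.3, 150.2))
  ct <- extract_contour(g, 0.80)
  expect_false(ct$complete)
  cs <- summarize_contours(g)
  expect_false(cs$usable)
  expect_true(is.na(cs$mean_roundness))
  expect_error(vcar_inside_outside(scalar_map(matrix(5, 300, 300), scale = 1),
                                   ct),
               class = "excluded_subject")
})

test_that("VCAR inside/outside the 80% contour compares region means", {
  g <- gaussian_map(peak = 2e5, sx = 30, sy = 30, extent = 200, scale = 1,
                    center = c(100.3, 100.2))
  ct <- extract_contour(g, 0.80)
  flat <- scalar_map(matrix(6.5, 200, 200), scale = 1, quantity = "vcar")
  io <- vcar_inside_outside(flat, ct)
  expect_equal(io$difference, 0, tolerance = 1e-12)
  expect_equal(io$mean_in, 6.5)
  # a map lower inside the contour yields a negative difference
  xc <- (seq_len(200) - 0.5)
  rad <- outer(xc, xc, function(y, x) sqrt((x - 100.3)^2 + (y - 100.2)^2))
  graded <- scalar_map(4 + 3 * pmin(rad / 60, 1), scale = 1,
                       quantity = "vcar")
  io2 <- vcar_inside_outside(graded, ct)
  expect_lt(io2$difference, 0)
})

test_that("roundness of a contour is invariant to uniform map rescaling", {
  g <- gaussian_map(peak = 2e5, sx = 45, sy = 30, extent = 300, scale = 1,
                    center = c(150.3, 150.2))
  ct1 <- extract_contour(g, 0.8)
  g2 <- scalar_map(g$values, scale = 2.5, quantity = "density")
  ct2 <- extract_contour(g2, 0.8)
  expect_equal(ct2$roundness, ct1$roundness, tolerance = 1e-6)
  expect_equal(ct2$area_mm2, ct1$area_mm2 * 2.5^2, tolerance = 1e-6)
})
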