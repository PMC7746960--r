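test_that("adaptive windows grow to the bound-cell target", {
  s <- 2.59   # hex spacing giving ~172,000 cones/mm^2
  m <- hex_mosaic(s, 80, 80, jitter_sd = 0.02 * s, seed = 1)
  ctr <- extent_um(m) / 2
  roi <- grow_window(m, ctr, target_bound = 100)
  # ~100 cells at this density need a 23-29 um window (plus lattice margin)
  expect_gte(roi$side, 20)
  expect_lte(roi$side, 32)
  expect_gte(roi$n_bound, 100)
  expect_rel(roi$density, 2 / (sqrt(3) * s^2) * 1e6, 0.03)

  # doubling the spacing doubles the window side (within one growth step of
  # the doubled schedule)
  m2 <- hex_mosaic(2 * s, 160, 160, jitter_sd = 0.04 * s, seed = 1)
  roi2 <- grow_window(m2, extent_um(m2) / 2, target_bound = 100)
  expect_lte(abs(roi2$side - 2 * roi$side), 2)
})

test_that("impossible bound-cell targets raise the unresolved-ROI signal", {
  m <- hex_mosaic(8, 40, 40)   # far fewer than 100 cells in reach
  m$coords <- m$coords[seq_len(50), , drop = FALSE]
  expect_error(grow_window(m, c(20, 20), target_bound = 100),
               class = "unresolved_roi")
})

test_that("increasing the bound-cell target never shrinks the window", {
  m <- hex_mosaic(2.5, 70, 70, jitter_sd = 0.2, seed = 3)
  for (ctr in list(c(35, 35), c(30, 42), c(45, 30))) {
    sides <- sapply(c(20, 50, 100, 150),
                    function(tb) grow_window(m, ctr + 6, target_bound = tb)$side)
    expect_true(all(diff(sides) >= 0))
  }
})

test_that("sum-map equals the brute-force per-pixel ROI-average oracle", {
  # ~200-cone mosaic, small bound target so windows stay enumerable
  s <- 2.5
  m <- hex_mosaic(s, 30, 30, jitter_sd = 0.15, seed = 9)
  m$coords <- m$coords    # ~300 points incl. margin ring
  ctl <- map_control(target_bound = 25, side_min = 4, side_max = 40,
                     side_step = 1, map_scale = 1,
                     region = c(10, 10, 40, 40))
  maps <- sum_maps(m, quantities = c("density", "spacing", "vcar"),
                   control = ctl)

  # oracle: per cone, scan the schedule with full tessellations; per pixel,
  # average all covering windows in cone-index order
  xy <- coords_um(m)
  sel <- which(xy[, 1] >= ctl$region[1] - 20 & xy[, 1] <= ctl$region[3] + 20 &
               xy[, 2] >= ctl$region[2] - 20 & xy[, 2] <= ctl$region[4] + 20)
  rois <- list()
  for (k in sel) {
    hit <- NULL
    for (side in seq(4, 40, by = 1)) {
      w <- c(xy[k, 1] - side / 2, xy[k, 2] - side / 2,
             xy[k, 1] + side / 2, xy[k, 2] + side / 2)
      tc <- tryCatch(tessellate(m, w), error = function(e) NULL)
      if (is.null(tc) || sum(tc$bounded) < 25) next
      hit <- list(x = xy[k, 1], y = xy[k, 2], side = side,
                  density = bound_density(tc), icd = icd_value(tc),
                  vcar = vcar_value(tc))
      break
    }
    if (!is.null(hit)) rois[[length(rois) + 1]] <- hit
  }
  nx <- 30; ny <- 30
  for (q in c("density", "spacing", "vcar")) {
    fld <- c(density = "density", spacing = "icd", vcar = "vcar")[[q]]
    oracle <- matrix(NA_real_, ny, nx)
    for (i in seq_len(ny)) for (j in seq_len(nx)) {
      pc <- c(10 + (j - 0.5), 10 + (i - 0.5))
      acc <- 0; nacc <- 0L
      for (r in rois)
        if (abs(pc[1] - r$x) <= r$side / 2 && abs(pc[2] - r$y) <= r$side / 2) {
          acc <- acc + r[[fld]]
          nacc <- nacc + 1L
        }
      if (nacc > 0L) oracle[i, j] <- acc / nacc
    }
    expect_identical(dim(maps[[q]]$values), dim(oracle))
    expect_identical(maps[[q]]$mask, !is.na(oracle))
    expect_equal(maps[[q]]$values[maps[[q]]$mask], oracle[!is.na(oracle)],
                 tolerance = 1e-12)
  }
})

test_that("uniform lattices give flat density maps at the closed form", {
  s <- 2.5
  m <- hex_mosaic(s, 60, 60, jitter_sd = 0.05 * s, seed = 5)
  ctl <- map_control(target_bound = 60, map_scale = 2,
                     region = c(15, 15, 55, 55) + 6)
  dm <- sum_map(m, "density", control = ctl)
  expect_true(all(dm$mask))
  expect_true(all(abs(dm$values - 2 / (sqrt(3) * s^2) * 1e6) /
                    (2 / (sqrt(3) * s^2) * 1e6) < 0.03))
  sm <- sum_map(m, "spacing", control = ctl)
  expect_true(all(abs(sm$values - s) / s < 0.03))
})

test_that("peak extraction handles ties, corners and lookup", {
  v <- matrix(1, 5, 5)
  cm <- scalar_map(v, scale = 1)
  expect_warning(pk <- extract_peak(cm), class = "peak_tie")
  expect_equal(unname(pk$location_px), c(3, 3))

  v2 <- matrix(0, 5, 5); v2[1, 5] <- 7   # corner peak (top-right)
  pk2 <- extract_peak(scalar_map(v2, scale = 1))
  expect_equal(unname(pk2$location_px), c(5, 1))
  expect_equal(pk2$value, 7)

  # the analytic Gaussian centred between pixel centres ties symmetrically
  g <- gaussian_map(peak = 1000, sx = 20, sy = 20, extent = 100, scale = 1)
  expect_warning(pk3 <- extract_peak(g), class = "peak_tie")
  expect_lt(max(abs(pk3$location_um - 50)), 1.01)
  expect_equal(metric_at(g, pk3$location_px), pk3$value)

  msk <- matrix(TRUE, 5, 5); msk[2, 4] <- FALSE
  mm <- scalar_map(v2, scale = 1, mask = msk)
  expect_error(metric_at(mm, c(4, 2)), class = "out_of_support")
  expect_error(metric_at(mm, c(99, 1)), class = "out_of_support")
  expect_error(extract_peak(scalar_map(v, scale = 1,
                                       mask = matrix(FALSE, 5, 5))),
               class = "empty_map")
})

test_that("restricted-region maps agree with full-extent maps", {
  m <- hex_mosaic(2.5, 70, 70, jitter_sd = 0.2, seed = 11)
  full <- sum_map(m, "density",
                  control = map_control(target_bound = 40, map_scale = 1))
  reg <- c(25, 25, 55, 55)
  part <- sum_map(m, "density",
                  control = map_control(target_bound = 40, map_scale = 1,
                                        region = reg))
  ii <- (reg[2] + 1):reg[4]; jj <- (reg[1] + 1):reg[3]
  expect_equal(part$values, full$values[ii, jj], tolerance = 1e-12)
})

test_that("density peak is robust to 30-degree rotation of an isotropic mosaic", {
  spec <- synthetic_fovea_spec(peak_density = 160000, falloff_sigma_x = 60,
                               falloff_sigma_y = 60, seed = 21)
  m <- generate_mosaic(spec)
  ctl <- map_control(region = c(130, 130, 170, 170), map_scale = 2)
  p0 <- extract_peak(sum_map(m, "density", control = ctl))$value
  th <- pi / 6
  xy <- sweep(coords_um(m), 2, c(150, 150))
  rot <- cbind(xy %*% c(cos(th), -sin(th)), xy %*% c(sin(th), cos(th)))
  rot <- sweep(rot, 2, c(150, 150), `+`)
  keep <- rot[, 1] > 0 & rot[, 1] < 300 & rot[, 2] > 0 & rot[, 2] < 300
  mr <- cone_mosaic(rot[keep, ], scale = 1, extent = c(300, 300),
                    subject_id = "rot")
  pr <- extract_peak(sum_map(mr, "density", control = ctl))$value
  expect_rel(pr, p0, 0.02)
})
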