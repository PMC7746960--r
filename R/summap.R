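#' Control parameters for sum-map construction
#'
#' @param target_bound Bound cells each adaptive window must contain
#'   (default 100).
#' @param side_min,side_max,side_step Window growth schedule in micrometres:
#'   sides `side_min, side_min + side_step, ...` up to `side_max`. Defaults
#'   10-80 um in 1-um steps; typical foveal densities resolve at 20-65 um.
#' @param map_scale Pixel size of the output map grid in micrometres; `NULL`
#'   uses the mosaic's image scale (map grid = image pixel grid).
#' @param region `c(xmin, ymin, xmax, ymax)` in micrometres restricting the
#'   mapped area; `NULL` maps the full extent. Windows are still grown for
#'   cones up to `side_max / 2` outside the region so that values inside the
#'   region equal those of a full-extent run.
#' @param tol Geometric tolerance, micrometres.
#' @return A list of class `map_control`.
#' @export
map_control <- function(target_bound = 100, side_min = 10, side_max = 80,
                        side_step = 1, map_scale = NULL, region = NULL,
                        tol = 1e-9) {
  stopifnot(target_bound >= 3, side_min > 0, side_max >= side_min,
            side_step > 0)
  structure(list(target_bound = target_bound, side_min = side_min,
                 side_max = side_max, side_step = side_step,
                 map_scale = map_scale, region = region, tol = tol),
            class = "map_control")
}

#' Grow an adaptive density window at a point
#'
#' Starting from the smallest side on the growth schedule, a square window
#' centred on `center` is enlarged until its tessellation contains at least
#' `target_bound` bound Voronoi cells; the smallest qualifying side is
#' returned together with the bound-cell metrics of that window.
#'
#' @param mosaic A [cone_mosaic()].
#' @param center `c(x, y)` in micrometres.
#' @param target_bound Required number of bound cells (default 100).
#' @param control A [map_control()].
#' @return A list of class `density_roi` with `center`, `side` (um),
#'   `n_bound`, `density` (cones/mm^2), `icd` (um) and `vcar`.
#' @export
grow_window <- function(mosaic, center, target_bound = 100,
                        control = map_control(target_bound = target_bound)) {
  stopifnot(inherits(mosaic, "cone_mosaic"), length(center) == 2)
  xy <- coords_um(mosaic)
  res <- cpp_sum_map_rois(xy[, 1], xy[, 2], center[1], center[2],
                          control$side_min, control$side_max,
                          control$side_step, as.integer(control$target_bound),
                          control$tol)
  if (res$status[1] != 0L)
    fm_stop(sprintf(
      "window reached side_max = %g um with only %d bound cells (target %d)",
      control$side_max, res$n_bound[1], control$target_bound),
      "unresolved_roi")
  structure(list(center = center, side = res$side[1], n_bound = res$n_bound[1],
                 density = res$density[1], icd = res$icd[1],
                 vcar = res$vcar[1]),
            class = "density_roi")
}

#' @export
print.density_roi <- function(x, ...) {
  cat(sprintf(
    "density_roi at (%.1f, %.1f) um: side %g um, %d bound cells\n  density %.0f /mm^2, ICD %.3f um, VCAR %.2f\n",
    x$center[1], x$center[2], x$side, x$n_bound, x$density, x$icd, x$vcar))
  invisible(x)
}

# internal scalar_map constructor
new_scalar_map <- function(values, mask, quantity, scale, origin) {
  structure(list(values = values, mask = mask, quantity = quantity,
                 scale = scale, origin = origin),
            class = "scalar_map")
}

#' Construct a scalar map from a value matrix
#'
#' Mainly for tests and synthetic surfaces: wraps a matrix (rows = y, columns
#' = x, image convention) into the same `scalar_map` container that
#' [sum_map()] produces. Pixel centres sit at
#' `origin + (index - 0.5) * scale`.
#'
#' @param values Numeric matrix (row = y index, column = x index).
#' @param scale Map pixel size, micrometres.
#' @param mask Logical matrix of defined pixels; default: finite values.
#' @param quantity One of `"density"`, `"spacing"`, `"vcar"`, or a free label.
#' @param origin `c(x0, y0)` offset of the grid in the source frame, um.
#' @return A `scalar_map`.
#' @export
scalar_map <- function(values, scale, mask = NULL,
                       quantity = "density", origin = c(0, 0)) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- is.finite(values)
  stopifnot(identical(dim(mask), dim(values)), scale > 0)
  new_scalar_map(values, mask, quantity, scale, as.numeric(origin))
}

#' Pixel-centre coordinates of a map grid
#' @param map A `scalar_map`.
#' @return List with `x` (length ncol) and `y` (length nrow), micrometres.
#' @export
map_axes <- function(map) {
  stopifnot(inherits(map, "scalar_map"))
  list(x = map$origin[1] + (seq_len(ncol(map$values)) - 0.5) * map$scale,
       y = map$origin[2] + (seq_len(nrow(map$values)) - 0.5) * map$scale)
}

#' Sum-maps of density, spacing and regularity
#'
#' For every cone coordinate an adaptive window is grown ([grow_window()]);
#' each output pixel is the arithmetic mean of the metric values of all
#' windows overlapping that pixel (a window overlaps a pixel when it covers
#' the pixel's centre). Windows that fail to reach the bound-cell target at
#' `side_max` are excluded from the averaging. Accumulation is in cone-index
#' order. `sum_maps()` computes all requested quantities in a single pass
#' over the mosaic (the windows are shared); [sum_map()] is the
#' single-quantity convenience wrapper.
#'
#' @param mosaic A [cone_mosaic()].
#' @param quantities Subset of `c("density", "spacing", "vcar")`.
#' @param target_bound Bound cells per window, default 100.
#' @param control A [map_control()].
#' @return `sum_maps()`: named list of `scalar_map` objects, with an
#'   attribute `rois` (data frame of per-cone window side, bound count and
#'   metric values, unresolved windows flagged). `sum_map()`: one
#'   `scalar_map`.
#' @export
sum_maps <- function(mosaic, quantities = c("density", "spacing", "vcar"),
                     target_bound = 100,
                     control = map_control(target_bound = target_bound)) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  quantities <- match.arg(quantities, several.ok = TRUE)
  xy <- coords_um(mosaic)
  e <- extent_um(mosaic)
  region <- if (is.null(control$region)) c(0, 0, e[1], e[2]) else control$region
  ms <- if (is.null(control$map_scale)) mosaic$scale else control$map_scale
  margin <- control$side_max / 2
  sel <- xy[, 1] >= region[1] - margin & xy[, 1] <= region[3] + margin &
         xy[, 2] >= region[2] - margin & xy[, 2] <= region[4] + margin
  if (!any(sel)) fm_stop("no cones in mapped region", "empty_map")
  cx <- xy[sel, 1]; cy <- xy[sel, 2]
  res <- cpp_sum_map_rois(xy[, 1], xy[, 2], cx, cy,
                          control$side_min, control$side_max,
                          control$side_step, as.integer(control$target_bound),
                          control$tol)
  ok <- res$status == 0L
  if (!any(ok)) fm_stop("no window reached the bound-cell target", "empty_map")

  nx <- max(1L, as.integer(round((region[3] - region[1]) / ms)))
  ny <- max(1L, as.integer(round((region[4] - region[2]) / ms)))
  qty_col <- c(density = "density", spacing = "icd", vcar = "vcar")
  sums <- lapply(quantities, function(q) matrix(0, ny, nx))
  names(sums) <- quantities
  cnt <- matrix(0L, ny, nx)
  for (k in which(ok)) {
    half <- res$side[k] / 2
    j0 <- max(1L, ceiling((cx[k] - half - region[1]) / ms + 0.5))
    j1 <- min(nx, floor((cx[k] + half - region[1]) / ms + 0.5))
    i0 <- max(1L, ceiling((cy[k] - half - region[2]) / ms + 0.5))
    i1 <- min(ny, floor((cy[k] + half - region[2]) / ms + 0.5))
    if (j0 > j1 || i0 > i1) next
    for (q in quantities)
      sums[[q]][i0:i1, j0:j1] <- sums[[q]][i0:i1, j0:j1] + res[[qty_col[q]]][k]
    cnt[i0:i1, j0:j1] <- cnt[i0:i1, j0:j1] + 1L
  }
  mask <- cnt > 0L
  maps <- lapply(quantities, function(q) {
    v <- sums[[q]] / ifelse(mask, cnt, NA)
    new_scalar_map(v, mask, q, ms, origin = region[1:2])
  })
  names(maps) <- quantities
  rois <- data.frame(x = cx, y = cy, side = res$side, n_bound = res$n_bound,
                     density = res$density, icd = res$icd, vcar = res$vcar,
                     resolved = ok)
  n_bad <- sum(!ok)
  if (n_bad > 0)
    message(sprintf("sum_maps: %d of %d windows unresolved at side_max and excluded",
                    n_bad, length(ok)))
  attr(maps, "rois") <- rois
  maps
}

#' @rdname sum_maps
#' @param quantity One of `"density"`, `"spacing"`, `"vcar"`.
#' @export
sum_map <- function(mosaic, quantity = c("density", "spacing", "vcar"),
                    target_bound = 100,
                    control = map_control(target_bound = target_bound)) {
  quantity <- match.arg(quantity)
  maps <- sum_maps(mosaic, quantities = quantity, target_bound = target_bound,
                   control = control)
  out <- maps[[quantity]]
  attr(out, "rois") <- attr(maps, "rois")
  out
}

#' @export
print.scalar_map <- function(x, ...) {
  rng <- range(x$values[x$mask])
  cat(sprintf("scalar_map [%s]: %d x %d px at %.4g um/px, %d%% defined\n",
              x$quantity, nrow(x$values), ncol(x$values), x$scale,
              round(100 * mean(x$mask))))
  cat(sprintf("  range %.4g .. %.4g\n", rng[1], rng[2]))
  invisible(x)
}

#' @export
plot.scalar_map <- function(x, contours = NULL, ...) {
  ax <- map_axes(x)
  z <- t(x$values)
  z[!t(x$mask)] <- NA
  image(ax$x, ax$y, z[, rev(seq_along(ax$y)), drop = FALSE], asp = 1,
        col = gray.colors(128), xlab = "x (um)", ylab = "y (um)",
        main = x$quantity, ...)
  invisible(x)
}

#' Extract the peak of a scalar map
#'
#' Global maximum over defined (masked-true) pixels. If several pixels tie at
#' the maximum the one nearest the centroid of the defined region is returned
#' and a tie warning is raised.
#'
#' @param map A `scalar_map`.
#' @return A list of class `peak_result`: `value`, `location_px` (`c(x, y)`
#'   pixel indices in the map frame) and `location_um`.
#' @export
extract_peak <- function(map) {
  stopifnot(inherits(map, "scalar_map"))
  if (!any(map$mask)) fm_stop("map has no defined pixels", "empty_map")
  v <- map$values
  v[!map$mask] <- -Inf
  mx <- max(v)
  hits <- which(v == mx, arr.ind = TRUE)  # (row = y, col = x)
  if (nrow(hits) > 1L) {
    fm_warn(sprintf("%d pixels tie at the peak value; returning the centroid-nearest",
                    nrow(hits)), "peak_tie")
    msk <- which(map$mask, arr.ind = TRUE)
    cen <- colMeans(msk)
    d2 <- (hits[, 1] - cen[1])^2 + (hits[, 2] - cen[2])^2
    hits <- hits[which.min(d2), , drop = FALSE]
  }
  loc_px <- c(x = unname(hits[1, 2]), y = unname(hits[1, 1]))
  ax <- map_axes(map)
  structure(list(value = mx,
                 location_px = loc_px,
                 location_um = c(x = ax$x[loc_px["x"]], y = ax$y[loc_px["y"]])),
            class = "peak_result")
}

#' @export
print.peak_result <- function(x, ...) {
  cat(sprintf("peak %.6g at pixel (%d, %d) = (%.1f, %.1f) um\n", x$value,
              x$location_px["x"], x$location_px["y"],
              x$location_um["x"], x$location_um["y"]))
  invisible(x)
}

#' Value of a map at a pixel location
#'
#' @param map A `scalar_map`.
#' @param location `c(x, y)` pixel indices (as in `peak_result$location_px`).
#' @return The map value at that pixel.
#' @export
metric_at <- function(map, location) {
  stopifnot(inherits(map, "scalar_map"), length(location) == 2)
  j <- as.integer(location[[1]]); i <- as.integer(location[[2]])
  if (i < 1L || i > nrow(map$values) || j < 1L || j > ncol(map$values) ||
      !map$mask[i, j])
    fm_stop("location is outside the defined region of the map", "out_of_support")
  map$values[i, j]
}

#' Write / read a scalar map as CSV (+ JSON sidecar)
#'
#' The grid is written as a plain CSV matrix (rows = y); a JSON sidecar
#' stores quantity, scale, origin and the mask row-ranges. A 32-bit float
#' TIFF is written alongside when the `tiff` package is available.
#'
#' @param map A `scalar_map`.
#' @param path Output stem; `.csv` / `.json` / `.tif` are appended.
#' @export
write_scalar_map <- function(map, path) {
  stopifnot(inherits(map, "scalar_map"))
  v <- map$values
  v[!map$mask] <- NA
  write.table(format(v, digits = 17, trim = TRUE, scientific = TRUE),
              paste0(path, ".csv"), sep = ",", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  meta <- list(quantity = map$quantity, scale = map$scale,
               origin = map$origin, nrow = nrow(v), ncol = ncol(v))
  writeLines(sprintf(
    '{"quantity": "%s", "scale": %.17g, "origin": [%.17g, %.17g], "nrow": %d, "ncol": %d}',
    meta$quantity, meta$scale, meta$origin[1], meta$origin[2], meta$nrow,
    meta$ncol), paste0(path, ".json"))
  if (requireNamespace("tiff", quietly = TRUE)) {
    z <- map$values
    z[!map$mask] <- NaN
    tiff::writeTIFF(z / max(1, max(abs(z[map$mask]))),
                    paste0(path, ".tif"), bits.per.sample = 32L)
  }
  invisible(path)
}

#' @rdname write_scalar_map
#' @export
read_scalar_map <- function(path) {
  meta_txt <- paste(readLines(paste0(path, ".json")), collapse = "")
  grab <- function(key) {
    m <- regmatches(meta_txt,
                    regexpr(sprintf('"%s":\\s*[^,}]+', key), meta_txt))
    sub(sprintf('"%s":\\s*', key), "", m)
  }
  origin <- regmatches(meta_txt,
                       regexpr('"origin":\\s*\\[[^]]*\\]', meta_txt))
  origin <- as.numeric(strsplit(gsub('[^0-9eE+.,-]', "",
                                     sub('"origin":', "", origin)), ",")[[1]])
  v <- as.matrix(read.table(paste0(path, ".csv"), sep = ",", header = FALSE,
                            colClasses = "numeric"))
  dimnames(v) <- NULL
  scalar_map(v, scale = as.numeric(grab("scale")),
             quantity = gsub('"', "", grab("quantity")), origin = origin)
}
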