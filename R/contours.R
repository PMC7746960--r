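#' Extract an isodensity contour from a density map
#'
#' Traces the level set at `fraction` times the map's peak value by marching
#' squares with linear interpolation, and among the resulting curves returns
#' the one enclosing the peak location (innermost if several are nested).
#' A contour is `complete` when it closes inside the analysis region without
#' any vertex within one map pixel of the region boundary; open curves that
#' leave the region are closed across the boundary for bookkeeping and
#' flagged incomplete.
#'
#' @param map A density `scalar_map` (see [sum_map()]).
#' @param fraction Fraction of peak density in (0, 1); the analysis uses
#'   0.70, 0.75, 0.80, 0.85, 0.90.
#' @param peak Optional precomputed [extract_peak()] result.
#' @return An object of class `isodensity_contour`: `fraction`, `level`
#'   (cones/mm^2), `polygon` (closed vertex matrix, um), `complete`,
#'   `roundness`, `area_mm2`, `axes` (equivalent-ellipse major/minor, um).
#' @export
extract_contour <- function(map, fraction, peak = NULL) {
  stopifnot(inherits(map, "scalar_map"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    fm_stop("fraction must lie strictly between 0 and 1", "invalid_parameter")
  if (is.null(peak)) peak <- extract_peak(map)
  level <- fraction * peak$value
  ax <- map_axes(map)
  z <- t(map$values)          # contourLines wants z[x, y]
  z[!t(map$mask)] <- NA
  segs <- contourLines(ax$x, ax$y, z, levels = level)
  if (length(segs) == 0L)
    fm_stop(sprintf("no level set at %.3g (fraction %.2f of peak)", level,
                    fraction), "contour_not_found")
  bnd <- c(map$origin[1], map$origin[2],
           map$origin[1] + ncol(map$values) * map$scale,
           map$origin[2] + nrow(map$values) * map$scale)
  px <- peak$location_um
  cands <- list()
  for (sg in segs) {
    P <- cbind(sg$x, sg$y)
    closed <- sqrt(sum((P[1, ] - P[nrow(P), ])^2)) < 1e-8
    if (closed) P <- P[-nrow(P), , drop = FALSE]
    if (nrow(P) < 3L) next
    if (!point_in_poly(px[1], px[2], P)) next
    cands[[length(cands) + 1L]] <- list(P = P, closed = closed,
                                        area = abs(shoelace_area(P)))
  }
  if (length(cands) == 0L)
    fm_stop("no contour at this level encloses the peak", "contour_not_found")
  pick <- cands[[which.min(vapply(cands, `[[`, numeric(1), "area"))]]
  P <- pick$P
  touches <- any(P[, 1] <= bnd[1] + map$scale | P[, 1] >= bnd[3] - map$scale |
                 P[, 2] <= bnd[2] + map$scale | P[, 2] >= bnd[4] - map$scale)
  complete <- pick$closed && !touches
  area_mm2 <- abs(shoelace_area(P)) / 1e6
  axes <- tryCatch(equivalent_ellipse(P, pixel = map$scale),
                   error = function(e) c(major = NA_real_, minor = NA_real_))
  structure(list(fraction = fraction, level = level, polygon = P,
                 complete = complete,
                 roundness = unname(axes["minor"] / axes["major"]),
                 area_mm2 = area_mm2, axes = axes),
            class = "isodensity_contour")
}

#' @export
print.isodensity_contour <- function(x, ...) {
  cat(sprintf(
    "isodensity_contour %.0f%%: level %.5g, area %.4g mm^2, roundness %.3f, %s\n",
    100 * x$fraction, x$level, x$area_mm2, x$roundness,
    if (x$complete) "complete" else "INCOMPLETE"))
  invisible(x)
}

# signed shoelace area of an open-stored (implicitly closed) polygon
shoelace_area <- function(P) {
  n <- nrow(P)
  j <- c(2:n, 1L)
  sum(P[, 1] * P[j, 2] - P[j, 1] * P[, 2]) / 2
}

# even-odd point-in-polygon via mgcv::in.out (boundary treated as inside by
# a tiny outward tolerance on the query)
point_in_poly <- function(x, y, P) {
  bnd <- rbind(P, P[1, , drop = FALSE])
  as.logical(mgcv::in.out(bnd, matrix(c(x, y), 1)))
}

points_in_poly <- function(xy, P) {
  bnd <- rbind(P, P[1, , drop = FALSE])
  as.logical(mgcv::in.out(bnd, xy))
}

#' Equivalent ellipse of a simple closed polygon
#'
#' Axes of the ellipse having the same normalized second central moments as
#' the filled polygonal region (the region-moments convention of image
#' analysis, e.g. MATLAB `regionprops`): major/minor full axis lengths are
#' `4 * sqrt(eigenvalue)` of the region covariance matrix. Two computation
#' paths are provided: `"raster"` (default) fills the polygon on a pixel grid
#' at resolution `pixel` and accumulates pixel moments (with the per-pixel
#' 1/12 variance term), `"polygon"` evaluates the exact polygon moment
#' integrals via Green's theorem. Both are invariant to rotation and
#' translation.
#'
#' @param P Closed polygon as a two-column vertex matrix (um; last vertex
#'   need not repeat the first).
#' @param method `"raster"` or `"polygon"`.
#' @param pixel Raster resolution in um; default scales with the polygon size.
#' @return Named vector `c(major, minor)` in micrometres.
#' @export
equivalent_ellipse <- function(P, method = c("raster", "polygon"),
                               pixel = NULL) {
  method <- match.arg(method)
  P <- as.matrix(P)
  if (nrow(P) >= 2 &&
      sqrt(sum((P[1, ] - P[nrow(P), ])^2)) < 1e-12)
    P <- P[-nrow(P), , drop = FALSE]
  A <- shoelace_area(P)
  if (nrow(P) < 3L || abs(A) < 1e-12)
    fm_stop("degenerate polygon (zero area)", "degenerate_shape")
  if (method == "polygon") {
    if (A < 0) { P <- P[rev(seq_len(nrow(P))), , drop = FALSE]; A <- -A }
    n <- nrow(P); j <- c(2:n, 1L)
    cr <- P[, 1] * P[j, 2] - P[j, 1] * P[, 2]
    cx <- sum((P[, 1] + P[j, 1]) * cr) / (6 * A)
    cy <- sum((P[, 2] + P[j, 2]) * cr) / (6 * A)
    ixx <- sum((P[, 1]^2 + P[, 1] * P[j, 1] + P[j, 1]^2) * cr) / 12
    iyy <- sum((P[, 2]^2 + P[, 2] * P[j, 2] + P[j, 2]^2) * cr) / 12
    ixy <- sum((P[, 1] * P[j, 2] + 2 * P[, 1] * P[, 2] +
                2 * P[j, 1] * P[j, 2] + P[j, 1] * P[, 2]) * cr) / 24
    sxx <- ixx / A - cx^2
    syy <- iyy / A - cy^2
    sxy <- ixy / A - cx * cy
  } else {
    if (is.null(pixel)) {
      pixel <- max(diff(range(P[, 1])), diff(range(P[, 2]))) / 256
    }
    gx <- seq(min(P[, 1]) + pixel / 2, max(P[, 1]), by = pixel)
    gy <- seq(min(P[, 2]) + pixel / 2, max(P[, 2]), by = pixel)
    gr <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
    inside <- points_in_poly(gr, P)
    if (!any(inside)) fm_stop("degenerate polygon (zero area)", "degenerate_shape")
    q <- gr[inside, , drop = FALSE]
    cx <- mean(q[, 1]); cy <- mean(q[, 2])
    sxx <- mean((q[, 1] - cx)^2) + pixel^2 / 12
    syy <- mean((q[, 2] - cy)^2) + pixel^2 / 12
    sxy <- mean((q[, 1] - cx) * (q[, 2] - cy))
  }
  tr <- sxx + syy
  dt <- sqrt(max(0, (sxx - syy)^2 / 4 + sxy^2))
  lam <- c(tr / 2 + dt, tr / 2 - dt)
  c(major = 4 * sqrt(max(lam[1], 0)), minor = 4 * sqrt(max(lam[2], 0)))
}

#' Roundness of an equivalent ellipse
#'
#' The unitless ratio `4 * Area / (pi * Major^2)`, which for an ellipse
#' equals `Minor / Major`: 1 for a circle, smaller for elongated shapes.
#'
#' @param major,minor Ellipse axis lengths (any common unit), `major >=
#'   minor > 0`.
#' @return Roundness in (0, 1].
#' @export
roundness <- function(major, minor) {
  if (!is.finite(major) || !is.finite(minor) || minor <= 0 || major < minor)
    fm_stop("need major >= minor > 0", "invalid_axis")
  minor / major
}

#' Area enclosed by a contour polygon
#'
#' Shoelace area of the polygon, orientation independent, converted from
#' um^2 to mm^2. Self-intersecting polygons are rejected.
#'
#' @param P Two-column vertex matrix in micrometres.
#' @return Area in mm^2.
#' @export
contour_area <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) >= 2 && sqrt(sum((P[1, ] - P[nrow(P), ])^2)) < 1e-12)
    P <- P[-nrow(P), , drop = FALSE]
  if (nrow(P) < 3L) fm_stop("polygon needs >= 3 vertices", "invalid_polygon")
  if (polygon_self_intersects(P))
    fm_stop("polygon is self-intersecting", "invalid_polygon")
  abs(shoelace_area(P)) / 1e6
}

# O(n^2) segment-pair crossing test, skipping adjacent segments
polygon_self_intersects <- function(P) {
  n <- nrow(P)
  j <- c(2:n, 1L)
  ax <- P[, 1]; ay <- P[, 2]; bx <- P[j, 1]; by <- P[j, 2]
  for (i in seq_len(n - 2L)) {
    ks <- (i + 2L):n
    if (i == 1L) ks <- ks[ks != n]   # segment n is adjacent to segment 1
    if (length(ks) == 0L) next
    d1 <- (bx[i] - ax[i]) * (ay[ks] - ay[i]) - (by[i] - ay[i]) * (ax[ks] - ax[i])
    d2 <- (bx[i] - ax[i]) * (by[ks] - ay[i]) - (by[i] - ay[i]) * (bx[ks] - ax[i])
    d3 <- (bx[ks] - ax[ks]) * (ay[i] - ay[ks]) - (by[ks] - ay[ks]) * (ax[i] - ax[ks])
    d4 <- (bx[ks] - ax[ks]) * (by[i] - ay[ks]) - (by[ks] - ay[ks]) * (bx[i] - ax[ks])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Summary of the five isodensity contours of a density map
#'
#' Extracts contours at 70/75/80/85/90% of peak density and averages their
#' roundness and enclosed area into one value per map. If any contour is
#' missing or incomplete the map is unusable for shape analyses (the
#' exclusion rule applied to subjects whose contours leave the imaged area)
#' and the means are `NA`.
#'
#' @param map A density `scalar_map`.
#' @param fractions Contour fractions, default `c(0.70, 0.75, 0.80, 0.85,
#'   0.90)`.
#' @return An object of class `contour_summary`: `contours` (list),
#'   `mean_roundness`, `mean_area_mm2`, `n_complete`, `usable`.
#' @export
summarize_contours <- function(map, fractions = c(0.70, 0.75, 0.80, 0.85, 0.90)) {
  peak <- extract_peak(map)
  contours <- lapply(fractions, function(f)
    tryCatch(extract_contour(map, f, peak = peak), error = function(e) NULL))
  names(contours) <- sprintf("f%02d", round(100 * fractions))
  found <- !vapply(contours, is.null, logical(1))
  complete <- found & vapply(contours, function(ct)
    isTRUE(ct$complete), logical(1))
  usable <- all(complete)
  structure(list(
    contours = contours,
    n_complete = sum(complete),
    usable = usable,
    mean_roundness = if (usable)
      mean(vapply(contours, `[[`, numeric(1), "roundness")) else NA_real_,
    mean_area_mm2 = if (usable)
      mean(vapply(contours, `[[`, numeric(1), "area_mm2")) else NA_real_),
    class = "contour_summary")
}

#' @export
print.contour_summary <- function(x, ...) {
  cat(sprintf("contour_summary: %d/%d complete, %s\n", x$n_complete,
              length(x$contours),
              if (x$usable) sprintf("mean roundness %.3f, mean area %.4g mm^2",
                                    x$mean_roundness, x$mean_area_mm2)
              else "unusable (excluded from shape analyses)"))
  invisible(x)
}

#' Mosaic regularity inside vs outside the 80% isodensity contour
#'
#' Mean of the VCAR map over defined pixels whose centres fall inside the
#' contour polygon versus those outside it (within the analysis region);
#' pixels on the boundary count as inside. Requires a complete contour —
#' subjects whose 80% contour leaves the imaged area are excluded.
#'
#' @param vcar_map A VCAR `scalar_map`.
#' @param contour80 An [extract_contour()] result at fraction 0.80.
#' @return List with `mean_in`, `mean_out`, `difference` (= in - out).
#' @export
vcar_inside_outside <- function(vcar_map, contour80) {
  stopifnot(inherits(vcar_map, "scalar_map"),
            inherits(contour80, "isodensity_contour"))
  if (!isTRUE(contour80$complete))
    fm_stop("80% contour incomplete; subject excluded from VCAR in/out comparison",
            "excluded_subject")
  ax <- map_axes(vcar_map)
  idx <- which(vcar_map$mask, arr.ind = TRUE)
  pts <- cbind(ax$x[idx[, 2]], ax$y[idx[, 1]])
  inside <- points_in_poly(pts, contour80$polygon)
  vals <- vcar_map$values[vcar_map$mask]
  vin <- vals[inside]; vout <- vals[!inside]
  if (length(vin) == 0L || length(vout) == 0L)
    fm_stop("contour does not split the defined region", "excluded_subject")
  mean_in <- mean(vin); mean_out <- mean(vout)
  list(mean_in = mean_in, mean_out = mean_out,
       difference = mean_in - mean_out)
}
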