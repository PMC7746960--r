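#' Voronoi tessellation of a cone mosaic within a window
#'
#' Tessellates all cones falling inside a rectangular analysis window (in
#' micrometres) and classifies each cell as *bound* or not. A cell is bound
#' iff its Voronoi polygon — computed from all cones inside the window — is
#' finite and lies entirely inside the window; containment is tested on the
#' polygon vertices. Bound-cell metrics ([bound_density()], [icd_value()],
#' [vcar_value()]) consume the result.
#'
#' @param mosaic A [cone_mosaic()].
#' @param window `c(xmin, ymin, xmax, ymax)` in micrometres; defaults to the
#'   full extent.
#' @param tol Geometric tolerance in micrometres for degeneracy and
#'   containment tests.
#' @return An object of class `voronoi_cells`: a list with `cone_index`
#'   (row indices into the mosaic), `xy` (cone positions, um), `bounded`,
#'   `area` (um^2), `neighbors` (per-cell integer vectors indexing into this
#'   cell set), `polygons` (per-cell vertex matrices, um) and `window`.
#' @export
tessellate <- function(mosaic, window = NULL, tol = 1e-9) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  xy <- coords_um(mosaic)
  if (is.null(window)) {
    e <- extent_um(mosaic)
    window <- c(0, 0, e[1], e[2])
  }
  stopifnot(length(window) == 4, window[3] > window[1], window[4] > window[2])
  inside <- xy[, 1] >= window[1] & xy[, 1] <= window[3] &
            xy[, 2] >= window[2] & xy[, 2] <= window[4]
  idx <- which(inside)
  if (length(idx) < 3L)
    fm_stop(sprintf("tessellation needs >= 3 cones in the window (found %d)",
                    length(idx)), "degenerate_geometry")
  pts <- xy[idx, , drop = FALSE]
  # collinearity: maximal |cross product| relative to the spread
  v <- sweep(pts, 2, pts[1, ])
  cr <- abs(v[, 1] * v[2, 2] - v[, 2] * v[2, 1])
  span <- max(dist(pts[seq_len(min(nrow(pts), 50L)), , drop = FALSE]))
  if (all(abs(v[2, ]) < tol) || max(cr) <= tol * max(span, 1))
    fm_stop("all cones in the window are collinear", "degenerate_geometry")
  res <- cpp_voronoi(pts[, 1], pts[, 2], window[1], window[2], window[3],
                     window[4], tol)
  structure(list(cone_index = idx, xy = pts, bounded = res$bounded,
                 area = res$area, neighbors = res$neighbors,
                 polygons = res$polygons, window = window),
            class = "voronoi_cells")
}

#' @export
print.voronoi_cells <- function(x, ...) {
  cat(sprintf("voronoi_cells: %d cones, %d bound, window [%g, %g] x [%g, %g] um\n",
              length(x$bounded), sum(x$bounded), x$window[1], x$window[3],
              x$window[2], x$window[4]))
  invisible(x)
}

#' Bound-cell density of a tessellated window
#'
#' Number of bound Voronoi cells divided by their summed area, in cones/mm^2.
#' Invariant under rigid motion of the point set.
#'
#' @param cells A [tessellate()] result.
#' @return Density in cones/mm^2.
#' @export
bound_density <- function(cells) {
  stopifnot(inherits(cells, "voronoi_cells"))
  nb <- sum(cells$bounded)
  if (nb < 1L)
    fm_stop("no bound cells in window; grow the window", "insufficient_bound_cells")
  nb / sum(cells$area[cells$bounded]) * 1e6
}

#' Inter-cell distance (ICD) of a tessellated window
#'
#' For each bound cell, the mean Euclidean distance from its cone to its
#' Voronoi neighbours; ICD is the mean of these over bound cells, in um.
#'
#' @param cells A [tessellate()] result.
#' @return Mean inter-cell distance in micrometres.
#' @export
icd_value <- function(cells) {
  stopifnot(inherits(cells, "voronoi_cells"))
  use <- which(cells$bounded & lengths(cells$neighbors) > 0L)
  if (length(use) == 0L)
    fm_stop("no bound cell has neighbour relations", "insufficient_data")
  per_cell <- vapply(use, function(i) {
    nb <- cells$neighbors[[i]]
    d <- sqrt((cells$xy[nb, 1] - cells$xy[i, 1])^2 +
              (cells$xy[nb, 2] - cells$xy[i, 2])^2)
    mean(d)
  }, numeric(1))
  mean(per_cell)
}

#' Voronoi cell area regularity (VCAR) of a tessellated window
#'
#' Mean bound-cell area divided by the sample standard deviation of bound-cell
#' areas; unitless, larger = more regular. A perfectly regular lattice (zero
#' SD) returns `Inf` with a warning.
#'
#' @param cells A [tessellate()] result.
#' @return VCAR (unitless).
#' @export
vcar_value <- function(cells) {
  stopifnot(inherits(cells, "voronoi_cells"))
  a <- cells$area[cells$bounded]
  if (length(a) < 2L)
    fm_stop("VCAR needs >= 2 bound cells", "insufficient_data")
  s <- sd(a)
  # a perfect lattice yields equal areas up to floating-point clipping noise
  if (s <= 1e-10 * mean(a)) {
    fm_warn("all bound cell areas identical; VCAR is infinite", "perfect_lattice")
    return(Inf)
  }
  mean(a) / s
}
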