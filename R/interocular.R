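#' Mirror a map about its vertical midline
#'
#' Left-right flip (column reversal) converting a left-eye map to right-eye
#' nasal/temporal orientation. Involutive: flipping twice restores the map
#' bit-exactly.
#'
#' @param map A `scalar_map`.
#' @return The flipped `scalar_map`.
#' @export
flip_map <- function(map) {
  stopifnot(inherits(map, "scalar_map"))
  rev_cols <- rev(seq_len(ncol(map$values)))
  new_scalar_map(map$values[, rev_cols, drop = FALSE],
                 map$mask[, rev_cols, drop = FALSE],
                 map$quantity, map$scale, map$origin)
}

#' Resample a map to a finer pixel scale
#'
#' Interpolates the map onto a grid with pixel size `target_scale` covering
#' the same extent, using separable cubic-spline interpolation (exact on
#' cubic polynomials along each axis, hence exact on constants and linear
#' ramps). Only resampling *toward* the finer scale is allowed — when two
#' eyes' maps differ in scale, the coarser is brought to the finer. The mask
#' is resampled conservatively: a target pixel is defined only when the 2 x 2
#' source pixels bracketing it are all defined; undefined source values are
#' nearest-neighbour filled before interpolation so they cannot poison
#' defined output.
#'
#' @param map A `scalar_map`.
#' @param target_scale New pixel size in micrometres, `<= map$scale`.
#' @return The resampled `scalar_map`.
#' @export
rescale_map <- function(map, target_scale) {
  stopifnot(inherits(map, "scalar_map"))
  if (target_scale > map$scale + 1e-12)
    fm_stop("can only rescale toward a finer (smaller um/pixel) scale",
            "wrong_direction")
  if (abs(target_scale - map$scale) < 1e-12) return(map)
  v <- map$values
  if (any(!map$mask)) {
    # nearest-defined fill so the spline has finite support everywhere
    und <- which(!map$mask, arr.ind = TRUE)
    def <- which(map$mask, arr.ind = TRUE)
    for (k in seq_len(nrow(und))) {
      d2 <- (def[, 1] - und[k, 1])^2 + (def[, 2] - und[k, 2])^2
      v[und[k, 1], und[k, 2]] <- map$values[def[which.min(d2), , drop = FALSE]]
    }
  }
  w_um <- ncol(v) * map$scale
  h_um <- nrow(v) * map$scale
  nx2 <- max(1L, as.integer(round(w_um / target_scale)))
  ny2 <- max(1L, as.integer(round(h_um / target_scale)))
  xs <- (seq_len(ncol(v)) - 0.5) * map$scale
  ys <- (seq_len(nrow(v)) - 0.5) * map$scale
  xt <- (seq_len(nx2) - 0.5) * target_scale
  yt <- (seq_len(ny2) - 0.5) * target_scale
  # rows first (along x), then columns (along y)
  tmp <- t(apply(v, 1, function(row)
    splinefun(xs, row, method = "fmm")(xt)))
  out <- apply(tmp, 2, function(col)
    splinefun(ys, col, method = "fmm")(yt))
  out <- matrix(out, ny2, nx2)
  # conservative mask: bracketing 2x2 source pixels all defined
  ix <- pmin(pmax(findInterval(xt, xs), 1L), length(xs) - 1L)
  iy <- pmin(pmax(findInterval(yt, ys), 1L), length(ys) - 1L)
  m <- map$mask
  mk <- m[iy, ix, drop = FALSE] & m[iy + 1L, ix, drop = FALSE] &
        m[iy, ix + 1L, drop = FALSE] & m[iy + 1L, ix + 1L, drop = FALSE]
  new_scalar_map(out, mk, map$quantity, target_scale, map$origin)
}

#' Interocular difference maps of fellow-eye density maps
#'
#' Aligns a right-eye (OD) and a left-eye (OS) density map: the coarser map
#' is resampled to the finer scale, the OS map is mirrored about its vertical
#' midline to match nasal/temporal orientation, the peak-density locations
#' are aligned by integer-pixel translation, and the maps are cropped to
#' their overlap. The signed difference is OD minus (flipped, aligned) OS.
#'
#' @param map_OD,map_OS Density `scalar_map`s of fellow eyes.
#' @param subject_id Optional label carried into the result.
#' @return An object of class `interocular_pair`: `map_OD`, `map_OS`
#'   (aligned, common scale), `common_scale`, `diff_map`, `abs_diff_map`
#'   (`scalar_map`s over the overlap), `mean_abs_diff`, `offset_px`, and the
#'   per-eye peaks.
#' @export
align_difference <- function(map_OD, map_OS, subject_id = NA_character_) {
  stopifnot(inherits(map_OD, "scalar_map"), inherits(map_OS, "scalar_map"))
  os <- flip_map(map_OS)
  common <- min(map_OD$scale, os$scale)
  od <- rescale_map(map_OD, common)
  os <- rescale_map(os, common)
  p_od <- extract_peak(od)
  p_os <- extract_peak(os)
  off <- p_od$location_px - p_os$location_px   # (x, y): os index + off = od index
  nr_od <- nrow(od$values); nc_od <- ncol(od$values)
  nr_os <- nrow(os$values); nc_os <- ncol(os$values)
  j_lo <- max(1L, 1L + off[["x"]]); j_hi <- min(nc_od, nc_os + off[["x"]])
  i_lo <- max(1L, 1L + off[["y"]]); i_hi <- min(nr_od, nr_os + off[["y"]])
  if (j_lo > j_hi || i_lo > i_hi)
    fm_stop("no overlap between aligned maps", "no_overlap")
  j_od <- j_lo:j_hi
  i_od <- i_lo:i_hi
  j_os <- j_od - off[["x"]]; i_os <- i_od - off[["y"]]
  v_od <- od$values[i_od, j_od, drop = FALSE]
  v_os <- os$values[i_os, j_os, drop = FALSE]
  mk <- od$mask[i_od, j_od, drop = FALSE] & os$mask[i_os, j_os, drop = FALSE]
  if (!any(mk)) fm_stop("empty overlap mask after alignment", "no_overlap")
  origin <- od$origin + c((j_od[1] - 1L), (i_od[1] - 1L)) * common
  d <- v_od - v_os
  diff_map <- new_scalar_map(d, mk, "difference", common, origin)
  abs_map <- new_scalar_map(abs(d), mk, "abs_difference", common, origin)
  structure(list(subject_id = subject_id,
                 map_OD = new_scalar_map(v_od, od$mask[i_od, j_od, drop = FALSE],
                                         od$quantity, common, origin),
                 map_OS = new_scalar_map(v_os, os$mask[i_os, j_os, drop = FALSE],
                                         os$quantity, common, origin),
                 common_scale = common,
                 diff_map = diff_map, abs_diff_map = abs_map,
                 mean_abs_diff = mean(abs(d)[mk]),
                 offset_px = off, peak_OD = p_od, peak_OS = p_os),
            class = "interocular_pair")
}

#' @export
print.interocular_pair <- function(x, ...) {
  cat(sprintf("interocular_pair %s: %d x %d px overlap at %.4g um/px\n",
              x$subject_id, nrow(x$diff_map$values), ncol(x$diff_map$values),
              x$common_scale))
  cat(sprintf("  peak OD %.6g, peak OS %.6g, mean |OD - OS| = %.6g\n",
              x$peak_OD$value, x$peak_OS$value, x$mean_abs_diff))
  invisible(x)
}
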