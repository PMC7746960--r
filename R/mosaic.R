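#' Cone mosaic: a labelled point pattern of cone centres
#'
#' The pipeline's input object: cone-centre coordinates in image pixels over a
#' rectangular crop (typically ~300 x 300 um of central fovea), with the
#' micrometres-per-pixel scale attached. Pixel coordinates follow the image
#' convention: 0-based, x rightward, y downward; all downstream geometry is
#' computed after conversion to micrometres.
#'
#' @param coords Two-column matrix or data frame of (x, y) cone centres in
#'   pixels.
#' @param scale Micrometres per pixel (> 0); see [compute_linear_scale()].
#' @param extent Width and height of the crop in pixels; defaults to the
#'   ceiling of the coordinate range.
#' @param subject_id,eye Labels; `eye` must be `"OD"` or `"OS"` (or `NA`).
#' @param duplicates `"error"` (default) rejects exact duplicate coordinates,
#'   which make the tessellation degenerate and usually indicate marking
#'   errors; `"dedupe"` drops them with a warning.
#' @return An object of class `cone_mosaic`.
#' @export
cone_mosaic <- function(coords, scale, extent = NULL, subject_id = NA_character_,
                        eye = NA_character_, duplicates = c("error", "dedupe")) {
  duplicates <- match.arg(duplicates)
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y")
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    fm_stop("scale must be a positive scalar (um/pixel)", "invalid_parameter")
  if (anyNA(coords))
    fm_stop("coordinates contain missing values", "invalid_parameter")
  if (!is.na(eye) && !eye %in% c("OD", "OS"))
    fm_stop("eye must be 'OD' or 'OS'", "invalid_parameter")
  dup <- duplicated(coords)
  if (any(dup)) {
    if (duplicates == "error")
      fm_stop(sprintf("%d duplicate coordinate(s); use duplicates='dedupe' to drop them",
                      sum(dup)), "duplicate_coordinates")
    fm_warn(sprintf("dropped %d duplicate coordinate(s)", sum(dup)),
            "duplicate_coordinates")
    coords <- coords[!dup, , drop = FALSE]
  }
  if (is.null(extent))
    extent <- ceiling(apply(coords, 2, max) + 1e-9)
  extent <- as.numeric(extent)
  if (any(coords[, 1] < 0 | coords[, 1] > extent[1] |
          coords[, 2] < 0 | coords[, 2] > extent[2]))
    fm_stop("coordinates fall outside the stated extent", "invalid_parameter")
  structure(list(subject_id = subject_id, eye = eye, coords = coords,
                 extent = extent, scale = scale),
            class = "cone_mosaic")
}

#' Cone coordinates in micrometres
#'
#' @param mosaic A [cone_mosaic()].
#' @return Two-column matrix of (x, y) in micrometres.
#' @export
coords_um <- function(mosaic) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  mosaic$coords * mosaic$scale
}

#' Extent of the analysis region in micrometres
#' @param mosaic A [cone_mosaic()].
#' @return `c(width, height)` in micrometres.
#' @export
extent_um <- function(mosaic) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  mosaic$extent * mosaic$scale
}

#' @export
print.cone_mosaic <- function(x, ...) {
  cat(sprintf("cone_mosaic: %d cones | subject %s, eye %s\n",
              nrow(x$coords), x$subject_id, x$eye))
  cat(sprintf("  extent %g x %g px at %.4g um/px (%.1f x %.1f um)\n",
              x$extent[1], x$extent[2], x$scale,
              x$extent[1] * x$scale, x$extent[2] * x$scale))
  invisible(x)
}

#' @export
plot.cone_mosaic <- function(x, cex = 0.3, pch = 16, ...) {
  xy <- coords_um(x)
  plot(xy[, 1], xy[, 2], asp = 1, cex = cex, pch = pch,
       xlab = "x (um)", ylab = "y (um)", ylim = rev(range(xy[, 2])),
       main = sprintf("%s %s (%d cones)", x$subject_id, x$eye, nrow(xy)), ...)
  invisible(x)
}

#' Read cone coordinates from a delimited text file
#'
#' Accepts the common two-column coordinate formats (CSV/TSV/whitespace),
#' sniffing the delimiter and an optional header. Coordinates may be stored in
#' pixels (default) or already in micrometres (`units = "um"`, in which case
#' they are converted back to pixels with the supplied scale so that a single
#' internal convention holds).
#'
#' @param path File with x, y in the first two columns.
#' @param scale Micrometres per pixel for the eye.
#' @param units `"px"` or `"um"`; units of the stored coordinates.
#' @inheritParams cone_mosaic
#' @return A [cone_mosaic()].
#' @export
read_cone_coords <- function(path, scale, units = c("px", "um"),
                             subject_id = NA_character_, eye = NA_character_,
                             extent = NULL, duplicates = "error") {
  units <- match.arg(units)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  has_header <- {
    fields <- strsplit(sub("^﻿", "", first),
                       if (sep == "") "[[:space:]]+" else sep)[[1]]
    suppressWarnings(any(is.na(as.numeric(fields[1:2]))))
  }
  tab <- read.table(path, sep = sep, header = has_header)
  xy <- as.matrix(tab[, 1:2])
  if (units == "um") xy <- xy / scale
  cone_mosaic(xy, scale = scale, extent = extent, subject_id = subject_id,
              eye = eye, duplicates = duplicates)
}

#' Write cone coordinates to CSV
#'
#' Coordinates are written in pixels with an `x,y` header; reading the file
#' back with [read_cone_coords()] reproduces them bit for bit (values are
#' printed at full double precision).
#'
#' @param mosaic A [cone_mosaic()].
#' @param path Output CSV path.
#' @export
write_cone_coords <- function(mosaic, path) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  df <- data.frame(x = sprintf("%.17g", mosaic$coords[, 1]),
                   y = sprintf("%.17g", mosaic$coords[, 2]))
  write.table(df, path, sep = ",", row.names = FALSE, col.names = TRUE,
              quote = FALSE)
  invisible(path)
}
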