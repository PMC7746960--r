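#' Scale parameters of the imaging system
#'
#' Bundles the quantities needed to convert image pixels to retinal
#' micrometres for a given eye: the Ronchi-ruling calibration of the scanner
#' (`T_um`, `T_s`), the model-eye focal length (`f_l`), the assumed retinal
#' magnification factor at the reference axial length, and the subject's
#' measured axial length.
#'
#' @param T_um Ronchi-ruling periodicity, micrometres per cycle.
#' @param T_s Sampling period of the ruling lines in the model-eye image,
#'   pixels per cycle.
#' @param f_l Focal length of the model eye, micrometres.
#' @param RMF Assumed retinal magnification factor, micrometres per degree of
#'   visual angle, referenced to an eye of axial length `l_A0`. Default 291.
#' @param l_A Subject axial length, millimetres.
#' @param l_A0 Reference axial length, millimetres (fixed at 24.0 by the
#'   magnification model; override only for sensitivity analyses).
#' @param l_A_range Plausibility bounds for `l_A`, millimetres.
#'
#' @return An object of class `scale_parameters`.
#' @seealso [compute_linear_scale()]
#' @export
scale_parameters <- function(T_um, T_s, f_l, l_A, RMF = 291, l_A0 = 24.0,
                             l_A_range = c(18, 32)) {
  vals <- c(T_um = T_um, T_s = T_s, f_l = f_l, l_A = l_A, RMF = RMF,
            l_A0 = l_A0)
  if (any(!is.finite(vals)) || any(vals <= 0))
    fm_stop("all scale parameters must be finite and strictly positive",
            "invalid_parameter")
  if (l_A < l_A_range[1] || l_A > l_A_range[2])
    fm_stop(sprintf("axial length %.2f mm outside plausible range [%g, %g]",
                    l_A, l_A_range[1], l_A_range[2]),
            "invalid_parameter")
  structure(as.list(vals), class = "scale_parameters")
}

#' Linear scale of an AOSLO image in micrometres per pixel
#'
#' Evaluates the magnification model
#' \deqn{S_{R(x)}' = \frac{T}{T_s \, f_l} \cdot \frac{180}{\pi} \cdot
#'   \mathrm{RMF} \cdot \frac{l_A}{l_{A,0}}}
#' where the Ronchi-ruling terms calibrate pixels per radian of scan angle,
#' RMF converts visual angle to retinal distance for the reference eye, and
#' the axial-length ratio adjusts the retinal magnification to the subject's
#' eye. The result is linear in `l_A`, `T_um` and `RMF`, and inversely linear
#' in `T_s` and `f_l`.
#'
#' @param params A [scale_parameters()] object.
#' @return Scale in micrometres per pixel (positive scalar).
#' @examples
#' p <- scale_parameters(T_um = 50, T_s = 10, f_l = 1e5, l_A = 24)
#' compute_linear_scale(p)
#' @export
compute_linear_scale <- function(params) {
  stopifnot(inherits(params, "scale_parameters"))
  with(params, (T_um / (T_s * f_l)) * (180 / pi) * RMF * (l_A / l_A0))
}

#' @export
print.scale_parameters <- function(x, ...) {
  cat("AOSLO scale parameters\n")
  cat(sprintf("  T = %g um/cycle, T_s = %g px/cycle, f_l = %g um\n",
              x$T_um, x$T_s, x$f_l))
  cat(sprintf("  RMF = %g um/deg at reference axial length %g mm\n",
              x$RMF, x$l_A0))
  cat(sprintf("  axial length = %g mm -> %.4f um/pixel\n",
              x$l_A, compute_linear_scale(x)))
  invisible(x)
}
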