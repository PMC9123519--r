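#' Scan geometry for angular-scan (HMM-style) images
#'
#' Bundles the parameters needed to convert an angular raster scan into a
#' linear retinal scale: scan size in degrees, raw pixel count, the
#' subject's axial length, and the schematic-eye constants.
#'
#' @param theta Scan size of the image in degrees.
#' @param i_s Number of pixels across the raw image.
#' @param al Axial length of the imaged eye in mm.
#' @param rmf Retinal magnification factor in um/degree for the reference
#'   eye. Default 291.
#' @param al_ref Axial length of the reference eye in mm. Default 24.0.
#' @return An object of class `scan_geometry`.
#' @seealso [hmm_scale()]
#' @export
#' @examples
#' g <- scan_geometry(theta = 8, i_s = 768, al = 24)
#' hmm_scale(g)  # 3.03125 um/pixel
scan_geometry <- function(theta, i_s, al, rmf = 291, al_ref = 24) {
  check_positive(theta, "theta")
  check_positive(i_s, "i_s")
  check_positive(al, "al")
  check_positive(rmf, "rmf")
  check_positive(al_ref, "al_ref")
  structure(list(theta = theta, i_s = i_s, al = al, rmf = rmf,
                 al_ref = al_ref), class = "scan_geometry")
}

#' Ronchi-ruling calibration for AOSLO-style scanners
#'
#' Parameters of a model-eye calibration in which a ruling of known
#' periodicity is imaged to measure the scanner's angular sampling.
#'
#' @param t_period Periodicity of the Ronchi ruling in um/cycle.
#' @param f1 Focal length of the model eye in um.
#' @param t_s Sampling period of the ruling lines in the image, in
#'   pixels/cycle.
#' @inheritParams scan_geometry
#' @return An object of class `ronchi_calibration`.
#' @seealso [aoslo_scale()]
#' @export
ronchi_calibration <- function(t_period, f1, t_s, al, rmf = 291, al_ref = 24) {
  check_positive(t_period, "t_period")
  check_positive(f1, "f1")
  check_positive(t_s, "t_s")
  check_positive(al, "al")
  check_positive(rmf, "rmf")
  check_positive(al_ref, "al_ref")
  structure(list(t_period = t_period, f1 = f1, t_s = t_s, al = al,
                 rmf = rmf, al_ref = al_ref), class = "ronchi_calibration")
}

#' Linear scale of an angular-scan image
#'
#' Computes the linear image scale in um/pixel as
#' `(theta / i_s) * rmf * (al / al_ref)`: degrees per pixel, times the
#' retinal magnification factor of the reference eye, rescaled linearly by
#' the subject's axial length.
#'
#' @param g A [scan_geometry()] object.
#' @return Scale in um/pixel.
#' @export
hmm_scale <- function(g) {
  stopifnot(inherits(g, "scan_geometry"))
  (g$theta / g$i_s) * g$rmf * (g$al / g$al_ref)
}

#' Linear scale of a Ronchi-calibrated scanner image
#'
#' Computes the linear image scale in um/pixel as
#' `(t_period / (f1 * t_s)) * (180 / pi) * rmf * (al / al_ref)`. The first
#' factor is the angular sampling in radians/pixel measured in the model
#' eye; it is converted to degrees and mapped onto the retina with the
#' magnification factor and axial-length ratio.
#'
#' @param cal A [ronchi_calibration()] object.
#' @return Scale in um/pixel.
#' @export
aoslo_scale <- function(cal) {
  stopifnot(inherits(cal, "ronchi_calibration"))
  (cal$t_period / (cal$f1 * cal$t_s)) * (180 / pi) * cal$rmf *
    (cal$al / cal$al_ref)
}

#' Convert visual angle to retinal distance
#'
#' Maps degrees of visual angle to um of retina using the reference-eye
#' magnification factor scaled linearly by axial length:
#' `deg * rmf * al / al_ref`.
#'
#' @param deg Visual angle in degrees.
#' @param al Axial length in mm.
#' @inheritParams scan_geometry
#' @return Distance in um (vectorized over `deg`).
#' @export
#' @examples
#' degrees_to_um(1, al = 24)  # 291 um
degrees_to_um <- function(deg, al, rmf = 291, al_ref = 24) {
  check_positive(al, "al")
  deg * rmf * al / al_ref
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("scan geometry: %g deg / %g px, AL %g mm (RMF %g um/deg @ %g mm)\n",
              x$theta, x$i_s, x$al, x$rmf, x$al_ref))
  cat(sprintf("  scale: %.5f um/px\n", hmm_scale(x)))
  invisible(x)
}

#' @export
print.ronchi_calibration <- function(x, ...) {
  cat(sprintf("Ronchi calibration: T %g um/cycle, f1 %g um, Ts %g px/cycle, AL %g mm\n",
              x$t_period, x$f1, x$t_s, x$al))
  cat(sprintf("  scale: %.5f um/px\n", aoslo_scale(x)))
  invisible(x)
}
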