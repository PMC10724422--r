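#' Diffraction-limited beam width
#'
#' Width of a focused laser spot, `prefactor * wavelength / NA`, with the
#' Rayleigh-Airy prefactor 1.22 (first Airy minimum; contains ~84% of the
#' intensity) or the 0.51 prefactor giving the full width at half maximum.
#'
#' @param wavelength laser wavelength (nm).
#' @param numerical_aperture objective NA (0 < NA <= 1.7).
#' @param criterion `"rayleigh"` (1.22) or `"fwhm"` (0.51).
#' @return beam width in nm (not rounded; round to the nearest nm for
#'   display).
#' @examples
#' round(beam_width(488, 1.2, "rayleigh"))  # 496
#' round(beam_width(488, 1.2, "fwhm"))      # 207
#' @export
beam_width <- function(wavelength, numerical_aperture,
                       criterion = c("rayleigh", "fwhm")) {
  if (!is.finite(wavelength) || wavelength <= 0) {
    stop("wavelength must be positive (nm)")
  }
  if (!is.finite(numerical_aperture) || numerical_aperture <= 0 ||
      numerical_aperture > 1.7) {
    stop("numerical_aperture must lie in (0, 1.7]")
  }
  criterion <- match.arg(criterion)
  pref <- switch(criterion, rayleigh = 1.22, fwhm = 0.51)
  pref * wavelength / numerical_aperture
}

#' Per-pixel photostimulation energy dose
#'
#' Total energy received by one pixel over a scan:
#' `iterations * intensity * pixel_size^2 * dwell_time`. The pixel area
#' (`pixel_size^2`) enters because the laser intensity is given per unit
#' area; the pixel is the minimum exposed area.
#'
#' @param iterations number of scan iterations (integer >= 1).
#' @param intensity laser intensity (uW um^-2).
#' @param pixel_size square pixel side (um).
#' @param dwell_time pixel dwell time (us).
#' @param reference optional reference energy (same units) by which to
#'   normalise; must be non-zero.
#' @return list with `energy` (uW um^-2 um^2 us = uW us per pixel) and, when
#'   a reference is supplied, `relative` (= energy / reference).
#' @examples
#' e1 <- total_energy(1, 157, 0.2, 2.55)$energy
#' e2 <- total_energy(1, 346, 0.2, 1.00)$energy
#' e1 / e2  # ~ 1.16: similar relative energy dose
#' @export
total_energy <- function(iterations, intensity, pixel_size, dwell_time,
                         reference = NULL) {
  if (!is.finite(iterations) || iterations < 1 ||
      iterations != round(iterations)) {
    stop("iterations must be an integer >= 1")
  }
  vals <- c(intensity = intensity, pixel_size = pixel_size,
            dwell_time = dwell_time)
  if (any(!is.finite(vals) | vals <= 0)) {
    stop("intensity, pixel_size and dwell_time must be strictly positive")
  }
  energy <- iterations * intensity * pixel_size^2 * dwell_time
  out <- list(energy = energy)
  if (!is.null(reference)) {
    if (!is.finite(reference) || reference == 0) {
      stop("reference energy must be non-zero")
    }
    out$relative <- energy / reference
  }
  out
}

#' Shear displacement speed
#'
#' Mean lateral speed of the substrate surface during one pattern
#' inscription: displacement per scan iteration divided by the inscription
#' time of one stripe.
#'
#' @param displacement_per_frame mean particle displacement per scan
#'   iteration (nm, >= 0).
#' @param inscription_time time to inscribe one stripe (ms, > 0).
#' @return speed in nm ms^-1 (exact quotient; round to 2 decimals for
#'   display).
#' @examples
#' round(shear_speed(41, 27.7), 2)  # 1.48
#' @export
shear_speed <- function(displacement_per_frame, inscription_time) {
  if (!is.finite(displacement_per_frame) || displacement_per_frame < 0) {
    stop("displacement_per_frame must be >= 0")
  }
  if (!is.finite(inscription_time) || inscription_time <= 0) {
    stop("inscription_time must be > 0")
  }
  displacement_per_frame / inscription_time
}
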