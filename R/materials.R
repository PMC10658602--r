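#' Acoustic material properties
#'
#' Bundle the three acoustic parameters used throughout the package: sound
#' speed, mass density and the power-law absorption prefactor. Absorption
#' follows alpha(f) = alpha0 * f^2 with alpha0 in dB/cm/MHz^2 (the power-law
#' exponent is fixed at 2, for which the acoustic dispersion correction
#' vanishes identically).
#'
#' @param sound_speed Sound speed in m/s. Must be positive.
#' @param density Mass density in kg/m^3. Must be positive.
#' @param alpha0 Absorption prefactor in dB/cm/MHz^2. Must be non-negative.
#' @param name Optional label.
#' @return An object of class `pa_material` (a named list).
#' @examples
#' material_properties(3100, 2190, 2.7, "bone")
#' @export
material_properties <- function(sound_speed, density, alpha0 = 0, name = NULL) {
  stopifnot(is.numeric(sound_speed), length(sound_speed) == 1L, sound_speed > 0,
            is.numeric(density), length(density) == 1L, density > 0,
            is.numeric(alpha0), length(alpha0) == 1L, alpha0 >= 0)
  structure(list(sound_speed = sound_speed, density = density,
                 alpha0 = alpha0, power_law_exponent = 2, name = name),
            class = "pa_material")
}

#' @export
print.pa_material <- function(x, ...) {
  cat(sprintf("<pa_material%s> c = %g m/s, rho = %g kg/m^3, alpha0 = %g dB/cm/MHz^2\n",
              if (is.null(x$name)) "" else paste0(": ", x$name),
              x$sound_speed, x$density, x$alpha0))
  invisible(x)
}

#' Reference material set
#'
#' Default acoustic properties: solid cortical/cancellous skull bone
#' (c = 3100 m/s, rho = 2190 kg/m^3, alpha0 = 2.7 dB/cm/MHz^2), degassed water
#' (c = 1480 m/s, rho = 1000 kg/m^3, lossless), and the polymer/sensor
#' materials used by the sensor response models: parylene C spacer, cyclo-olefin
#' polymer (COP) substrate, and a UV-cured spacer polymer.
#'
#' @return Named list of `pa_material` objects.
#' @export
pa_materials <- function() {
  list(
    bone     = material_properties(3100, 2190, 2.7, "bone"),
    water    = material_properties(1480, 1000, 0,   "water"),
    parylene = material_properties(2200, 1290, 0,   "parylene C"),
    cop      = material_properties(2440, 1010, 0,   "COP"),
    spacer   = material_properties(2500, 1200, 0,   "cured spacer polymer")
  )
}

#' Convert a power-law absorption prefactor to SI Nepers
#'
#' Converts alpha0 expressed in dB/cm/MHz^2 to the Np m^-1 (rad/s)^-2
#' prefactor used by the time-domain solver, via
#' alpha[Np/m] = alpha0 * 100 / 8.686 * (f / 1 MHz)^2.
#'
#' @param alpha0_db Absorption prefactor in dB/cm/MHz^2.
#' @return Prefactor in Np m^-1 (rad/s)^-2.
#' @export
alpha0_db_to_np <- function(alpha0_db) {
  alpha0_db * 100 / 8.686 / (2 * pi * 1e6)^2
}

#' Characteristic acoustic impedance
#'
#' @param material A `pa_material`.
#' @return Impedance Z = rho * c in Rayl (kg m^-2 s^-1).
#' @export
acoustic_impedance <- function(material) {
  material$density * material$sound_speed
}
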