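#' Acoustic intensity from spent energy and probe geometry
#'
#' Sonication dosimetry for probe-type transducers: the output power is the
#' spent energy over the sonication on-time, P = E / t_on, and the
#' intensity is the power over the probe face area, I = P / (pi r^2).
#'
#' @param energy_J spent energy in J (alternatively give `power_W`).
#' @param t_on_s sonication on-time in s (> 0; ignored when `power_W` is
#'   given).
#' @param radius_mm probe radius in mm (> 0); a "3.2 mm probe" has
#'   `radius_mm = 1.6`.
#' @param power_W output power in W, bypassing the energy/time step.
#' @return intensity in W/cm^2.
#' @examples
#' intensity_from_power(power_W = 1, radius_mm = 1.6)  # ~12.4 W/cm^2
#' @export
intensity_from_power <- function(energy_J = NULL, t_on_s = NULL, radius_mm,
                                 power_W = NULL) {
  if (is.null(power_W)) {
    if (is.null(energy_J) || is.null(t_on_s)) {
      stop("give either power_W, or energy_J together with t_on_s",
           call. = FALSE)
    }
    if (t_on_s <= 0) stop("on-time must be positive", call. = FALSE)
    if (energy_J < 0) stop("spent energy must be non-negative", call. = FALSE)
    power_W <- energy_J / t_on_s
  }
  if (power_W < 0) stop("power must be non-negative", call. = FALSE)
  if (radius_mm <= 0) stop("probe radius must be positive", call. = FALSE)
  area_cm2 <- pi * (radius_mm / 10)^2
  power_W / area_cm2
}

#' Acoustic pressure from intensity (linear plane-wave approximation)
#'
#' For sinusoidal waves in the linear approximation the intensity relates
#' to the acoustic pressure through I = p^2 / (rho c) with p the RMS
#' pressure; the peak pressure of a sinusoid is sqrt(2) times larger, so
#' p_peak = sqrt(2 I rho c).  Defaults are water near room temperature
#' (rho = 998 kg/m^3, c = 1482 m/s).
#'
#' @param intensity_W_cm2 acoustic intensity in W/cm^2 (>= 0).
#' @param rho fluid density in kg/m^3.
#' @param c_sound speed of sound in m/s.
#' @param convention `"peak"` (default) or `"rms"`.
#' @return acoustic pressure in MPa.
#' @examples
#' pressure_from_intensity(75.5)  # ~1.494 MPa peak
#' @export
pressure_from_intensity <- function(intensity_W_cm2, rho = 998,
                                    c_sound = 1482,
                                    convention = c("peak", "rms")) {
  convention <- match.arg(convention)
  if (intensity_W_cm2 < 0) stop("intensity must be >= 0", call. = FALSE)
  i_si <- intensity_W_cm2 * 1e4            # W/m^2
  p_pa <- sqrt(i_si * rho * c_sound)       # RMS, Pa
  if (convention == "peak") p_pa <- p_pa * sqrt(2)
  p_pa / 1e6
}

#' Intensity from acoustic pressure (inverse of [pressure_from_intensity()])
#'
#' @param pressure_MPa acoustic pressure in MPa.
#' @inheritParams pressure_from_intensity
#' @return intensity in W/cm^2.
#' @export
intensity_from_pressure <- function(pressure_MPa, rho = 998, c_sound = 1482,
                                    convention = c("peak", "rms")) {
  convention <- match.arg(convention)
  p_pa <- pressure_MPa * 1e6
  if (convention == "peak") p_pa <- p_pa / sqrt(2)
  p_pa^2 / (rho * c_sound) / 1e4
}

#' FDA mechanical index
#'
#' MI = p_neg / sqrt(f): peak negative acoustic pressure in MPa over the
#' square root of the frequency in MHz — the standard regulatory metric for
#' cavitation-related bioeffects (the FDA diagnostic limit is MI 1.9).  In
#' the linear approximation used here the peak negative pressure is taken
#' equal to the peak pressure magnitude.
#'
#' @param p_peak_negative_MPa peak negative pressure in MPa (>= 0).
#' @param f_MHz frequency in MHz (> 0).
#' @return dimensionless mechanical index.
#' @export
mechanical_index <- function(p_peak_negative_MPa, f_MHz) {
  if (f_MHz <= 0) stop("frequency must be positive (MHz)", call. = FALSE)
  if (p_peak_negative_MPa < 0) stop("pressure must be >= 0", call. = FALSE)
  p_peak_negative_MPa / sqrt(f_MHz)
}

#' Mechanical index straight from frequency and intensity
#'
#' Convenience chain: intensity -> peak pressure (linear approximation,
#' water defaults) -> MI.  With the printed HIFU operating points
#' (0.68 MHz at 75.5 W/cm^2; 1.52 MHz at 134.2 W/cm^2) this evaluates to
#' 1.8 and 1.6 after rounding to one decimal.
#'
#' @param f_MHz frequency in MHz.
#' @param intensity_W_cm2 intensity in W/cm^2.
#' @inheritParams pressure_from_intensity
#' @return dimensionless mechanical index.
#' @examples
#' round(mi_from_intensity(0.68, 75.5), 1)   # 1.8
#' round(mi_from_intensity(1.52, 134.2), 1)  # 1.6
#' @export
mi_from_intensity <- function(f_MHz, intensity_W_cm2, rho = 998,
                              c_sound = 1482,
                              convention = c("peak", "rms")) {
  convention <- match.arg(convention)
  mechanical_index(
    pressure_from_intensity(intensity_W_cm2, rho, c_sound, convention),
    f_MHz)
}

#' On-time and spent energy of a pulsed sonication protocol
#'
#' Pulsed sonication alternates on/off intervals (the release experiments
#' use 2 s on / 1 s off).  The on-fraction is on / (on + off); the spent
#' energy over a total wall-clock run is P * total * on-fraction.
#'
#' @param total_time_s total wall-clock sonication time in s.
#' @param on_s,off_s pulse on/off durations in s (>= 0, on + off > 0).
#' @param power_W output power in W.
#' @return list with `on_fraction`, `on_time_s` and `energy_J`.
#' @examples
#' duty_cycle_energy(900, 2, 1, 1)$energy_J  # 600 J
#' @export
duty_cycle_energy <- function(total_time_s, on_s, off_s, power_W) {
  if (on_s < 0 || off_s < 0 || total_time_s < 0 || power_W < 0) {
    stop("times and power must be non-negative", call. = FALSE)
  }
  if (on_s + off_s <= 0) stop("on + off must be positive", call. = FALSE)
  frac <- on_s / (on_s + off_s)
  on_time <- total_time_s * frac
  list(on_fraction = frac, on_time_s = on_time,
       energy_J = power_W * on_time)
}
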