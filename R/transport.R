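# Surfing / roll-over transport model.
#
# An ion in a traveling sinusoidal potential either locks to a wave trough
# and travels at the wave speed ("surfing") or repeatedly rolls over wave
# crests, advancing at a mobility-dependent mean speed below the wave speed.
# The control parameter is c = K * E_eff / v_wave, the ratio of the ion's
# maximum field-driven drift speed to the wave speed. For c >= 1 the ion
# surfs; for c < 1 the mean speed is v_wave * (1 - sqrt(1 - c^2)).

#' Maximum effective axial field of the traveling wave
#'
#' For a sinusoidal surface potential of peak-to-peak amplitude A over
#' wavelength lambda, the maximum axial field gradient is `pi * A / lambda`.
#' A square drive is represented by its fundamental Fourier harmonic, whose
#' amplitude is 4/pi times larger. The surface field is attenuated by the
#' configured `field_attenuation` factor to give the field at the ion's
#' position midway between the two electrode boards.
#'
#' @param config A [sim_config()].
#' @return Effective maximum field in V/m.
#' @export
wave_field_max <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  wv <- config$wave
  lambda_m <- wavelength(wv$geometry) / 1000
  e_surface <- pi * wv$amplitude_vpp / lambda_m
  if (wv$waveform == "square") e_surface <- e_surface * 4 / pi
  config$field_attenuation * e_surface
}

#' Wave-speed ratio of an ion (the surfing control parameter)
#'
#' `c = K * E_eff / v_wave`: the ion's maximum drift speed in the effective
#' wave field divided by the wave speed. `c >= 1` means the ion surfs.
#'
#' @param species An [ion_species()].
#' @param config A [sim_config()].
#' @return Dimensionless speed ratio c.
#' @export
wave_speed_ratio <- function(species, config) {
  stopifnot(inherits(species, "ion_species"), inherits(config, "sim_config"))
  k_si <- mobility_si(species$mz, species$z, species$ccs_a2, config$transport)
  k_si * wave_field_max(config) / config$wave$wave_speed_m_s
}

#' Mean axial ion speed under the traveling wave
#'
#' Surfing ions (`c >= 1`) travel at the wave speed; rolling-over ions
#' advance at `v_wave * (1 - sqrt(1 - c^2))`, which is monotone increasing
#' in c and vanishes with the mobility.
#'
#' @inheritParams wave_speed_ratio
#' @return Mean speed in m/s.
#' @examples
#' cfg <- sim_config(wave_config("sine", 40, wave_speed_m_s = 180))
#' mean_ion_speed(ion_species("x", 1522, 1, 324), cfg)
#' @export
mean_ion_speed <- function(species, config) {
  c_ratio <- wave_speed_ratio(species, config)
  v <- config$wave$wave_speed_m_s
  if (c_ratio >= 1) v else v * (1 - sqrt(1 - c_ratio^2))
}

#' Is an ion surfing under the configured wave?
#'
#' @inheritParams wave_speed_ratio
#' @return `TRUE` if the ion is locked to the wave (no mobility selectivity).
#' @export
is_surfing <- function(species, config) {
  wave_speed_ratio(species, config) >= 1
}

#' Arrival time of an ion
#'
#' `path_length / mean_speed + t0`. An ion whose mean speed is zero is
#' flagged as non-transmitted (`NA` arrival time with attribute
#' `transmitted = FALSE`) rather than raising an error.
#'
#' @inheritParams wave_speed_ratio
#' @return Arrival time in ms, with attributes `transmitted` (logical) and
#'   `surfing` (logical).
#' @export
arrival_time <- function(species, config) {
  vbar <- mean_ion_speed(species, config)
  tr <- config$transport
  if (vbar <= 0) {
    return(structure(NA_real_, transmitted = FALSE, surfing = FALSE))
  }
  t_ms <- tr$path_length_m / vbar * 1000 + tr$t0_ms
  structure(t_ms, transmitted = TRUE, surfing = is_surfing(species, config))
}

#' Ion speed as a fraction of the wave speed, from an arrival time
#'
#' Recovers the mean ion speed from a measured arrival time
#' (`L / (t - t0)`) and expresses it as a percentage of the wave speed.
#' An ion arriving at exactly the surf-only time is at 100%; one arriving
#' at three times the surf-only time moved at 33.3% of the wave speed.
#'
#' @param t_arrival_ms Arrival time in ms.
#' @param config A [sim_config()].
#' @return Ion speed as a percentage of the wave speed.
#' @examples
#' cfg <- sim_config(wave_config("sine", 40, wave_speed_m_s = 225),
#'                   transport_params(t0_ms = 0))
#' t_surf <- 13 / 225 * 1000
#' ion_speed_fraction(3 * t_surf, cfg) # 33.3%
#' @export
ion_speed_fraction <- function(t_arrival_ms, config) {
  stopifnot(inherits(config, "sim_config"))
  tr <- config$transport
  if (any(t_arrival_ms <= tr$t0_ms)) stop("`t_arrival_ms` must exceed t0")
  vbar <- tr$path_length_m / ((t_arrival_ms - tr$t0_ms) / 1000)
  100 * vbar / config$wave$wave_speed_m_s
}

#' Peak width of an ion under the transport model
#'
#' Three contributions added in quadrature:
#'
#' * diffusion: spatial spread `sigma = sqrt(2 D t_drift)` with
#'   `D = diffusion_scale * kB T K / q` (Einstein relation scaled for
#'   wave-driven dispersion), converted to time through the mean ion speed;
#'   at fixed speed this component grows as `sqrt(t_drift)`;
#' * an instrument width floor (`fwhm_floor_ms`);
#' * near-boundary intermittency: `boundary_scale * c^boundary_power *
#'   (t_drift - t_surf)`, a steep-onset term that degrades peaks of ions
#'   traveling just below the surfing threshold (`c -> 1`).
#'
#' @param species An [ion_species()].
#' @param t_arrival_ms Arrival time in ms (must exceed t0).
#' @param config A [sim_config()].
#' @return Full width at half maximum in ms.
#' @export
peak_width <- function(species, t_arrival_ms, config) {
  stopifnot(inherits(species, "ion_species"), inherits(config, "sim_config"))
  tr <- config$transport
  if (t_arrival_ms <= tr$t0_ms) stop("`t_arrival_ms` must exceed t0")
  t_drift_ms <- t_arrival_ms - tr$t0_ms
  t_drift_s <- t_drift_ms / 1000
  vbar <- tr$path_length_m / t_drift_s
  cc <- .slim_const
  k_si <- mobility_si(species$mz, species$z, species$ccs_a2, tr)
  d <- config$diffusion_scale * cc$kb_J_per_K * tr$temperature_k * k_si /
    (species$z * cc$e_C)
  sigma_t_ms <- sqrt(2 * d * t_drift_s) / vbar * 1000
  c_ratio <- min(wave_speed_ratio(species, config), 1)
  t_surf_ms <- tr$path_length_m / config$wave$wave_speed_m_s * 1000
  fwhm_boundary <- config$boundary_scale * c_ratio^config$boundary_power *
    max(t_drift_ms - t_surf_ms, 0)
  sqrt((cc$fwhm_sigma * sigma_t_ms)^2 + config$fwhm_floor_ms^2 +
         fwhm_boundary^2)
}
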