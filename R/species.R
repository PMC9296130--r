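#' Define an ion species
#'
#' Bundles the identifying and transport-relevant properties of an ion:
#' m/z, charge count, neutral mass, and its (ground-truth or reference)
#' collision cross section in nitrogen.
#'
#' @param label Text label.
#' @param mz Mass-to-charge ratio in Th (> 0).
#' @param z Charge count (>= 1).
#' @param ccs_a2 Collision cross section in A^2 (> 0).
#' @param neutral_mass_da Neutral monoisotopic mass in Da. Defaults to
#'   `mz * z - z * m_proton`, i.e. a protonated even-electron ion; supply
#'   explicitly for other adducts. A supplied value must be consistent with
#'   `mz * z` to within 2 Da times the charge.
#' @return An object of class `ion_species`.
#' @examples
#' ion_species("mz622", 622, 1, 202.1)
#' @export
ion_species <- function(label, mz, z = 1L, ccs_a2, neutral_mass_da = NULL) {
  stopifnot(is.numeric(mz), is.numeric(ccs_a2))
  if (mz <= 0) stop("`mz` must be > 0")
  if (z < 1) stop("`z` must be >= 1")
  if (ccs_a2 <= 0) stop("`ccs_a2` must be > 0")
  if (is.null(neutral_mass_da)) {
    neutral_mass_da <- mz * z - z * .slim_const$proton_Da
  } else if (abs(neutral_mass_da - (mz * z - z * .slim_const$proton_Da)) > 2 * z + 1) {
    stop("`neutral_mass_da` inconsistent with `mz` and `z`")
  }
  structure(
    list(label = as.character(label), mz = mz, z = as.integer(z),
         ccs_a2 = ccs_a2, neutral_mass_da = neutral_mass_da),
    class = "ion_species"
  )
}

#' @export
print.ion_species <- function(x, ...) {
  cat(sprintf("<ion_species> %s: m/z %.2f, z=%d, CCS %.1f A^2\n",
              x$label, x$mz, x$z, x$ccs_a2))
  invisible(x)
}

#' The eight-component tune-mix ion panel
#'
#' Returns the eight singly charged fluoroalkyl phosphazene tune-mix ions
#' that appear prominently in positive mode (m/z 622 to 2722 in 300 Th
#' steps). The packaged CCS ladder is SYNTHETIC: a smooth power law
#' `CCS = 6.81 * mz^0.527` A^2 (202-440 A^2 across the panel) chosen to be
#' monotone in m/z and of realistic magnitude for singly charged
#' phosphazenes in nitrogen. It is intended for simulation and testing,
#' not as literature reference data; supply `ccs_a2` to override with
#' measured values.
#'
#' @param ccs_a2 Optional numeric vector of 8 CCS values (A^2), one per ion
#'   in ascending m/z order, overriding the synthetic ladder.
#' @return A list of 8 [ion_species()] objects.
#' @examples
#' panel <- tune_mix_panel()
#' vapply(panel, function(p) p$mz, numeric(1))
#' @export
tune_mix_panel <- function(ccs_a2 = NULL) {
  mz <- seq(622, 2722, by = 300)
  if (is.null(ccs_a2)) {
    # synthetic ladder, 6.81 * mz^0.527 rounded to 0.1 A^2; also packaged as
    # extdata/tune_mix_synthetic_ccs.csv
    ccs_a2 <- c(202.1, 248.6, 288.4, 323.8, 356.0, 385.8, 413.6, 439.9)
  }
  stopifnot(length(ccs_a2) == length(mz), all(ccs_a2 > 0))
  if (any(diff(ccs_a2) <= 0)) stop("CCS ladder must be strictly increasing with m/z")
  mapply(function(m, c) ion_species(paste0("mz", m), m, 1L, c),
         mz, ccs_a2, SIMPLIFY = FALSE)
}

#' Gas and transport conditions of the separation region
#'
#' @param path_length_m Separation path length in m. Default 13.
#' @param gas Buffer gas name. Default `"N2"`.
#' @param gas_mass_da Buffer gas molar mass in Da. Default 28.0134 (N2).
#' @param pressure_torr Gas pressure in Torr. Default 2.5.
#' @param temperature_k Gas temperature in K. Default 300.
#' @param t0_ms Non-mobility transit time (source, transfer optics, TOF) added
#'   to every arrival time, in ms. Default 5.
#' @return An object of class `transport_params`.
#' @export
transport_params <- function(path_length_m = 13, gas = "N2",
                             gas_mass_da = 28.0134, pressure_torr = 2.5,
                             temperature_k = 300, t0_ms = 5) {
  if (path_length_m <= 0) stop("`path_length_m` must be > 0")
  if (pressure_torr <= 0) stop("`pressure_torr` must be > 0")
  if (temperature_k <= 0) stop("`temperature_k` must be > 0")
  if (gas_mass_da <= 0) stop("`gas_mass_da` must be > 0")
  if (t0_ms < 0) stop("`t0_ms` must be >= 0")
  structure(
    list(path_length_m = path_length_m, gas = gas, gas_mass_da = gas_mass_da,
         pressure_torr = pressure_torr, temperature_k = temperature_k,
         t0_ms = t0_ms),
    class = "transport_params"
  )
}

#' Simulation configuration
#'
#' Collects everything the synthetic trace generator needs: the wave drive,
#' the transport conditions, sampling, the noise model, and the seed that
#' makes generation bit-reproducible.
#'
#' @param wave A [wave_config()].
#' @param transport A [transport_params()].
#' @param sampling_interval_ms Trace sampling interval in ms. Default 0.05.
#' @param noise `"gaussian"` (default), `"shot"`, or `"none"`.
#' @param noise_scale For `"gaussian"`: the noise s.d. as a fraction of the
#'   tallest peak (default 0.01, i.e. 1%); for `"shot"`: counts at the
#'   tallest peak apex (Poisson statistics).
#' @param seed Integer random seed.
#' @param diffusion_scale Dimensionless factor applied to the Einstein
#'   diffusion coefficient. Wave-driven heating and intra-well mixing make
#'   the effective axial dispersion in traveling-wave transport several
#'   times larger than free-flight thermal diffusion; the default 5
#'   reproduces the peak-width scale of 13 m SLIM tracks.
#' @param fwhm_floor_ms Instrument peak-width floor (release width of the
#'   accumulation gate, detector response) added in quadrature to the
#'   diffusive width, in ms. Default 2.5.
#' @param boundary_scale,boundary_power Phenomenological near-boundary
#'   broadening: ions just below the surfing threshold intermittently lock
#'   to the wave, which degrades selectivity close to `c = 1`. Adds
#'   `boundary_scale * c^boundary_power * (t_drift - t_surf)` (ms, in
#'   quadrature) to the peak width. Defaults 0.3 and 20 (steep onset, only
#'   material for `c` above roughly 0.85); set `boundary_scale = 0` to
#'   disable.
#' @param field_attenuation Fraction of the surface waveform field felt by
#'   ions midway between the boards. `NULL` (default) computes
#'   `exp(-pi * board_gap / wavelength)`, the leading-order decay of a
#'   periodic surface potential at the midplane.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(wave_config("sine", 40, wave_speed_m_s = 180))
#' @export
sim_config <- function(wave = wave_config(),
                       transport = transport_params(),
                       sampling_interval_ms = 0.05,
                       noise = c("gaussian", "shot", "none"),
                       noise_scale = 0.01,
                       seed = 1L,
                       diffusion_scale = 5,
                       fwhm_floor_ms = 2.5,
                       boundary_scale = 0.3,
                       boundary_power = 20,
                       field_attenuation = NULL) {
  noise <- match.arg(noise)
  stopifnot(inherits(wave, "wave_config"), inherits(transport, "transport_params"))
  if (sampling_interval_ms <= 0) stop("`sampling_interval_ms` must be > 0")
  if (diffusion_scale < 0) stop("`diffusion_scale` must be >= 0")
  if (fwhm_floor_ms < 0) stop("`fwhm_floor_ms` must be >= 0")
  if (boundary_scale < 0 || boundary_power <= 0) {
    stop("`boundary_scale` must be >= 0 and `boundary_power` > 0")
  }
  if (is.null(field_attenuation)) {
    field_attenuation <-
      exp(-pi * wave$geometry$board_gap_mm / wavelength(wave$geometry))
  }
  if (field_attenuation <= 0 || field_attenuation > 1) {
    stop("`field_attenuation` must be in (0, 1]")
  }
  structure(
    list(wave = wave, transport = transport,
         sampling_interval_ms = sampling_interval_ms,
         noise = noise, noise_scale = noise_scale, seed = as.integer(seed),
         diffusion_scale = diffusion_scale, fwhm_floor_ms = fwhm_floor_ms,
         boundary_scale = boundary_scale, boundary_power = boundary_power,
         field_attenuation = field_attenuation),
    class = "sim_config"
  )
}
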