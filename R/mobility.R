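#' Ion-neutral reduced mass
#'
#' `m1 * m2 / (m1 + m2)`; symmetric in its arguments and always smaller than
#' the lighter partner.
#'
#' @param m_ion_da Ion mass in Da (> 0).
#' @param m_gas_da Neutral gas mass in Da (> 0). Default 28.0134 (N2).
#' @return Reduced mass in Da.
#' @examples
#' reduced_mass(621, 28.0134)
#' @export
reduced_mass <- function(m_ion_da, m_gas_da = 28.0134) {
  if (any(m_ion_da <= 0) || any(m_gas_da <= 0)) {
    stop("masses must be > 0")
  }
  m_ion_da * m_gas_da / (m_ion_da + m_gas_da)
}

#' Low-field ion mobility from a collision cross section (and back)
#'
#' Mason-Schamp relation at the given gas number density:
#' `K = (3 z e / 16 N) * sqrt(2 pi / (mu kB T)) / CCS`, with `mu` the
#' ion-neutral reduced mass. `ccs_from_mobility()` is the exact inverse.
#' The ion mass entering `mu` is `mz * z` (electron and adduct masses folded
#' into the measured m/z).
#'
#' @param species An [ion_species()].
#' @param transport A [transport_params()].
#' @param k_cm2 Mobility in cm^2/(V s) (for the inverse).
#' @param mz,z m/z (Th) and charge (for the inverse).
#' @return `mobility_from_ccs()`: K in cm^2/(V s). `ccs_from_mobility()`:
#'   CCS in A^2.
#' @examples
#' sp <- ion_species("mz622", 622, 1, 202)
#' K <- mobility_from_ccs(sp, transport_params())
#' ccs_from_mobility(K, 622, 1, transport_params()) # 202
#' @export
mobility_from_ccs <- function(species, transport = transport_params()) {
  stopifnot(inherits(species, "ion_species"), inherits(transport, "transport_params"))
  mobility_si(species$mz, species$z, species$ccs_a2, transport) * 1e4
}

#' @rdname mobility_from_ccs
#' @export
ccs_from_mobility <- function(k_cm2, mz, z = 1L, transport = transport_params()) {
  if (any(k_cm2 <= 0)) stop("`k_cm2` must be > 0")
  # invert: CCS = (3 z e / 16 N) * sqrt(2 pi / (mu kB T)) / K
  pref <- .mobility_prefactor(mz, z, transport)   # m^2/(V s) * m^2
  pref / (k_cm2 / 1e4) * 1e20
}

# K in SI units m^2/(V s); internal
#' @keywords internal
#' @noRd
mobility_si <- function(mz, z, ccs_a2, transport) {
  .mobility_prefactor(mz, z, transport) / (ccs_a2 * 1e-20)
}

#' @keywords internal
#' @noRd
.mobility_prefactor <- function(mz, z, transport) {
  cc <- .slim_const
  mu_kg <- reduced_mass(mz * z, transport$gas_mass_da) * cc$amu_kg
  n <- gas_number_density(transport$pressure_torr, transport$temperature_k)
  (3 * z * cc$e_C / (16 * n)) *
    sqrt(2 * pi / (mu_kg * cc$kb_J_per_K * transport$temperature_k))
}
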