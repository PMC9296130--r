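# Physical constants (CODATA 2018) and unit conversions.
# All geometry math runs in mm/kHz/ms; transport math in SI; conversions live
# here so no factor is scattered through the code.

.slim_const <- list(
  e_C          = 1.602176634e-19,   # elementary charge, C
  kb_J_per_K   = 1.380649e-23,      # Boltzmann constant, J/K
  amu_kg       = 1.66053906660e-27, # unified atomic mass unit, kg
  torr_Pa      = 101325 / 760,      # 1 Torr in Pa
  proton_Da    = 1.00727646688,     # mass of H+ (H minus electron), Da
  electron_Da  = 0.00054857990907,
  fwhm_sigma   = 2 * sqrt(2 * log(2)) # fwhm = 2.3548 * sigma for a Gaussian
)

#' @keywords internal
#' @noRd
gas_number_density <- function(pressure_torr, temperature_k) {
  stopifnot(pressure_torr > 0, temperature_k > 0)
  pressure_torr * .slim_const$torr_Pa / (.slim_const$kb_J_per_K * temperature_k)
}

# Monoisotopic element masses, Da
.element_mass <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  F  = 18.99840322
)

# Monoisotopic amino-acid residue masses, Da (residue = amino acid - water)
.residue_mass <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.water_Da <- 18.0105646863

# Supported adducts: mass shift added to the neutral (Da) and implied charge.
# Cation adducts subtract one electron mass per charge (folded into the shift).
.adducts <- list(
  "+H"  = list(dm = 1.00727646688, z = 1L),
  "+2H" = list(dm = 2 * 1.00727646688, z = 2L),
  "+Na" = list(dm = 22.9897692809 - 0.00054857990907, z = 1L),
  "-2H" = list(dm = -2 * 1.00727646688, z = 2L)
)
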