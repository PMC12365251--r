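# Physical constants for palladium tracer quantification.

.pd_const <- list(
  atomic_mass_g_mol = 106.42,
  avogadro          = 6.02214076e23,
  # Natural isotopic composition of Pd (atom fractions).
  abundances = c(Pd102 = 0.0102, Pd104 = 0.1114, Pd105 = 0.2233,
                 Pd106 = 0.2733, Pd108 = 0.2646, Pd110 = 0.1172),
  # Characteristic K-line energies (keV).
  kalpha_kev = 21.12,
  kbeta_kev  = 23.82,
  # Effective fluorescence-production cross sections per line at 53 keV
  # excitation (cm^2/atom): K-shell photoionization (~2.8e-22 cm^2) times
  # K fluorescence yield omega_K ~ 0.82 times K-alpha/K-beta branching
  # (0.77/0.23). Absolute scale is calibrated out by reference targets;
  # only the forward model uses these.
  sigma_f_kalpha_cm2 = 2.8e-22 * 0.82 * 0.77,
  sigma_f_kbeta_cm2  = 2.8e-22 * 0.82 * 0.23
)

# Mass attenuation coefficients of liquid water (cm^2/g), NIST
# (Hubbell & Seltzer) tabulation, 15-60 keV.
.water_mu_rho <- data.frame(
  energy_kev = c(15, 20, 30, 40, 50, 60),
  mu_rho_cm2_g = c(1.673, 0.8096, 0.3756, 0.2683, 0.2269, 0.2059)
)

#' Natural palladium isotope abundances
#'
#' Atom fractions of the six stable Pd isotopes, used to split simulated ion
#' counts across IMC detector channels.
#'
#' @return Named numeric vector (names `Pd102` ... `Pd110`) summing to 1.
#' @export
#' @examples
#' pd_isotope_abundances()
pd_isotope_abundances <- function() {
  .pd_const$abundances / sum(.pd_const$abundances)
}

#' Palladium K-line energies
#'
#' @return Named numeric vector `c(kalpha = 21.12, kbeta = 23.82)` in keV.
#' @export
pd_line_energies <- function() {
  c(kalpha = .pd_const$kalpha_kev, kbeta = .pd_const$kbeta_kev)
}

#' Tabulated mass attenuation coefficients of water
#'
#' NIST (Hubbell & Seltzer) mass attenuation coefficients of liquid water
#' between 15 and 60 keV, the range bracketing the Pd K lines and the
#' excitation energy. Values are interpolated log-log by
#' [estimate_attenuation_bias()].
#'
#' @return `data.frame` with columns `energy_kev` and `mu_rho_cm2_g`.
#' @export
water_mass_attenuation <- function() {
  .water_mu_rho
}

# Number of Pd atoms per microgram of Pd.
pd_atoms_per_ug <- function() {
  1e-6 * .pd_const$avogadro / .pd_const$atomic_mass_g_mol
}

# Deterministic child seed for a named RNG stream; keeps results < 2^31.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483647)
}
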