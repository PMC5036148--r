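#' Physical constants (CODATA 2018, exact SI values)
#'
#' @description
#' Constants used throughout: Boltzmann constant `kB` (J K^-1), Avogadro
#' number `N_A` (mol^-1), molar gas constant `R_gas` (J mol^-1 K^-1), and the
#' molar mass of water `M_WATER` (g mol^-1).
#'
#' Internal unit conventions follow MD practice: lengths in nm, times in ps,
#' particle masses in g mol^-1, mass densities in g cm^-3, temperatures in K.
#' Thermal quantities cross into SI at the model boundary: interfacial
#' conductance in MW m^-2 K^-1, heating power density in GW m^-2, thermal
#' conductivity in W m^-1 K^-1.
#'
#' @name constants
#' @keywords internal
NULL

KB <- 1.380649e-23       # J K^-1
N_AVOGADRO <- 6.02214076e23  # mol^-1
R_GAS <- KB * N_AVOGADRO     # J mol^-1 K^-1
M_WATER <- 18.01528      # g mol^-1
M_CARBON <- 12.011       # g mol^-1

# 1 nm^3 in cm^3
NM3_TO_CM3 <- 1e-21
# 1 nm ps^-1 in m s^-1
NMPS_TO_MS <- 1e3

#' Specific heat of graphene from the Dulong-Petit law
#'
#' Classical high-temperature lattice specific heat: three quadratic degrees
#' of freedom per atom, \eqn{c = 3 N_A k_B / M}, evaluated per gram of carbon.
#' Returns approximately 2.1 J g^-1 K^-1, the value conventionally used for
#' the heat capacity of a graphene sheet.
#'
#' @param molar_mass Atomic molar mass in g mol^-1 (default: carbon, 12.011).
#' @return Specific heat in J g^-1 K^-1.
#' @examples
#' graphite_specific_heat()  # ~2.08, rounds to 2.1
#' @export
graphite_specific_heat <- function(molar_mass = M_CARBON) {
  3 * R_GAS / molar_mass
}
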