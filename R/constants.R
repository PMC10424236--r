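#' Physical constants used throughout the package
#'
#' All energies are in kJ/mol, lengths in nm, charges in elementary charge
#' units. The constants are centralised here so every module draws the same
#' literature values.
#'
#' @format A named list with components:
#' \describe{
#'   \item{N_A}{Avogadro constant, 1/mol (CODATA exact value).}
#'   \item{R_GAS}{Molar gas constant, kJ/(mol K).}
#'   \item{BJERRUM_WATER_300K}{Bjerrum length of water at 300 K, nm.}
#'   \item{BDNA_RISE_NM}{Canonical B-DNA rise per base pair, nm.}
#' }
#' @export
phys_const <- list(
  N_A               = 6.02214076e23,
  R_GAS             = 8.31446261815324e-3,
  BJERRUM_WATER_300K = 0.7,
  BDNA_RISE_NM      = 0.338
)

#' Thermal energy kT in kJ/mol
#'
#' @param temperature Temperature in kelvin.
#' @return `R * T` in kJ/mol (2.494 kJ/mol at 300 K).
#' @export
kT <- function(temperature = 300) {
  stopifnot(is.numeric(temperature), temperature > 0)
  phys_const$R_GAS * temperature
}
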