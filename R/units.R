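# Unit conventions used throughout: lengths nm, times ns, energies kJ/mol,
# temperatures K.  File readers convert at the boundary (PDB Angstrom -> nm).

#' Boltzmann constant in kJ/mol/K
#'
#' The package works in nm / ns / kJ/mol units; `KB` is the Boltzmann constant
#' in those units.
#' @export
KB <- 0.0083145

#' Thermal energy k_B*T
#'
#' @param temperature Temperature in K. Default 310 K, physiological
#'   temperature used for all sampling and reweighting in this package.
#' @return Thermal energy in kJ/mol (2.5775 kJ/mol at 310 K).
#' @export
#' @examples
#' kT(310)
kT <- function(temperature = 310) {
  stopifnot(is.numeric(temperature), temperature > 0)
  KB * temperature
}
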