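# Physical constants used throughout.
# Electrostatic conversion constant e^2/(4 pi eps0), kcal A / (mol e^2).
.ke <- 332.0637

# Boltzmann constant, kcal / (mol K).
.kb <- 0.0019872041

# Avogadro scaling: mol/L -> particles/A^3.
.mol_per_L_to_per_A3 <- 6.02214076e-4

#' Thermal energy kT in kcal/mol
#'
#' @param temperature Temperature in Kelvin.
#' @return kT in kcal/mol (0.6160 kcal/mol at 310 K).
#' @export
kT_kcal <- function(temperature = 310) {
  .kb * temperature
}
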