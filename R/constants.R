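#' Physical constants
#'
#' CODATA 2018 values used throughout the kinetic and thermodynamic
#' computations: the molar gas constant `R_GAS` (J mol^-1 K^-1), the
#' Boltzmann constant `K_BOLTZMANN` (J K^-1) and the Planck constant
#' `H_PLANCK` (J s).
#'
#' @name constants
#' @keywords internal
NULL

R_GAS <- 8.314462618
K_BOLTZMANN <- 1.380649e-23
H_PLANCK <- 6.62607015e-34
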