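#' Physical constants used throughout the package
#'
#' CODATA-2018 exact values. The hartree-to-electronvolt factor is stored in
#' one place and used for every unit conversion; conversions are always
#' explicit, never implicit.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{hartree_ev}{1 hartree in eV (27.211386245988).}
#'   \item{kB}{Boltzmann constant, J/K.}
#'   \item{h}{Planck constant, J s.}
#'   \item{R}{Molar gas constant, J/(mol K).}
#' }
#' @export
thio_constants <- list(
  hartree_ev = 27.211386245988,
  kB = 1.380649e-23,
  h  = 6.62607015e-34,
  R  = 8.31446261815324
)

#' Convert hartree to electronvolt
#'
#' Multiplies by the CODATA-2018 conversion factor 27.211386245988 eV/hartree.
#' No rounding is applied.
#'
#' @param x Numeric vector of energies in hartree.
#' @return Numeric vector of energies in eV.
#' @examples
#' hartree_to_ev(1)    # 27.211386245988
#' hartree_to_ev(-551)
#' @export
hartree_to_ev <- function(x) {
  x * thio_constants$hartree_ev
}
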