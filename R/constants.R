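#' Physical constants in internal units
#'
#' The package works throughout in the MD unit system kJ/mol (energy),
#' nm (length), ps (time), amu (mass) and K (temperature), in which
#' 1 kJ/mol = 1 amu nm^2/ps^2.  Energies cross to kcal/mol only at
#' reporting boundaries.
#'
#' @return A list with elements `kB` (Boltzmann constant,
#'   0.0083144621 kJ/mol/K), `hbar` (reduced Planck constant,
#'   0.0635077993 kJ ps/mol) and `kcal_per_kJ` (1/4.184).
#' @examples
#' pc <- phys_constants()
#' pc$kB * 300   # thermal energy at 300 K, kJ/mol
#' @export
phys_constants <- function() {
  list(kB = 0.0083144621,
       hbar = 0.0635077993,
       kcal_per_kJ = 1 / 4.184)
}

#' Inverse temperature beta = 1/(kB T)
#'
#' @param temperature Temperature in K.
#' @return beta in mol/kJ.
#' @export
beta_of <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  1 / (phys_constants()$kB * temperature)
}

#' Convert kJ/mol to kcal/mol
#' @param x Energy in kJ/mol.
#' @return Energy in kcal/mol.
#' @export
kj_to_kcal <- function(x) x * phys_constants()$kcal_per_kJ
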