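## Physical constants and unit conventions.
##
## Internal units throughout: lengths in Angstrom, energies in kcal/mol,
## times in ns (protocol time steps are given in ps and converted once),
## charges in units of the elementary charge e, diffusion in A^2/ns.

#' Physical constants used by the model
#'
#' Unit system: Angstrom, kcal/mol, ns, elementary charge.
#'
#' @format A named list with elements
#' \describe{
#'   \item{kbt298}{Thermal energy at 298 K, 0.59248 kcal/mol.}
#'   \item{coulomb}{e^2 in kcal A / mol, 332.06.}
#'   \item{eta_water}{Viscosity of water at 298 K in cP, 0.89.}
#'   \item{bp_rise}{Base-pair spacing b of B-DNA used in search-rate theory, 3.4 A.}
#'   \item{residue_rise}{Rise per pseudo-residue of the CG helix, 3.38 A.}
#'   \item{helix_pitch}{Helix pitch, 33.8 A (10 residues).}
#' }
#' @export
bd_constants <- list(
  kbt298       = 0.59248,
  coulomb      = 332.06,
  eta_water    = 0.89,
  bp_rise      = 3.4,
  residue_rise = 3.38,
  helix_pitch  = 33.8,
  kB_SI        = 1.380649e-23,
  NA_SI        = 6.02214076e23
)

#' Thermal energy in kcal/mol
#'
#' @param temperature Temperature in K.
#' @return k_B T in kcal/mol (0.59248 at 298 K).
#' @export
kbt <- function(temperature = 298) {
  bd_constants$kbt298 * temperature / 298
}

#' Stokes-Einstein mobility constant k_B T / (6 pi eta)
#'
#' Dividing by a Stokes radius in Angstrom gives a translational diffusion
#' coefficient in A^2/ns; 245.2 A^3/ns at 298 K in water (eta = 0.89 cP).
#'
#' @param temperature Temperature in K.
#' @param eta Solvent viscosity in cP.
#' @return k_B T / (6 pi eta) in A^3/ns.
#' @export
mobility_constant <- function(temperature = 298, eta = bd_constants$eta_water) {
  # kB*T[J] / (6 pi eta[Pa s]) = m^3/s; 1 m^3/s = 1e30 A^3 / 1e9 ns
  bd_constants$kB_SI * temperature / (6 * pi * eta * 1e-3) * 1e21
}

#' Stokes-Einstein translational diffusion coefficient
#'
#' @param a Stokes radius in A.
#' @inheritParams mobility_constant
#' @return D in A^2/ns.
#' @export
stokes_einstein_d <- function(a, temperature = 298, eta = bd_constants$eta_water) {
  stopifnot(all(a > 0))
  mobility_constant(temperature, eta) / a
}
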