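## Potential energy terms and analytic forces.
##
## V_total = sum of harmonic bonds, harmonic angles, harmonic torsions
## (minimum-image wrapped), half-harmonic excluded volume, screened DLVO
## electrostatics, Cartesian positional restraints and optional umbrella /
## plane biases. All bonded terms use the 1/2 k convention.

#' Default nonbonded / force-field parameters
#'
#' The reference simulation conditions: k_ex = 1 kcal/mol/A^2, dielectric
#' 78.5, Debye length 7.8 A (0.15 M 1:1 salt at 298 K), nonbonded cutoff
#' 40 A (plain truncation), and nonbonded exclusion of pairs within the
#' same molecule separated by at most 4 pseudo-residues.
#'
#' @param kex Excluded-volume force constant, kcal/mol/A^2.
#' @param eps Relative dielectric constant.
#' @param debye_length Debye screening length 1/kappa in A.
#' @param cutoff Nonbonded cutoff in A.
#' @param excl_sep Intramolecular residue-separation exclusion bound.
#' @param use_dlvo If `TRUE` (default) the DLVO finite-size factors
#'   exp(kappa a)/(1 + kappa a) multiply each bead's charge; if `FALSE`
#'   bare Debye-Hueckel screening is used.
#' @return A list of class `ff_params`.
#' @export
ff_params <- function(kex = 1, eps = 78.5, debye_length = 7.8, cutoff = 40,
                      excl_sep = 4, use_dlvo = TRUE) {
  stopifnot(kex >= 0, eps > 0, debye_length > 0, cutoff > 0)
  structure(
    list(kex = kex, eps = eps, kappa = 1 / debye_length, cutoff = cutoff,
         coulomb = bd_constants$coulomb, excl_sep = as.integer(excl_sep),
         use_dlvo = isTRUE(use_dlvo)),
    class = "ff_params"
  )
}

#' Harmonic bond energy
#'
#' V = 1/2 k (r - r0)^2.
#'
#' @param r Bond length in A (> 0).
#' @param k Force constant in kcal/mol/A^2.
#' @param r0 Equilibrium length in A.
#' @return Energy in kcal/mol.
#' @export
bond_energy <- function(r, k, r0) {
  if (any(r <= 0)) stop("singular geometry: bond length must be > 0")
  0.5 * k * (r - r0)^2
}

#' Harmonic angle energy
#'
#' V = 1/2 k (theta - theta0)^2.
#'
#' @param theta Bond angle in radians, in `[0, pi]`.
#' @param k Force constant in kcal/mol.
#' @param theta0 Equilibrium angle in radians.
#' @return Energy in kcal/mol.
#' @export
angle_energy <- function(theta, k, theta0) {
  stopifnot(all(theta >= 0), all(theta <= pi))
  0.5 * k * (theta - theta0)^2
}

#' Harmonic torsion energy
#'
#' V = 1/2 k dphi^2 with dphi the difference phi - phi0 wrapped to
#' (-pi, pi], so that +pi and -pi deviations have equal energy.
#'
#' @param phi Torsion angle in radians.
#' @param k Force constant in kcal/mol.
#' @param phi0 Equilibrium torsion in radians.
#' @return Energy in kcal/mol.
#' @export
torsion_energy <- function(phi, k, phi0) {
  dphi <- (phi - phi0) %% (2 * pi)
  dphi <- ifelse(dphi > pi, dphi - 2 * pi, dphi)
  0.5 * k * dphi^2
}

#' Half-harmonic excluded-volume energy
#'
#' Zero for r >= sigma_i + sigma_j, else 1/2 k_ex (sigma_i + sigma_j - r)^2;
#' continuous with continuous first derivative at contact.
#'
#' @param r Center distance in A (> 0).
#' @param sigma_i,sigma_j Excluded-volume radii in A.
#' @param kex Force constant in kcal/mol/A^2.
#' @return Energy in kcal/mol.
#' @export
excluded_volume_energy <- function(r, sigma_i, sigma_j, kex = 1) {
  if (any(r <= 0)) stop("singular geometry: distance must be > 0")
  ov <- pmax(sigma_i + sigma_j - r, 0)
  0.5 * kex * ov^2
}

#' Screened DLVO (Yukawa) electrostatic pair energy
#'
#' V = (C/eps) q_i q_j \[exp(kappa a_i)/(1 + kappa a_i)\]
#' \[exp(kappa a_j)/(1 + kappa a_j)\] exp(-kappa r)/r with
#' C = 332.06 kcal A/mol. With `use_dlvo = FALSE` the finite-size factors
#' are dropped (bare Debye-Hueckel). At kappa = 0 the size factors reduce
#' to 1 and the potential to Coulomb/eps.
#'
#' @param r Center distance in A (> 0).
#' @param q_i,q_j Effective charges in units of e.
#' @param a_i,a_j Stokes radii in A (enter the size factors).
#' @param eps Relative dielectric constant.
#' @param kappa Inverse Debye length in 1/A.
#' @param use_dlvo Include the finite-size factors?
#' @return Energy in kcal/mol.
#' @export
electrostatic_energy <- function(r, q_i, q_j, a_i, a_j, eps = 78.5,
                                 kappa = 1 / 7.8, use_dlvo = TRUE) {
  if (any(r <= 0)) stop("singular geometry: distance must be > 0")
  size <- if (use_dlvo) {
    (exp(kappa * a_i) / (1 + kappa * a_i)) *
      (exp(kappa * a_j) / (1 + kappa * a_j))
  } else 1
  (bd_constants$coulomb / eps) * q_i * q_j * size * exp(-kappa * r) / r
}

## internal: marshal a cg_system into the flat arrays the C++ kernels take
.sys_arrays <- function(system) {
  b <- system$beads
  list(
    topo = list(
      bonds = cbind(as.integer(system$bonds$i) - 1L,
                    as.integer(system$bonds$j) - 1L),
      kb = as.numeric(system$bonds$k), b_r0 = as.numeric(system$bonds$r0),
      angles = cbind(as.integer(system$angles$i) - 1L,
                     as.integer(system$angles$j) - 1L,
                     as.integer(system$angles$k) - 1L),
      ka = as.numeric(system$angles$ka),
      th0 = as.numeric(system$angles$theta0),
      torsions = cbind(as.integer(system$torsions$i) - 1L,
                       as.integer(system$torsions$j) - 1L,
                       as.integer(system$torsions$k) - 1L,
                       as.integer(system$torsions$l) - 1L),
      kt = as.numeric(system$torsions$kt),
      phi0 = as.numeric(system$torsions$phi0)
    ),
    sys = list(
      sigma = as.numeric(b$sigma), stokes = as.numeric(b$stokes),
      charge = as.numeric(b$charge),
      molecule = as.integer(b$molecule), residue = as.integer(b$residue)
    )
  )
}

.empty_topo_matrices <- function(arr) {
  # arma insists on correctly-shaped matrices even when empty
  t <- arr$topo
  if (nrow(t$bonds) == 0) t$bonds <- matrix(integer(), 0, 2)
  if (nrow(t$angles) == 0) t$angles <- matrix(integer(), 0, 3)
  if (nrow(t$torsions) == 0) t$torsions <- matrix(integer(), 0, 4)
  arr$topo <- t
  arr
}

.restraint_list <- function(restraints, n) {
  if (is.null(restraints)) {
    list(kr = numeric(n), anchors = matrix(0, n, 3))
  } else {
    stopifnot(length(restraints$kr) == n,
              all(dim(restraints$anchors) == c(n, 3)))
    list(kr = as.numeric(restraints$kr),
         anchors = unname(as.matrix(restraints$anchors)))
  }
}

.bias_list <- function(bias) {
  if (is.null(bias)) return(list(umbrella = NULL, zplane = NULL))
  out <- list(umbrella = NULL, zplane = NULL)
  if (!is.null(bias$umbrella)) {
    u <- bias$umbrella
    out$umbrella <- list(i = as.integer(u$i) - 1L, j = as.integer(u$j) - 1L,
                         k = as.numeric(u$k), r0 = as.numeric(u$r0))
  }
  if (!is.null(bias$zplane)) {
    z <- bias$zplane
    out$zplane <- list(i = as.integer(z$i) - 1L, k = as.numeric(z$k),
                       z0 = as.numeric(z$z0))
  }
  out
}

#' Total potential energy and analytic forces
#'
#' Evaluates every term of the potential for a conformation of a built
#' system: bonded terms from the topology, nonbonded terms over pairs
#' within the cutoff (excluding intramolecular pairs separated by at most
#' `excl_sep` pseudo-residues; intermolecular pairs always interact),
#' Cartesian restraints, and optional umbrella / plane biases.
#'
#' @param system A `cg_system`.
#' @param x Conformation, N x 3 matrix in A. Defaults to the built
#'   coordinates.
#' @param params An `ff_params` object.
#' @param restraints `NULL` or `list(kr = <N vector>, anchors = <N x 3>)`.
#' @param bias `NULL` or a list with optional elements
#'   `umbrella = list(i, j, k, r0)` (1-based bead indices, distance
#'   restraint) and `zplane = list(i, k, z0)`.
#' @param forces Also compute analytic forces?
#' @return A list of class `energy_report`: `terms` (named vector,
#'   kcal/mol), `total`, and `forces` (N x 3, kcal/mol/A) if requested.
#' @export
total_energy_forces <- function(system, x = system$x, params = ff_params(),
                                restraints = NULL, bias = NULL,
                                forces = TRUE) {
  x <- unname(as.matrix(x))
  if (nrow(x) != nrow(system$beads) || ncol(x) != 3) {
    stop("invalid conformation: expected ", nrow(system$beads), " x 3")
  }
  if (any(!is.finite(x))) {
    stop("invalid conformation: NaN/Inf coordinate")
  }
  arr <- .empty_topo_matrices(.sys_arrays(system))
  res <- cpp_energy_forces(
    x, arr$topo, arr$sys, unclass(params),
    .restraint_list(restraints, nrow(x)), .bias_list(bias),
    params$use_dlvo, isTRUE(forces)
  )
  terms <- setNames(as.numeric(res$terms),
                    c("bond", "angle", "torsion", "excluded",
                      "electrostatic", "restraint", "bias"))
  out <- list(terms = terms, total = sum(terms))
  if (isTRUE(forces)) out$forces <- res$forces
  structure(out, class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat("<energy_report> total:", format(x$total, digits = 6), "kcal/mol\n")
  print(round(x$terms, 6))
  invisible(x)
}

#' Measured dihedral angle of four beads
#'
#' Standard atan2 convention: positive for a right-handed rotation of the
#' 3-4 bond relative to the 1-2 bond about the 2-3 axis.
#'
#' @param x 4 x 3 coordinate matrix (or an N x 3 matrix with `idx`).
#' @param idx Four 1-based row indices into `x`.
#' @return Dihedral in radians, in (-pi, pi].
#' @export
dihedral_angle <- function(x, idx = 1:4) {
  x <- as.matrix(x)
  b1 <- x[idx[2], ] - x[idx[1], ]
  b2 <- x[idx[3], ] - x[idx[2], ]
  b3 <- x[idx[4], ] - x[idx[3], ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
         n1[1] * n2[2] - n1[2] * n2[1])
  atan2(sum(m * b2) / sqrt(sum(b2^2)), sum(n1 * n2))
}
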