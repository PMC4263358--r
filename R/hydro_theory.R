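## Analytic layer: rigid-particle bead-model hydrodynamics, the
## Bagchi-Blainey-Xie (BBX) model of rotation-coupled sliding and its
## corrected form, Zwanzig's roughness reduction, the Debye length, and the
## facilitated-diffusion search rate.

.skew <- function(v) {
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
}

#' Rigid-particle translational and rotational diffusion
#'
#' Assembles the grand RPY mobility of the bead model, contracts it to the
#' 6 x 6 rigid-body friction matrix, and inverts to the rigid-body
#' diffusion matrix. The center of diffusion is located as the point
#' minimizing the trace of the translational diffusion block (equivalently,
#' where the translation-rotation coupling block is symmetric); the
#' orientation-averaged D_T is reported there and D_R is one third of the
#' rotational trace. Stokes radii follow from a_T = k_B T/(6 pi eta D_T)
#' and a_R = (k_B T/(8 pi eta D_R))^(1/3).
#'
#' @param x Bead positions, N x 3 in A.
#' @param a Stokes radii, length N, in A.
#' @param temperature Temperature in K.
#' @param eta Viscosity in cP.
#' @return A list of class `rigid_body_hydro` with `D_T` (A^2/ns), `D_R`
#'   (1/ns), `a_T`, `a_R` (A), `cod` (center of diffusion, input frame),
#'   `D6` (the 6 x 6 diffusion matrix at the center of diffusion).
#' @export
rigid_body_diffusion <- function(x, a, temperature = 298,
                                 eta = bd_constants$eta_water) {
  x <- unname(as.matrix(x))
  n <- nrow(x)
  stopifnot(n >= 1, length(a) == n, all(a > 0))
  mobc <- mobility_constant(temperature, eta)

  if (n == 1) {
    DT <- mobc / a[1]
    DR <- (mobc * 6 / 8) / a[1]^3
    return(structure(
      list(D_T = DT, D_R = DR, a_T = a[1], a_R = a[1], cod = as.numeric(x),
           D6 = diag(c(rep(DT, 3), rep(DR, 3)))),
      class = "rigid_body_hydro"))
  }

  D <- cpp_grand_diffusion(x, a, rep(1L, n), 0L, mobc)
  Z <- solve(D)   # friction * kBT^{-1}... (kBT folded into D throughout)
  zb <- function(i, j) Z[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)]

  ## 6x6 friction at a point p, by direct re-summation of pair blocks
  xi_at <- function(p) {
    Xtt <- matrix(0, 3, 3); Xrt <- matrix(0, 3, 3); Xrr <- matrix(0, 3, 3)
    for (i in seq_len(n)) {
      Ai <- .skew(x[i, ] - p)
      for (j in seq_len(n)) {
        z <- zb(i, j)
        Aj <- .skew(x[j, ] - p)
        Xtt <- Xtt + z
        Xrt <- Xrt + Ai %*% z
        Xrr <- Xrr - Ai %*% z %*% Aj
      }
    }
    rbind(cbind(Xtt, t(Xrt)), cbind(Xrt, Xrr))
  }

  ## a collinear point-bead body has no friction for rotation about its
  ## axis; the 6x6 friction is then singular and the free rotation is
  ## projected out with a pseudo-inverse
  d6_at <- function(p) {
    Xi <- xi_at(p)
    sv <- svd(Xi)
    keep <- sv$d > max(sv$d) * 1e-10
    sv$v[, keep, drop = FALSE] %*%
      (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  }
  tr_tt <- function(p) sum(diag(d6_at(p)[1:3, 1:3]))

  ## minimize the translational trace over the shift point
  start <- colSums(x * a) / sum(a)
  opt <- optim(start, tr_tt, method = "BFGS",
               control = list(reltol = 1e-12))
  cod <- opt$par
  D6 <- d6_at(cod)
  DT <- sum(diag(D6[1:3, 1:3])) / 3
  ## rotational average over the resisted axes (a free axis of a collinear
  ## body shows up as a null eigenvalue and is excluded)
  evr <- eigen(D6[4:6, 4:6], symmetric = TRUE, only.values = TRUE)$values
  evr <- evr[evr > max(evr) * 1e-8]
  DR <- mean(evr)
  structure(
    list(D_T = DT, D_R = DR, a_T = mobc / DT,
         a_R = ((mobc * 6 / 8) / DR)^(1 / 3), cod = cod, D6 = D6),
    class = "rigid_body_hydro"
  )
}

#' Rigid-body hydrodynamics of the built CG-protein
#'
#' Convenience wrapper: builds the three-bead protein and reports its
#' rigid-particle diffusion properties and R_OC (distance from the DNA
#' axis, the Z axis in the build frame, to the center of diffusion).
#'
#' @param a_pbp PBP Stokes radius in A.
#' @inheritParams rigid_body_diffusion
#' @return A `rigid_body_hydro` with an extra element `R_OC` (A).
#' @export
protein_hydro <- function(a_pbp = 40, temperature = 298,
                          eta = bd_constants$eta_water) {
  p <- build_protein(a_pbp = a_pbp, q_dbp = 0)
  h <- rigid_body_diffusion(p$x, p$beads$stokes, temperature, eta)
  h$R_OC <- sqrt(sum(h$cod[1:2]^2))
  h
}

#' @export
print.rigid_body_hydro <- function(x, ...) {
  cat(sprintf(
    "<rigid_body_hydro> D_T = %.3f A^2/ns (a_T = %.1f A), D_R = %.4f /ns (a_R = %.1f A)\n",
    x$D_T, x$a_T, x$D_R, x$a_R))
  if (!is.null(x$R_OC)) cat(sprintf("  R_OC = %.1f A\n", x$R_OC))
  invisible(x)
}

#' BBX 1D diffusion coefficient for rotation-coupled sliding
#'
#' D_1D = (k_B T / 6 pi eta) / ( a_pro \[1 + (4/3)(2 pi/pitch)^2 a_pro^2 +
#' (2 pi/pitch)^2 R_OC^2\] ). The three denominator terms are translational
#' friction along the helix axis, rotational friction about it, and the
#' friction of the off-axis circular motion of the center of diffusion.
#' As pitch -> infinity it reduces to the Stokes-Einstein D_3D(a_pro).
#'
#' @param a_pro Protein Stokes radius in A.
#' @param R_OC Distance from the DNA axis to the protein center of
#'   diffusion in A.
#' @param pitch Helix pitch in A (33.8 for the CG model).
#' @param temperature Temperature in K.
#' @param eta Viscosity in cP.
#' @param off_axis Include the off-axis circular term? `FALSE` recovers
#'   Schurr's on-axis model.
#' @return D_1D in A^2/ns.
#' @export
bbx_d1d <- function(a_pro, R_OC, pitch = bd_constants$helix_pitch,
                    temperature = 298, eta = bd_constants$eta_water,
                    off_axis = TRUE) {
  stopifnot(all(a_pro > 0), all(R_OC >= 0), pitch > 0)
  w <- (2 * pi / pitch)^2
  denom <- a_pro * (1 + (4 / 3) * w * a_pro^2 +
                      if (off_axis) w * R_OC^2 else 0)
  mobility_constant(temperature, eta) / denom
}

#' Corrected BBX 1D diffusion using separate Stokes radii
#'
#' Same friction decomposition as [bbx_d1d()], but the rotational term is
#' evaluated with the rotational Stokes radius a_R while the translational
#' and off-axis terms use a_T:
#' D*_1D = (k_B T / 6 pi eta) / ( a_T + (4/3)(2 pi/pitch)^2 a_R^3 +
#' (2 pi/pitch)^2 R_OC^2 a_T ). With a_R = a_T it reduces to [bbx_d1d()].
#'
#' @param a_T Translational Stokes radius in A.
#' @param a_R Rotational Stokes radius in A.
#' @inheritParams bbx_d1d
#' @return D_1D in A^2/ns.
#' @export
bbx_corrected_d1d <- function(a_T, a_R, R_OC,
                              pitch = bd_constants$helix_pitch,
                              temperature = 298,
                              eta = bd_constants$eta_water) {
  stopifnot(all(a_T > 0), all(a_R > 0), all(R_OC >= 0), pitch > 0)
  w <- (2 * pi / pitch)^2
  denom <- a_T + (4 / 3) * w * a_R^3 + w * R_OC^2 * a_T
  mobility_constant(temperature, eta) / denom
}

#' Zwanzig roughness reduction factor
#'
#' Effective-diffusivity reduction on a landscape with Gaussian energy
#' roughness epsilon: exp(-(epsilon/k_B T)^2). At epsilon = 1.1 k_B T the
#' factor is 0.30.
#'
#' @param epsilon_over_kbt Roughness in units of k_B T (>= 0).
#' @return Dimensionless factor in (0, 1].
#' @export
zwanzig_reduction <- function(epsilon_over_kbt) {
  stopifnot(all(epsilon_over_kbt >= 0))
  exp(-epsilon_over_kbt^2)
}

#' Debye screening length of a 1:1 electrolyte
#'
#' 1/kappa = sqrt(eps eps0 k_B T / (2 N_A e^2 I)), returned in A; 7.8 A at
#' 0.15 M NaCl, 298 K, eps = 78.5.
#'
#' @param ionic_strength Ionic strength in mol/L (> 0).
#' @param temperature Temperature in K.
#' @param eps Relative dielectric constant.
#' @return Debye length in A.
#' @export
debye_length <- function(ionic_strength, temperature = 298, eps = 78.5) {
  stopifnot(all(ionic_strength > 0))
  eps0 <- 8.8541878128e-12                        # F/m
  e <- 1.602176634e-19                            # C
  I <- ionic_strength * 1000 * bd_constants$NA_SI # ions/m^3 per species
  sqrt(eps * eps0 * bd_constants$kB_SI * temperature / (2 * I * e^2)) * 1e10
}

#' Facilitated-diffusion association rate
#'
#' k_Smol = 4 pi D_3D b f N_A with b = 3.4 A; sliding length
#' nbar = sqrt(c D_1D tau_1D)/b (prefactor c = 2 by default, the 1D
#' mean-squared-displacement convention); and
#' k_s = k_Smol nbar tau_3D / (tau_1D + tau_3D). For fixed D_1D the rate
#' is maximal at tau_1D = tau_3D.
#'
#' @param D_3D 3D diffusion coefficient in cm^2/s.
#' @param D_1D 1D sliding diffusion coefficient in cm^2/s.
#' @param tau_1D,tau_3D Mean durations of a 1D scan and a 3D excursion, s.
#' @param f Reactive fraction of the protein surface.
#' @param c_slide Sliding-length prefactor.
#' @return A list with `k_smol` and `k_s` (1/M/s) and `n_bar` (bp).
#' @export
search_rate <- function(D_3D, D_1D, tau_1D, tau_3D, f = 0.3, c_slide = 2) {
  stopifnot(D_3D > 0, D_1D >= 0, tau_1D >= 0, tau_3D > 0, f > 0)
  b_cm <- bd_constants$bp_rise * 1e-8
  ## 4 pi D b f gives cm^3/s per molecule; x N_A / 1000 -> 1/M/s
  k_smol <- 4 * pi * D_3D * b_cm * f * bd_constants$NA_SI / 1000
  n_bar <- sqrt(c_slide * D_1D * tau_1D) / b_cm
  k_s <- k_smol * n_bar * tau_3D / (tau_1D + tau_3D)
  list(k_smol = k_smol, n_bar = n_bar, k_s = k_s)
}

#' Analytic sliding table for a set of protein sizes
#'
#' Combines rigid-particle theory with the BBX expressions to reproduce
#' the model's diffusive-property table: D_3D, a_T, a_R, R_OC, and the
#' plain and corrected theoretical D_1D for each PBP Stokes radius.
#'
#' @param a_pbp Vector of PBP Stokes radii in A.
#' @inheritParams rigid_body_diffusion
#' @return A data.frame.
#' @export
sliding_theory_table <- function(a_pbp = c(30, 40, 50), temperature = 298,
                                 eta = bd_constants$eta_water) {
  rows <- lapply(a_pbp, function(ap) {
    h <- protein_hydro(ap, temperature, eta)
    data.frame(
      a_pbp = ap, a_T = h$a_T, a_R = h$a_R, D_3D = h$D_T, R_OC = h$R_OC,
      D_1D_theory = bbx_d1d(h$a_T, h$R_OC, temperature = temperature,
                            eta = eta),
      D_1D_theory_corr = bbx_corrected_d1d(h$a_T, h$a_R, h$R_OC,
                                           temperature = temperature,
                                           eta = eta)
    )
  })
  do.call(rbind, rows)
}
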