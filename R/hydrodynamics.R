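## Configuration-dependent hydrodynamic interactions: Rotne-Prager-Yamakawa
## pairwise mobility, the 3N x 3N grand diffusion matrix, and correlated
## Brownian displacements satisfying the fluctuation-dissipation theorem.

#' RPY diffusion tensor block for a bead pair
#'
#' Self block (i = j): (k_B T / 6 pi eta a) I. Far field
#' (r >= a_i + a_j): (k_B T / 8 pi eta r) \[(1 + (a_i^2 + a_j^2)/3r^2) I +
#' (1 - (a_i^2 + a_j^2)/r^2) rhat rhat\]. Overlapping pairs use the
#' positive-definite equal-sphere overlap form evaluated at the effective
#' radius abar = sqrt((a_i^2 + a_j^2)/2).
#'
#' @param r_i,r_j Bead positions (length-3, A). Pass `r_j = NULL` for the
#'   self block.
#' @param a_i,a_j Stokes radii in A.
#' @param temperature Temperature in K.
#' @param eta Viscosity in cP.
#' @return A 3 x 3 matrix in A^2/ns.
#' @export
rpy_block <- function(r_i, r_j = NULL, a_i, a_j = a_i, temperature = 298,
                      eta = bd_constants$eta_water) {
  mobc <- mobility_constant(temperature, eta)
  if (is.null(r_j)) return(diag(3) * mobc / a_i)
  d <- as.numeric(r_i) - as.numeric(r_j)
  r <- sqrt(sum(d^2))
  if (r < 1e-12) stop("singular geometry: coincident distinct beads")
  rh <- d / r
  P <- outer(rh, rh)
  if (r >= a_i + a_j) {
    s2 <- (a_i^2 + a_j^2) / r^2
    (mobc * 6 / (8 * r)) * ((1 + s2 / 3) * diag(3) + (1 - s2) * P)
  } else {
    ab <- sqrt((a_i^2 + a_j^2) / 2)
    (mobc / ab) * ((1 - 9 * r / (32 * ab)) * diag(3) + (3 * r / (32 * ab)) * P)
  }
}

#' Grand diffusion matrix of a system conformation
#'
#' Builds the dense symmetric 3N x 3N RPY diffusion matrix. Modes:
#' `full_hi` populates all blocks, `intra_hi` zeroes blocks between beads
#' of different molecules, `free_draining` keeps only the Stokes-Einstein
#' self blocks.
#'
#' @param system A `cg_system`.
#' @param x Conformation (N x 3); defaults to the built coordinates.
#' @param mode One of `"full_hi"`, `"intra_hi"`, `"free_draining"`.
#' @param temperature Temperature in K.
#' @param eta Viscosity in cP.
#' @param check Verify positive definiteness (Cholesky); on failure a
#'   matrix-construction error reports the minimum eigenvalue.
#' @return A 3N x 3N matrix (A^2/ns) with attributes `mode` and `mobc`.
#' @export
grand_matrix <- function(system, x = system$x,
                         mode = c("full_hi", "intra_hi", "free_draining"),
                         temperature = 298, eta = bd_constants$eta_water,
                         check = FALSE) {
  mode <- match.arg(mode)
  x <- unname(as.matrix(x))
  if (any(!is.finite(x))) stop("invalid conformation: NaN/Inf coordinate")
  midx <- c(full_hi = 0L, intra_hi = 1L, free_draining = 2L)[[mode]]
  D <- cpp_grand_diffusion(x, system$beads$stokes,
                           as.integer(system$beads$molecule), midx,
                           mobility_constant(temperature, eta))
  if (isTRUE(check)) {
    ok <- tryCatch({ chol(D); TRUE }, error = function(e) FALSE)
    if (!ok) {
      stop("matrix construction error: diffusion matrix not positive ",
           "definite (min eigenvalue ",
           format(min(eigen(D, symmetric = TRUE,
                            only.values = TRUE)$values), digits = 4), ")")
    }
  }
  attr(D, "mode") <- mode
  attr(D, "mobc") <- mobility_constant(temperature, eta)
  D
}

#' Correlated Brownian displacement draw
#'
#' Returns L z with L the lower Cholesky factor of 2 D dt and z standard
#' normal, i.e. a displacement with covariance 2 D dt. Reproducible under
#' `set.seed()`.
#'
#' @param D Grand diffusion matrix (A^2/ns).
#' @param dt Time step in ps.
#' @return A 3N displacement vector in A.
#' @export
correlated_displacement <- function(D, dt) {
  dtns <- dt / 1000
  L <- tryCatch(t(chol(2 * D * dtns)), error = function(e) {
    stop("matrix construction error: Cholesky factorization failed (",
         conditionMessage(e), ")")
  })
  as.numeric(L %*% rnorm(nrow(D)))
}
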