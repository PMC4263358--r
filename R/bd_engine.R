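## Brownian dynamics propagation: second-order Runge-Kutta scheme with the
## same noise realization in predictor and corrector, and the diffusion
## matrix (with its Cholesky factor) frozen between periodic refreshes.

#' Simulation protocol
#'
#' Reference conditions: dt = 0.25 ps, diffusion tensor and Cholesky factor
#' refreshed every 200 steps, samples every 10,000 steps (2.5 ns),
#' T = 298 K. `dna_mode` selects the DNA treatment: `"restrained"` anchors
#' every DNA bead with k_r = 1 kcal/mol/A^2, `"flexible"` anchors only the
#' two terminal PP+PB pairs at each end with k_r = 0.01, `"none"` applies
#' no DNA restraints.
#'
#' @param n_steps Number of BD steps.
#' @param dt Time step in ps.
#' @param tensor_update Steps between diffusion-tensor refreshes.
#' @param sample_interval Steps between stored samples.
#' @param hi_mode Hydrodynamic mode, see [grand_matrix()].
#' @param dna_mode `"restrained"`, `"flexible"` or `"none"`.
#' @param temperature Temperature in K.
#' @param seed RNG seed (`NULL` = leave the RNG stream alone).
#' @param max_disp Per-step displacement sanity bound in A; exceeding it
#'   aborts with a blow-up error reporting the step.
#' @return A list of class `bd_protocol`.
#' @export
bd_protocol <- function(n_steps, dt = 0.25, tensor_update = 200,
                        sample_interval = 10000,
                        hi_mode = c("full_hi", "intra_hi", "free_draining"),
                        dna_mode = c("restrained", "flexible", "none"),
                        temperature = 298, seed = NULL, max_disp = 5) {
  stopifnot(dt > 0, n_steps >= 1, tensor_update >= 1, sample_interval >= 1)
  structure(
    list(n_steps = as.integer(n_steps), dt = dt,
         tensor_update = as.integer(tensor_update),
         sample_interval = as.integer(sample_interval),
         hi_mode = match.arg(hi_mode), dna_mode = match.arg(dna_mode),
         temperature = temperature, seed = seed, max_disp = max_disp),
    class = "bd_protocol"
  )
}

#' DNA restraints for a protocol's dna_mode
#'
#' @param system A `cg_system` whose molecule 1 is the DNA.
#' @param dna_mode `"restrained"`, `"flexible"` or `"none"`.
#' @param anchors Anchor coordinates (defaults to the current build).
#' @return `list(kr, anchors)` suitable for [total_energy_forces()].
#' @export
dna_restraints <- function(system, dna_mode, anchors = system$x) {
  n <- nrow(system$beads)
  kr <- numeric(n)
  dna <- which(system$beads$molecule == 1L)
  if (dna_mode == "restrained") {
    kr[dna] <- 1
  } else if (dna_mode == "flexible") {
    res <- system$beads$residue[dna]
    term <- dna[res <= 1 | res >= max(res) - 1]   # two residues each end
    kr[term] <- 0.01
  }
  list(kr = kr, anchors = unname(as.matrix(anchors)))
}

#' One second-order Runge-Kutta BD step (reference implementation)
#'
#' Predictor x* = x + (dt/k_B T) D F(x) + S with S ~ N(0, 2 D dt);
#' corrector x' = x + (dt/2 k_B T) D (F(x) + F(x*)) + S, with the same S
#' and the same D in both stages. This R-level single step backs unit
#' tests; production runs use the compiled loop in [run_simulation()].
#'
#' @param x N x 3 conformation in A.
#' @param D Grand diffusion matrix (A^2/ns).
#' @param forces_fn Function x -> N x 3 forces in kcal/mol/A.
#' @param dt Time step in ps.
#' @param temperature Temperature in K.
#' @param S Optional 3N noise vector (A); drawn from 2 D dt if missing.
#' @return Updated N x 3 conformation.
#' @export
rk2_step <- function(x, D, forces_fn, dt, temperature = 298, S = NULL) {
  x <- unname(as.matrix(x))
  n <- nrow(x)
  dtns <- dt / 1000
  kT <- kbt(temperature)
  if (is.null(S)) S <- correlated_displacement(D, dt)
  S <- matrix(S, n, 3, byrow = TRUE)
  f1 <- forces_fn(x)
  drift1 <- matrix(D %*% as.numeric(t(f1)), n, 3, byrow = TRUE)
  xs <- x + (dtns / kT) * drift1 + S
  f2 <- forces_fn(xs)
  drift2 <- matrix(D %*% as.numeric(t(f1 + f2)), n, 3, byrow = TRUE)
  x + (dtns / (2 * kT)) * drift2 + S
}

#' Run a Brownian dynamics simulation
#'
#' Propagates the system under the given protocol, applying the DNA
#' restraint mode (anchors captured from the initial conformation),
#' refreshing the diffusion tensor and its Cholesky factor every
#' `tensor_update` steps, and sampling coordinates and energies every
#' `sample_interval` steps (the initial frame is stored too). Identical
#' seed and protocol give bit-identical trajectories on one platform.
#'
#' @param system A `cg_system`.
#' @param protocol A `bd_protocol`.
#' @param params An `ff_params`.
#' @param bias Optional bias list, see [total_energy_forces()].
#' @param x0 Starting conformation (defaults to the build).
#' @param restraints Optional explicit restraints overriding `dna_mode`.
#' @param eta Viscosity in cP.
#' @return A list of class `bd_trajectory`: `times` (ns), `coords`
#'   (N x 3 x frames array), `energies` (frames x 8 matrix), `final`,
#'   `protocol`, `system`.
#' @export
run_simulation <- function(system, protocol, params = ff_params(),
                           bias = NULL, x0 = system$x, restraints = NULL,
                           eta = bd_constants$eta_water) {
  x0 <- unname(as.matrix(x0))
  if (nrow(x0) != nrow(system$beads)) {
    stop("invalid conformation: bead count mismatch")
  }
  if (any(!is.finite(x0))) stop("invalid conformation: NaN/Inf coordinate")
  if (!is.null(protocol$seed)) set.seed(protocol$seed)
  if (is.null(restraints)) {
    restraints <- dna_restraints(system, protocol$dna_mode, x0)
  }
  arr <- .empty_topo_matrices(.sys_arrays(system))
  midx <- c(full_hi = 0L, intra_hi = 1L,
            free_draining = 2L)[[protocol$hi_mode]]
  res <- cpp_run_bd(
    x0, arr$topo, arr$sys, unclass(params),
    .restraint_list(restraints, nrow(x0)), .bias_list(bias),
    params$use_dlvo, midx, protocol$dt / 1000, protocol$n_steps,
    protocol$tensor_update, protocol$sample_interval,
    kbt(protocol$temperature),
    mobility_constant(protocol$temperature, eta), protocol$max_disp
  )
  traj <- structure(
    list(times = as.numeric(res$times), coords = res$coords,
         energies = `colnames<-`(res$energies,
                                 c("bond", "angle", "torsion", "excluded",
                                   "electrostatic", "restraint", "bias",
                                   "total")),
         final = res$final, protocol = protocol, system = system),
    class = "bd_trajectory"
  )
  if (res$blowup_step > 0) {
    cond <- simpleError(paste0(
      "blow-up error: per-step displacement exceeded ", protocol$max_disp,
      " A at step ", res$blowup_step,
      " (trajectory so far attached as condition$trajectory)"))
    cond$trajectory <- traj
    stop(cond)
  }
  traj
}

#' @export
print.bd_trajectory <- function(x, ...) {
  cat("<bd_trajectory>", dim(x$coords)[3], "frames,",
      dim(x$coords)[1], "beads,",
      format(max(x$times), digits = 4), "ns",
      sprintf("(%s, %s DNA)\n", x$protocol$hi_mode, x$protocol$dna_mode))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `bd_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]
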