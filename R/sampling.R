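## Equilibrium Metropolis Monte Carlo samplers targeting the identical
## potential as the BD engine: a pivot-move sampler for DNA chain
## conformations and a protein/DNA move set for umbrella windows. These
## give equilibrium averages (PMFs, chain statistics) much faster than BD;
## equilibrium properties are independent of the hydrodynamic mode.

#' Equilibrium pivot-MC sampling of CG-DNA conformations
#'
#' Samples the flexible chain by pivot moves: all residues beyond a random
#' pivot residue are rotated rigidly about a random axis through its PB
#' bead. Only the two bending terms and the torsion straddling the pivot
#' change, so moves are cheap and the chain decorrelates in a few sweeps.
#'
#' By default (`bending_only = TRUE`) the move energetics contain only the
#' PB-PB-PB bending term, i.e. the ensemble is the discrete worm-like
#' chain whose persistence length the bending stiffness parameterizes
#' (Lp = k b / k_B T). With `bending_only = FALSE` the full bonded
#' potential acts; the phosphate-anchoring 90-degree angles and the
#' backbone torsion then stiffen bending anisotropically and the measured
#' Lp comes out roughly a third larger. Screened electrostatic
#' self-repulsion of the PP track can additionally be switched on.
#'
#' @param dna A `dna_model`.
#' @param n_sweeps MC sweeps (one sweep = n_residues - 2 pivot attempts).
#' @param n_equil Discarded equilibration sweeps.
#' @param sample_every Sweeps between stored samples.
#' @param max_angle Maximum pivot rotation in degrees.
#' @param bending_only Restrict the energetics to the backbone bending
#'   term (see above).
#' @param include_nonbonded Include excluded-volume + electrostatic terms.
#' @param params An `ff_params` (only used when `include_nonbonded`).
#' @param temperature Temperature in K.
#' @param seed RNG seed (`NULL` = leave the stream alone).
#' @return A list of class `dna_ensemble`: `pb_frames` (n_residues x 3 x
#'   n_samples array of PB positions), `final` (full coordinates),
#'   `acceptance`.
#' @export
sample_dna_conformations <- function(dna, n_sweeps = 800, n_equil = 100,
                                     sample_every = 2, max_angle = 10,
                                     bending_only = TRUE,
                                     include_nonbonded = FALSE,
                                     params = ff_params(),
                                     temperature = 298, seed = NULL) {
  stopifnot(inherits(dna, "dna_model"), n_sweeps > n_equil)
  if (!is.null(seed)) set.seed(seed)
  arr <- .empty_topo_matrices(.sys_arrays(dna))
  res <- cpp_pivot_mc(
    unname(dna$x), dna$n_residues, arr$topo, arr$sys, unclass(params),
    params$use_dlvo, isTRUE(include_nonbonded), isTRUE(bending_only),
    as.integer(n_sweeps), as.integer(sample_every), as.integer(n_equil),
    max_angle * pi / 180, kbt(temperature)
  )
  structure(
    list(pb_frames = res$pb_frames, final = res$final,
         acceptance = res$acceptance, n_residues = dna$n_residues,
         rise = bd_constants$residue_rise),
    class = "dna_ensemble"
  )
}

#' @export
print.dna_ensemble <- function(x, ...) {
  cat("<dna_ensemble>", dim(x$pb_frames)[3], "conformations of",
      x$n_residues, "residues (acceptance",
      sprintf("%.2f)\n", x$acceptance))
  invisible(x)
}

## internal: one umbrella window by Metropolis MC
.umbrella_mc_window <- function(x0, arr, params, restraints, bias,
                                protein_beads, n_sweeps, n_equil,
                                sample_every, temperature, move_dna) {
  cpp_umbrella_mc(
    unname(x0), arr$topo, arr$sys, unclass(params),
    restraints, .bias_list(bias), params$use_dlvo,
    as.integer(protein_beads) - 1L,
    as.integer(n_sweeps), as.integer(n_equil), as.integer(sample_every),
    0.6, 0.8, 0.25, isTRUE(move_dna), kbt(temperature)
  )
}
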