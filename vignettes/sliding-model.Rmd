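---
title: "A coarse-grained Brownian-dynamics model of protein sliding along DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coarse-grained Brownian-dynamics model of protein sliding along DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdslide)
```

## The model

DNA-binding proteins locate their targets by facilitated diffusion:
three-dimensional excursions through solution alternate with
one-dimensional sliding along non-specifically bound DNA. Because DNA is
helical, a sliding protein that tracks the phosphate backbone must corkscrew
around the helix axis, and hydrodynamic theory (the Schurr and
Bagchi–Blainey–Xie models) predicts that this rotation-coupled motion
suppresses the apparent 1D diffusion coefficient by roughly two orders of
magnitude relative to free 3D diffusion. `bdslide` implements a
coarse-grained bead model designed to probe what that theory leaves out:
hydrodynamic coupling between the protein and the DNA, DNA flexibility, and
binding-strength-dependent hopping.

**Geometry.** One pseudo-residue per base pair: a pseudo-backbone bead (PB,
Stokes radius 7 Å) on the helix axis every 3.38 Å, and a pseudo-phosphate
bead (PP, excluded-volume radius 10.4 Å, Stokes radius 7 Å, effective charge
−2) at 8.973 Å radial distance, advancing 36° per residue (pitch 33.8 Å,
right-handed). The protein is three beads: a neutral protein-body bead (PBP,
excluded-volume radius 27.6 Å, Stokes radius 30/40/50 Å) whose center sits
47 Å off-axis, and two DNA-binding beads (DBP, radius 6 Å, Stokes radius
8 Å, charge `q_dbp`) on the phosphate-track radius, offset ±16.9 Å axially,
so the PBP–DBP bonds (41.59 Å) and DBP–DBP bond (33.8 Å) close exactly.

**Potential.** Harmonic bonds, angles and torsions (all ½·k conventions;
`build_dna()` carries the parameter tables), a half-harmonic excluded-volume
term ½k_ex(σ_i+σ_j−r)² and screened DLVO (Yukawa) electrostatics

V = (C/ε)\,q_i q_j \frac{e^{κa_i}}{1+κa_i}\frac{e^{κa_j}}{1+κa_j}
\frac{e^{-κr}}{r}

with ε = 78.5, Debye length 1/κ = 7.8 Å (0.15 M 1:1 salt at 298 K), plain
truncation at 40 Å, and intramolecular pairs within 4 pseudo-residues
excluded. Bare Debye–Hückel screening (`ff_params(use_dlvo = FALSE)`) is
available for comparison.

**Dynamics.** The grand diffusion matrix is built from the
Rotne–Prager–Yamakawa tensor (positive definite for all configurations;
overlapping unequal spheres use the equal-sphere overlap form at the
effective radius ā = √((a_i²+a_j²)/2)); propagation uses the second-order
Runge–Kutta (predictor–corrector) Brownian-dynamics scheme with the same
noise realization in both stages, D and its Cholesky factor refreshed every
200 steps, Δt = 0.25 ps, T = 298 K, η = 0.89 cP. The RPY divergence
vanishes, so no spurious-drift term is needed. Hydrodynamic modes:
`full_hi`, `intra_hi` (intermolecular blocks zeroed), `free_draining`.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `q_dbp` | 8 | DBP effective charge (e); sets the binding affinity |
| `a_pbp` | 40 Å | protein-body Stokes radius; sets protein size |
| `dt` | 0.25 ps | BD time step |
| `tensor_update` | 200 steps | diffusion-tensor refresh interval |
| `k_umb`, windows | 5 kcal/mol/Å², r₀ = 90…31 Å | umbrella protocol |
| `kex` | 1 kcal/mol/Å² | excluded-volume stiffness |
| `theta0_pb` | 180° | backbone bending reference angle |

The angle stiffness 87.7 kcal/mol at bond length 3.38 Å encodes the B-DNA
persistence length through Lp = k·b/k_BT = 500 Å. A published table lists
32.7° for the backbone equilibrium angle; a bent reference angle cannot
reproduce a straight ground state with a 50-nm persistence length, so we
treat it as an erratum, default to 180°, and expose `theta0_pb` for
exact-replication experiments.

## Numerical choices and their rationale

**Time step and stiff modes.** With hydrodynamic interactions the reference
Δt = 0.25 ps samples the Boltzmann distribution correctly: bonded
neighbours overlap hydrodynamically (a = 7 Å, r = 3.38 Å), their mobilities
are strongly correlated, and the relative mobility of stiff bonded modes is
small. In the free-draining mode that correlation is absent and the same
time step overheats the stiffest angle modes (we measure ~3× equipartition
energy); free-draining runs that feed equilibrium estimates should use
Δt ≤ 0.1 ps. Equilibrium-sensitive results in this package therefore come
either from HI dynamics at 0.25 ps, from free-draining BD at ≤ 0.1 ps, or
from the Metropolis samplers, which are discretization-free.

**Equilibrium Monte Carlo samplers.** Two MC move sets target the identical
potential: a pivot sampler for DNA chain statistics and a protein/DNA move
set for umbrella windows (equilibrium averages are independent of the
hydrodynamic mode, which justifies replacing BD windows with MC). Umbrella
sweeps perform six rounds of protein moves (rigid translation, rigid
rotation, per-bead displacements) per DNA sweep because the bound-state
orientation is the slow degree of freedom; with less protein sampling the
descending window chain shows 1–2 kcal/mol of hysteresis between seeds.

**Persistence length.** The pivot sampler defaults to `bending_only = TRUE`:
the ensemble is then the discrete worm-like chain whose persistence length
the PB–PB–PB stiffness parameterizes, and the tangent-correlation fit
recovers 500 Å. With the full bonded potential the 90° phosphate-anchoring
angles and the torsion stiffen bending anisotropically and the chain
measures Lp ≈ 680–700 Å — a property of the decorated model worth knowing
when comparing to experiment.

**WHAM.** Bin width 0.5 Å, offsets iterated to 10⁻⁶ kcal/mol. The PMF is
anchored at its minimum; the binding free energy is the mean PMF over the
80–90 Å plateau (no standard-state correction), with a Boltzmann-integrated
well-depth estimator available for comparison. The reaction coordinate is
the 3D distance from the PBP bead to the PB bead nearest the origin; with
the PBP confined to the Z = 0 plane (k = 1 kcal/mol/Å²) it is effectively
the in-plane separation.

**Initial placements.** The canonical groove pose puts the DBP beads on the
phosphate-track radius, where they nominally overlap the PP excluded-volume
radii; the half-harmonic term resolves this within picoseconds. Because the
screened-Coulomb attraction diverges as 1/r while the excluded-volume
penalty stays finite, the pair potential is only metastable: for
q(DBP) ≳ 15 the canonical pose sits inside the inward collapse barrier, so
bound sliding runs start from a pose retracted 12 Å radially, which relaxes
into the bound state immediately.

**Degenerate geometry.** Angle forces use a guarded small-angle branch near
collinearity; dihedrals with collinear triples raise a singular-geometry
error; rigid-body theory projects out the free rotation axis of collinear
bead arrangements with a pseudo-inverse.

## What the synthetic systems do and do not emulate

The builders generate ideal B-form helices with identical residues: no
sequence, no groove asymmetry, no supercoiling, and the protein has no
internal elasticity beyond its three soft bonds. Electrostatics is a
uniform-dielectric screened monopole model. Consequently the package's
validations demonstrate correctness of the mechanics (integrators, samplers,
estimators, hydrodynamic theory) and reproduce this model family's published
analytic tables; they do not demonstrate sequence-specific energetics or
atomistic binding geometry, and free-energy roughness from sequence is
represented only through the analytic Zwanzig reduction factor.

## Problem sizes used in the shipped checks

Scaled-down study conditions keep every check on a single desktop core: the
persistence length uses the full 200-residue chain (pivot MC, ~2000 sweeps);
umbrella sampling uses a 60-bp restrained segment with the full 60-window
ladder and ~4000 MC sweeps per window; the sliding-ordering comparison uses
a 26-bp segment with 300–400-ns matched-seed BD runs at q(DBP) = 20 instead
of the 200-bp, 25-µs, ten-replica production protocol, measuring the
apparent diffusion of the protein's axis-projected sliding coordinate
(`sliding_coordinate()`), which removes rigid-body wobble of the short
flexible chain. The full-scale tables are represented by orderings and
bands at this reduced scale.

## Known limitations

* The binding free energy at q(DBP) = 8 converges to ≈ 8.5 kcal/mol under
  this reconstruction of the interaction terms, above the ≈ 5.7 kcal/mol
  reported for the reference parameterization; the discrepancy is analyzed
  in the repository notes and appears tied to the excluded-volume contact
  convention of the original (the published q-dependence implies closer
  protein–phosphate approach than an additive σ_i+σ_j contact permits).
  The model's qualitative affinity ordering (monotone in q, restrained ≥
  flexible) is unaffected.
* Dense-matrix hydrodynamics limits systems to a few hundred beads; no
  fast HI solvers, lubrication corrections or wall effects.
* Apparent 1D diffusion estimates at reduced duration carry large
  statistical error; orderings are robust, absolute values are not.

## A compact session

```{r, eval = FALSE}
sys <- assemble_system(build_dna(60), build_protein(a_pbp = 40, q_dbp = 20),
                       radial_offset = 12)
tr <- run_simulation(sys, bd_protocol(n_steps = 4e5, hi_mode = "intra_hi",
                                      dna_mode = "restrained", seed = 1))
apparent_d1d(msd_1d(tr, which(sys$beads$name == "PBP"), 3),
             fit_window = c(5, 40))

sliding_theory_table(c(30, 40, 50))
```
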