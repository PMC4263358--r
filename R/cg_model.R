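## Coarse-grained DNA and protein model builders.
##
## The model uses four bead types. DNA: one pseudo-residue per base pair,
## each made of a pseudo-phosphate (PP) bead on the B-form phosphate track
## and a pseudo-backbone (PB) bead on the helix axis. Protein: one protein
## body (PBP) bead plus two DNA-binding (DBP) beads.

#' Default bead specifications
#'
#' Excluded-volume radii (sigma), Stokes radii and effective charges of the
#' four bead types. The PBP Stokes radius is a model parameter (30, 40 or
#' 50 A); its excluded-volume radius is fixed at 27.6 A. The DBP charge is
#' the binding-affinity control parameter.
#'
#' @return A data.frame with columns `name`, `sigma`, `stokes`, `charge`.
#' @export
bead_table <- function() {
  data.frame(
    name   = c("PP", "PB", "PBP", "DBP"),
    sigma  = c(10.4, 2.5, 27.6, 6),
    stokes = c(7, 7, 40, 8),
    charge = c(-2, 0, 0, 8),
    stringsAsFactors = FALSE
  )
}

## Geometric constants of the helix (B-form, one residue per bp)
.dna_geom <- list(
  rise      = 3.38,    # PB-PB spacing along the axis, A
  pp_radius = 8.973,   # radial distance of the phosphate track, A
  twist     = 36       # degrees per residue (pitch 33.8 A over 10 residues)
)

.deg2rad <- function(x) x * pi / 180

## residue z coordinates, geometric center at the origin
.residue_z <- function(n) (seq_len(n) - 1 - (n - 1) / 2) * .dna_geom$rise

#' Build an ideal B-form CG-DNA molecule
#'
#' Constructs `n_residues` pseudo-residues: PB beads on the Z axis spaced
#' 3.38 A apart and PP beads at radial distance 8.973 A, rotating 36 degrees
#' per residue (right-handed). The geometric center is at the origin. Bead
#' order is PP(1), PB(1), PP(2), PB(2), ...
#'
#' The PB backbone bending term defaults to a straight equilibrium angle
#' (180 degrees), for which the stated stiffness of 87.7 kcal/mol reproduces
#' a 50 nm persistence length and the ideal helix is the energy minimum.
#' `theta0_pb` exposes the alternative published value (32.7 degrees) for
#' exact-replication runs, but that value is inconsistent with a straight
#' ground state and is treated as a suspected erratum.
#'
#' @param n_residues Number of pseudo-residues (one per base pair), >= 3.
#' @param theta0_pb Equilibrium PB-PB-PB bending angle in degrees.
#' @param temperature Temperature in K (enters the stiff-bond force
#'   constants, 100 k_B T / r0^2).
#' @return An object of class `dna_model` (and `cg_system`).
#' @export
build_dna <- function(n_residues, theta0_pb = 180, temperature = 298) {
  if (!is.numeric(n_residues) || length(n_residues) != 1 ||
      n_residues != round(n_residues) || n_residues < 3) {
    stop("invalid model: n_residues must be an integer >= 3 ",
         "(angle and torsion terms are undefined otherwise)")
  }
  n <- as.integer(n_residues)
  kT <- kbt(temperature)
  g <- .dna_geom

  z   <- .residue_z(n)
  phi <- .deg2rad(g$twist) * (seq_len(n) - 1)

  ## interleaved bead order: PP(a) = 2a-1, PB(a) = 2a  (1-based)
  x <- matrix(0, 2 * n, 3)
  ipp <- 2 * seq_len(n) - 1
  ipb <- 2 * seq_len(n)
  x[ipp, 1] <- g$pp_radius * cos(phi)
  x[ipp, 2] <- g$pp_radius * sin(phi)
  x[ipp, 3] <- z
  x[ipb, 3] <- z

  bt <- bead_table()
  beads <- data.frame(
    name     = rep(c("PP", "PB"), n),
    sigma    = rep(bt$sigma[1:2], n),
    stokes   = rep(bt$stokes[1:2], n),
    charge   = rep(c(-2, 0), n),
    molecule = 1L,
    residue  = rep(seq_len(n) - 1L, each = 2L),
    stringsAsFactors = FALSE
  )

  ## Bonds: PP(a)-PB(a) and PB(a)-PB(a+1), k = 100 kT / r0^2
  b1 <- data.frame(i = ipp, j = ipb,
                   k = 100 * kT / g$pp_radius^2, r0 = g$pp_radius)
  b2 <- data.frame(i = ipb[-n], j = ipb[-1],
                   k = 100 * kT / g$rise^2, r0 = g$rise)
  bonds <- rbind(b1, b2)

  ## Angles: PP(a)-PB(a)-PB(a+1) and PB(a)-PB(a+1)-PP(a+1) at 90 deg,
  ## k = 100 kcal/mol; PB(a-1)-PB(a)-PB(a+1) at theta0_pb, k = 87.7.
  a1 <- data.frame(i = ipp[-n], j = ipb[-n], k = ipb[-1],
                   ka = 100, theta0 = .deg2rad(90))
  a2 <- data.frame(i = ipb[-n], j = ipb[-1], k = ipp[-1],
                   ka = 100, theta0 = .deg2rad(90))
  a3 <- data.frame(i = ipb[seq_len(n - 2)], j = ipb[seq_len(n - 2) + 1],
                   k = ipb[seq_len(n - 2) + 2],
                   ka = 87.7, theta0 = .deg2rad(theta0_pb))
  angles <- rbind(a1, a2, a3)

  ## Torsions: PP(a)-PB(a)-PB(a+1)-PP(a+1) at +36 deg (right-handed)
  torsions <- data.frame(i = ipp[-n], j = ipb[-n],
                         k = ipb[-1], l = ipp[-1],
                         kt = 131.6, phi0 = .deg2rad(g$twist))

  structure(
    list(x = x, beads = beads, bonds = bonds, angles = angles,
         torsions = torsions, n_residues = n,
         meta = list(theta0_pb = theta0_pb, temperature = temperature)),
    class = c("dna_model", "cg_system")
  )
}

#' Build the three-bead CG-protein
#'
#' One PBP bead at 47 A from the (eventual) DNA axis and two DBP beads on
#' the phosphate-track radius (8.973 A) at the same azimuth, offset +-16.9 A
#' axially, so that the PBP-DBP bond (41.59 A) and DBP-DBP bond (33.8 A)
#' are satisfied by construction. Bonds use k = 1 kcal/mol/A^2. The protein
#' is built in its own frame with the DNA axis convention (axis = Z,
#' protein azimuth along +X).
#'
#' @param a_pbp Stokes radius of the PBP bead in A (30, 40 or 50 in the
#'   reference parameterization).
#' @param q_dbp Effective charge of each DBP bead in units of e.
#' @return An object of class `protein_model` (and `cg_system`).
#' @export
build_protein <- function(a_pbp = 40, q_dbp = 8) {
  if (!is.numeric(a_pbp) || length(a_pbp) != 1 || !is.finite(a_pbp) ||
      a_pbp <= 0) {
    stop("invalid model: a_pbp must be a positive finite Stokes radius")
  }
  if (!is.numeric(q_dbp) || length(q_dbp) != 1 || !is.finite(q_dbp)) {
    stop("invalid model: q_dbp must be a finite charge")
  }
  g <- .dna_geom
  x <- rbind(
    c(47, 0, 0),                 # PBP
    c(g$pp_radius, 0,  16.9),    # DBP, +z
    c(g$pp_radius, 0, -16.9)     # DBP, -z
  )
  bt <- bead_table()
  beads <- data.frame(
    name     = c("PBP", "DBP", "DBP"),
    sigma    = c(bt$sigma[3], 6, 6),
    stokes   = c(a_pbp, 8, 8),
    charge   = c(0, q_dbp, q_dbp),
    molecule = 1L,
    residue  = 0:2,
    stringsAsFactors = FALSE
  )
  bonds <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                      k = 1, r0 = c(41.59, 41.59, 33.8))
  structure(
    list(x = x, beads = beads, bonds = bonds,
         angles = data.frame(i = integer(), j = integer(), k = integer(),
                             ka = numeric(), theta0 = numeric()),
         torsions = data.frame(i = integer(), j = integer(), k = integer(),
                               l = integer(), kt = numeric(),
                               phi0 = numeric()),
         meta = list(a_pbp = a_pbp, q_dbp = q_dbp)),
    class = c("protein_model", "cg_system")
  )
}

## Groove-fit azimuth: each DBP midway (18 deg) between the two PP beads
## bracketing it axially. With the protein mid-height at z_center, the +z
## DBP sits between residues at z_center + 15.21 and + 18.59.
.groove_azimuth <- function(dna, z_center = 0) {
  g <- .dna_geom
  z <- .residue_z(dna$n_residues)
  zt <- z_center + 16.9
  ## azimuth of the (continued) helix interpolated at the DBP height; if
  ## that height falls on a residue (odd-length chains), step half a
  ## residue aside so the DBP is not driven onto a PP bead
  frac <- ((zt - z[1]) / g$rise) %% 1
  off <- if (min(frac, 1 - frac) < 0.25) 0.5 else 0
  g$twist * ((zt - z[1]) / g$rise + off)
}

#' Assemble a protein + DNA simulation system
#'
#' Places the protein beside the DNA. By default the protein is centered at
#' DNA mid-height with the groove-fit azimuth: each DBP bead sits midway
#' (18 degrees) between the two PP beads that bracket it along the axis.
#'
#' Note that in the canonical bound placement the DBP beads nominally
#' overlap the PP excluded-volume radii (sigma(DBP) + sigma(PP) = 16.4 A
#' versus a centre distance of ~3.3 A); the half-harmonic excluded-volume
#' term resolves this within picoseconds of dynamics, so the clash check
#' only rejects placements that are unphysical even for this model (beads
#' driven inside one another beyond `clash_tol`).
#'
#' @param dna A `dna_model`.
#' @param protein A `protein_model`.
#' @param azimuth Azimuth of the protein about the DNA axis in degrees, or
#'   `NULL` for the groove-fit default.
#' @param z_offset Axial offset of the protein center from DNA mid-height, A.
#' @param radial_offset Extra radial displacement of the whole protein, A
#'   (use e.g. 43 to start the PBP at 90 A for umbrella sampling).
#' @param clash_tol Maximum tolerated excluded-volume overlap in A beyond
#'   which assembly fails with a placement error.
#' @return An object of class `cg_system` with molecule 1 = DNA,
#'   molecule 2 = protein.
#' @export
assemble_system <- function(dna, protein, azimuth = NULL, z_offset = 0,
                            radial_offset = 0, clash_tol = 14) {
  stopifnot(inherits(dna, "dna_model"), inherits(protein, "protein_model"))
  half_len <- (dna$n_residues - 1) / 2 * .dna_geom$rise
  if (abs(z_offset) > half_len) {
    stop("placement error: z_offset ", z_offset,
         " A puts the protein beyond the DNA ends (half-length ",
         round(half_len, 2), " A)")
  }
  if (is.null(azimuth)) azimuth <- .groove_azimuth(dna, z_offset)

  ## rotate protein about Z by azimuth, then shift axially and radially
  th <- .deg2rad(azimuth)
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xp <- protein$x
  xp[, 1] <- xp[, 1] + radial_offset
  xp <- xp %*% t(R)
  xp[, 3] <- xp[, 3] + z_offset

  nd <- nrow(dna$x)
  x <- rbind(dna$x, xp)
  beads <- rbind(
    transform(dna$beads, molecule = 1L),
    transform(protein$beads, molecule = 2L)
  )
  rownames(beads) <- NULL

  shift <- function(df, by) {
    for (col in intersect(c("i", "j", "k", "l"), names(df))) {
      df[[col]] <- df[[col]] + by
    }
    df
  }
  bonds    <- rbind(dna$bonds, shift(protein$bonds, nd))
  angles   <- rbind(dna$angles, shift(protein$angles, nd))
  torsions <- rbind(dna$torsions, shift(protein$torsions, nd))

  sys <- structure(
    list(x = x, beads = beads, bonds = bonds, angles = angles,
         torsions = torsions, n_residues = dna$n_residues,
         meta = c(dna$meta, protein$meta,
                  list(azimuth = azimuth, z_offset = z_offset,
                       radial_offset = radial_offset))),
    class = "cg_system"
  )

  ## intermolecular clash check
  ip <- which(beads$molecule == 2L)
  id <- which(beads$molecule == 1L)
  worst <- c(0, NA, NA)
  for (p in ip) {
    d <- sqrt(rowSums((x[id, , drop = FALSE] -
                         matrix(x[p, ], length(id), 3, byrow = TRUE))^2))
    ov <- beads$sigma[p] + beads$sigma[id] - d
    m <- which.max(ov)
    if (ov[m] > worst[1]) worst <- c(ov[m], p, id[m])
  }
  if (worst[1] > clash_tol) {
    stop("placement error: beads ", worst[2], " (", beads$name[worst[2]],
         ") and ", worst[3], " (", beads$name[worst[3]],
         ") overlap by ", round(worst[1], 2), " A (tolerance ", clash_tol, ")")
  }
  sys
}

#' @export
print.cg_system <- function(x, ...) {
  cat("<cg_system>", nrow(x$x), "beads")
  if (!is.null(x$n_residues)) cat(",", x$n_residues, "DNA residues")
  cat("\n  bonds:", nrow(x$bonds), " angles:", nrow(x$angles),
      " torsions:", nrow(x$torsions), "\n")
  tb <- table(x$beads$name)
  cat("  beads:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  invisible(x)
}
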