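test_that("DNA build reproduces the B-form helix geometry", {
  dna <- build_dna(200)
  expect_equal(nrow(dna$x), 400)
  expect_equal(sum(dna$beads$name == "PP"), 200)
  expect_equal(sum(dna$beads$name == "PB"), 200)

  ipp <- which(dna$beads$name == "PP")
  ipb <- which(dna$beads$name == "PB")
  ## PB beads on the axis, 3.38 A apart
  expect_true(all(abs(dna$x[ipb, 1:2]) < 1e-12))
  expect_equal(diff(dna$x[ipb, 3]), rep(3.38, 199))
  ## end-to-end PB distance
  expect_equal(sqrt(sum((dna$x[ipb[200], ] - dna$x[ipb[1], ])^2)),
               199 * 3.38, tolerance = 1e-12)
  ## PP-PB distance 8.973 A for every residue
  d <- sqrt(rowSums((dna$x[ipp, ] - dna$x[ipb, ])^2))
  expect_equal(d, rep(8.973, 200), tolerance = 1e-12)
  ## torsion PP(a)-PB(a)-PB(a+1)-PP(a+1) = +36 degrees
  phis <- sapply(1:30, function(a) {
    dihedral_angle(dna$x, c(ipp[a], ipb[a], ipb[a + 1], ipp[a + 1]))
  })
  expect_equal(phis, rep(36 * pi / 180, 30), tolerance = 1e-10)
  ## geometric center at the origin
  expect_equal(colMeans(dna$x), c(0, 0, 0), tolerance = 1e-10)
})

test_that("helix maps onto itself under one pitch of screw symmetry", {
  dna <- build_dna(40)
  ipp <- which(dna$beads$name == "PP")
  xpp <- dna$x[ipp, ]
  th <- 2 * pi   # 360 degrees; combined with +33.8 A translation
  shifted <- cbind(xpp[, 1] * cos(th) - xpp[, 2] * sin(th),
                   xpp[, 1] * sin(th) + xpp[, 2] * cos(th),
                   xpp[, 3] + 33.8)
  ## residues 1..30 map onto residues 11..40
  expect_equal(shifted[1:30, ], xpp[11:40, ], tolerance = 1e-9)
})

test_that("ideal build is the bonded-energy minimum and rebuilds identically", {
  dna <- build_dna(30)
  er <- total_energy_forces(dna, params = ff_params(kex = 0), forces = FALSE)
  expect_lt(sum(er$terms[c("bond", "angle", "torsion")]), 1e-8)
  expect_identical(build_dna(30), dna)

  ## excluded volume of the ideal helix is exactly zero under the
  ## residue-separation exclusion rule
  er2 <- total_energy_forces(dna, forces = FALSE)
  expect_equal(unname(er2$terms["excluded"]), 0)
})

test_that("too-short DNA and bad protein parameters are rejected", {
  expect_error(build_dna(2), "invalid model")
  expect_error(build_dna(10.5), "invalid model")
  expect_error(build_protein(a_pbp = -1), "invalid model")
  expect_error(build_protein(a_pbp = 40, q_dbp = NaN), "invalid model")
})

test_that("protein geometry satisfies both bond lengths simultaneously", {
  p <- build_protein(a_pbp = 40, q_dbp = 8)
  d_pd <- sqrt(sum((p$x[1, ] - p$x[2, ])^2))
  d_dd <- sqrt(sum((p$x[2, ] - p$x[3, ])^2))
  expect_equal(d_pd, 41.59, tolerance = 0.05 / 41.59)
  expect_equal(d_dd, 33.8, tolerance = 1e-12)
  ## placement solves sqrt(38^2 + 16.9^2) = 41.59
  expect_equal(sqrt(38.027^2 + 16.9^2), 41.61, tolerance = 1e-3)
  expect_equal(p$beads$charge, c(0, 8, 8))
  expect_equal(p$beads$stokes, c(40, 8, 8))
})

test_that("default bead specifications carry the reference charges", {
  bt <- bead_table()
  expect_equal(bt$charge[bt$name == "PP"], -2)
  expect_equal(bt$charge[bt$name == "PB"], 0)
  expect_equal(bt$charge[bt$name == "PBP"], 0)
  expect_equal(bt$sigma, c(10.4, 2.5, 27.6, 6))
})

test_that("assembly places the protein in the groove-fit pose", {
  sys <- assemble_system(build_dna(200), build_protein(40, 8))
  expect_equal(nrow(sys$x), 403)
  expect_equal(sort(unique(sys$beads$molecule)), c(1L, 2L))

  ## each DBP is equidistant (in azimuth) from its two bracketing PP beads
  dbp <- which(sys$beads$name == "DBP")
  pp <- which(sys$beads$name == "PP")
  for (d in dbp) {
    dist <- sqrt(rowSums((sys$x[pp, ] -
                            matrix(sys$x[d, ], length(pp), 3,
                                   byrow = TRUE))^2))
    two <- sort(dist)[1:2]
    expect_equal(two[1], two[2], tolerance = 1e-6)
  }
  ## PBP at 47 A from the axis, mid-height
  pbp <- which(sys$beads$name == "PBP")
  expect_equal(sqrt(sum(sys$x[pbp, 1:2]^2)), 47, tolerance = 1e-9)
  expect_equal(sys$x[pbp, 3], 0, tolerance = 1e-9)
})

test_that("placement beyond the DNA ends is rejected", {
  expect_error(
    assemble_system(build_dna(20), build_protein(40, 8), z_offset = 100),
    "placement error")
})

test_that("gross steric clashes are reported with the offending pair", {
  ## driving the protein into the DNA axis overlaps PBP with everything
  expect_error(
    assemble_system(build_dna(60), build_protein(40, 8),
                    radial_offset = -46),
    "placement error.*overlap")
})

test_that("the backbone bending angle convention is configurable", {
  dna <- build_dna(10, theta0_pb = 32.7)
  bb <- dna$angles[dna$angles$ka == 87.7, ]
  expect_equal(unique(bb$theta0), 32.7 * pi / 180)
  ## default is the straight-chain convention
  dna2 <- build_dna(10)
  expect_equal(unique(dna2$angles$theta0[dna2$angles$ka == 87.7]), pi)
})
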