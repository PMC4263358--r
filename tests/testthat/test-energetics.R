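test_that("scalar bonded terms match closed-form values", {
  ## bonds
  expect_equal(bond_energy(41.59, 1, 41.59), 0)
  expect_equal(bond_energy(42.59, 1, 41.59), 0.5)
  k_ppb <- 100 * kbt(298) / 8.973^2
  expect_equal(bond_energy(9.073, k_ppb, 8.973),
               0.5 * (100 * 0.59248 / 8.973^2) * 0.01, tolerance = 1e-10)
  expect_error(bond_energy(0, 1, 1), "singular")

  ## angles
  expect_equal(angle_energy(1.2, 100, 1.2), 0)
  expect_equal(angle_energy(1.3, 87.7, 1.2), 0.5 * 87.7 * 0.01)
  ## bending stiffness / persistence-length relation: Lp = k b / kBT
  expect_equal(87.7 * 3.38 / kbt(298), 500.2, tolerance = 1e-3)

  ## torsions, with wrap symmetry
  expect_equal(torsion_energy(36 * pi / 180, 131.6, 36 * pi / 180), 0)
  expect_equal(torsion_energy(0.05, 131.6, 0), 0.5 * 131.6 * 0.0025)
  expect_equal(torsion_energy(pi + 0.3, 131.6, 0),
               torsion_energy(-pi + 0.3, 131.6, 0))
  expect_equal(torsion_energy(pi, 10, 0), torsion_energy(-pi, 10, 0))
})

test_that("excluded volume is half-harmonic with the Table contact radii", {
  expect_equal(excluded_volume_energy(21.8, 10.4, 10.4), 0)
  expect_equal(excluded_volume_energy(20.8, 10.4, 10.4), 0)
  expect_equal(excluded_volume_energy(19.8, 10.4, 10.4), 0.5)
  expect_equal(excluded_volume_energy(10, 7, 4, kex = 2), 0.5 * 2 * 1)
})

test_that("DLVO electrostatics reproduces the screened pair energy", {
  ## charge-free pair
  expect_equal(electrostatic_energy(20, 0, 5, 7, 7), 0)
  ## kappa -> 0 reduces to Coulomb / eps
  expect_equal(electrostatic_energy(10, 2, -1, 7, 7, eps = 80, kappa = 0),
               332.06 * 2 * (-1) / (80 * 10))
  ## two PP beads at 20 A, the full DLVO form
  v <- electrostatic_energy(20, -2, -2, 7, 7, eps = 78.5, kappa = 1 / 7.8)
  f <- exp(7 / 7.8) / (1 + 7 / 7.8)
  expect_equal(v, (332.06 / 78.5) * 4 * f^2 * exp(-20 / 7.8) / 20,
               tolerance = 1e-12)
  expect_equal(v, 0.1089, tolerance = 1e-3)
  ## pair exchange symmetry
  expect_equal(electrostatic_energy(15, -2, 8, 7, 8),
               electrostatic_energy(15, 8, -2, 8, 7))
  ## bare Debye-Hueckel drops the size factors
  expect_equal(electrostatic_energy(20, -2, -2, 7, 7, use_dlvo = FALSE),
               (332.06 / 78.5) * 4 * exp(-20 / 7.8) / 20)
})

test_that("analytic forces match the numerical gradient", {
  set.seed(71)
  sys <- mini_system(20)
  x <- sys$x + matrix(rnorm(length(sys$x), sd = 0.3), nrow(sys$x), 3)
  restr <- list(kr = c(rep(1, 40), numeric(nrow(x) - 40)),
                anchors = unname(sys$x))
  bias <- list(umbrella = list(i = 41, j = 20, k = 5, r0 = 50),
               zplane = list(i = 41, k = 1, z0 = 0))
  er <- total_energy_forces(sys, x, restraints = restr, bias = bias)
  beads <- c(1:6, 20, 21, 40:43)
  num <- numerical_forces(sys, x, restraints = restr, bias = bias,
                          beads = beads)
  expect_lt(max(abs(num - er$forces[beads, ])), 1e-5)
  expect_equal(er$total, sum(er$terms))
})

test_that("net force vanishes and energy is rigid-motion invariant", {
  set.seed(72)
  sys <- mini_system(15)
  x <- sys$x + matrix(rnorm(length(sys$x), sd = 0.2), nrow(sys$x), 3)
  er <- total_energy_forces(sys, x)
  expect_lt(max(abs(colSums(er$forces))), 1e-9)
  ## net torque about the origin (no restraints or bias)
  tq <- colSums(cbind(
    x[, 2] * er$forces[, 3] - x[, 3] * er$forces[, 2],
    x[, 3] * er$forces[, 1] - x[, 1] * er$forces[, 3],
    x[, 1] * er$forces[, 2] - x[, 2] * er$forces[, 1]))
  expect_lt(max(abs(tq)), 1e-8)

  R <- random_rotation()
  shift <- c(5, -3, 11)
  x2 <- sweep(x %*% t(R), 2, shift, `+`)
  er2 <- total_energy_forces(sys, x2, forces = FALSE)
  expect_equal(er2$total, er$total, tolerance = 1e-10)
})

test_that("restraint and bias terms enter the breakdown as stated", {
  sys <- make_fixture("dna20")
  x <- sys$x
  x[1, 1] <- x[1, 1] + 1
  restr <- list(kr = c(1, numeric(nrow(x) - 1)), anchors = unname(sys$x))
  er <- total_energy_forces(sys, x, restraints = restr, forces = FALSE)
  expect_equal(unname(er$terms["restraint"]), 0.5)
})

test_that("invalid conformations are rejected", {
  sys <- make_fixture("dna20")
  x <- sys$x
  x[3, 2] <- NaN
  expect_error(total_energy_forces(sys, x), "invalid conformation")
  expect_error(total_energy_forces(sys, sys$x[1:5, ]),
               "invalid conformation")
})
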