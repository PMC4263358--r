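test_that("deterministic step with zero force and zero noise is identity", {
  sys <- make_fixture("dimer")
  D <- grand_matrix(sys)
  x2 <- rk2_step(sys$x, D, function(x) matrix(0, nrow(x), 3), dt = 0.25,
                 S = numeric(6))
  expect_equal(x2, unname(sys$x))
})

test_that("free diffusion reproduces MSD = 6 D t", {
  sys <- make_fixture("bead1")
  D0 <- stokes_einstein_d(20)
  set.seed(21)
  msds <- sapply(1:12, function(rep) {
    tr <- run_simulation(sys, bd_protocol(
      n_steps = 20000, sample_interval = 50, hi_mode = "free_draining",
      dna_mode = "none"))
    xyz <- t(tr$coords[1, , ])
    nf <- nrow(xyz)
    sapply(1:30, function(m) {
      mean(rowSums((xyz[seq_len(nf - m) + m, ] - xyz[seq_len(nf - m), ])^2))
    })
  })
  lag <- (1:30) * 50 * 0.25 / 1000
  fit <- lm(rowMeans(msds) ~ lag)
  expect_equal(unname(coef(fit)[2]) / 6, D0, tolerance = 0.03)
})

test_that("a harmonically confined bead equilibrates to k_B T / k variance", {
  sys <- make_fixture("bead1")
  restr <- list(kr = 1, anchors = matrix(0, 1, 3))
  set.seed(22)
  tr <- run_simulation(sys, bd_protocol(
    n_steps = 3e5, sample_interval = 200, hi_mode = "free_draining",
    dna_mode = "none"), restraints = restr)
  xyz <- t(tr$coords[1, , ])
  v <- mean(apply(xyz, 2, function(u) mean(u^2)))
  expect_equal(v, kbt(298) / 1, tolerance = 0.05)
})

test_that("frame bookkeeping and determinism hold", {
  sys <- make_fixture("dimer")
  proto <- bd_protocol(n_steps = 1e4, sample_interval = 1e3,
                       hi_mode = "full_hi", dna_mode = "none", seed = 5)
  tr <- run_simulation(sys, proto)
  expect_equal(n_frames(tr), 11)
  expect_true(all(diff(tr$times) > 0))
  expect_equal(tr$times[11], 1e4 * 0.25 / 1000)

  tr2 <- run_simulation(sys, proto)
  expect_identical(tr$coords, tr2$coords)
  expect_identical(tr$energies, tr2$energies)
})

test_that("restrained DNA stays at its anchors on the thermal scale", {
  dna <- build_dna(10)
  set.seed(23)
  tr <- run_simulation(dna, bd_protocol(
    n_steps = 2e4, sample_interval = 200, hi_mode = "free_draining",
    dna_mode = "restrained"))
  dev <- sqrt(apply((tr$coords - c(tr$coords[, , 1]))^2, 3, max))
  ## thermal scale: at most sqrt(3 kBT / k_r) = 1.33 A RMSD (the bonded
  ## lattice confines further), never > 5 A
  expect_lt(max(dev), 5)
  rms <- sqrt(mean(apply(tr$coords[, , -1], 3, function(f) {
    mean(rowSums((f - tr$coords[, , 1])^2))
  })))
  expect_lt(rms, sqrt(3 * kbt() / 1) * 1.1)
  expect_gt(rms, 0.4)
})

test_that("sampled bond lengths follow the Boltzmann distribution", {
  ## isolated stiff bond: the exact marginal is P(r) dr ~ r^2
  ## exp(-beta k (r - r0)^2 / 2) dr, and frames 100 steps apart are far
  ## beyond the bond relaxation time (~7 steps), so a KS test applies
  sys <- make_fixture("dimer")
  sys$beads <- transform(sys$beads, molecule = 1L, stokes = 7,
                         sigma = 0, charge = 0)
  k <- 100 * kbt() / 3.38^2
  sys$bonds <- data.frame(i = 1, j = 2, k = k, r0 = 3.38)
  sys$x <- matrix(c(0, 0, 0, 3.38, 0, 0), 2, 3, byrow = TRUE)
  set.seed(24)
  tr <- run_simulation(sys, bd_protocol(
    n_steps = 1e6, sample_interval = 100, hi_mode = "free_draining",
    dna_mode = "none"))
  r <- sqrt(colSums((tr$coords[1, , ] - tr$coords[2, , ])^2))[-(1:50)]
  grid <- seq(3.38 - 6 * 0.34, 3.38 + 6 * 0.34, length.out = 4001)
  dens <- grid^2 * exp(-k * (grid - 3.38)^2 / (2 * kbt()))
  cdf <- cumsum(dens) / sum(dens)
  pfun <- function(q) approx(grid, cdf, q, yleft = 0, yright = 1)$y
  ks <- suppressWarnings(stats::ks.test(r, pfun))
  expect_gt(ks$p.value, 0.01)
})

test_that("the full chain equipartitions under HI at the protocol time step", {
  ## with hydrodynamic interactions, bonded neighbours overlap and their
  ## correlated mobilities keep the stiff modes stable at dt = 0.25 ps
  dna <- build_dna(10)
  set.seed(26)
  tr <- run_simulation(dna, bd_protocol(
    n_steps = 4e4, dt = 0.25, sample_interval = 100,
    hi_mode = "intra_hi", dna_mode = "none"))
  em <- colMeans(tr$energies[-(1:100), ])
  kT <- kbt()
  expect_equal(unname(em["bond"]), 19 * kT / 2, tolerance = 0.15)
  expect_equal(unname(em["angle"]), 26 * kT / 2, tolerance = 0.15)
  expect_equal(unname(em["torsion"]), 9 * kT / 2, tolerance = 0.20)
})

test_that("a blow-up aborts with the step index and partial trajectory", {
  sys <- make_fixture("bead1")
  proto <- bd_protocol(n_steps = 1000, sample_interval = 10,
                       hi_mode = "free_draining", dna_mode = "none",
                       seed = 3, max_disp = 1e-4)
  err <- tryCatch(run_simulation(sys, proto), error = function(e) e)
  expect_match(conditionMessage(err), "blow-up error")
  expect_match(conditionMessage(err), "step")
  expect_s3_class(err$trajectory, "bd_trajectory")
})

test_that("a strongly bound protein never detaches from restrained DNA", {
  ## start from the slightly retracted groove pose: at q(DBP) = 20 the
  ## DBP beads relax outward to their bound distance within picoseconds
  sys <- assemble_system(build_dna(20), build_protein(40, 20),
                         radial_offset = 12)
  set.seed(25)
  tr <- run_simulation(sys, bd_protocol(
    n_steps = 4e4, sample_interval = 400, hi_mode = "free_draining",
    dna_mode = "restrained"))
  hops <- detect_hops(tr, r_off = 40)
  expect_equal(nrow(hops), 0)
  ## bound throughout: minimum DBP-PP distance inside the cutoff
  dbp <- which(sys$beads$name == "DBP")
  pp <- which(sys$beads$name == "PP")
  mind <- apply(tr$coords, 3, function(f) {
    min(sqrt(outer(rowSums(f[dbp, ]^2), rowSums(f[pp, ]^2), `+`) -
               2 * f[dbp, ] %*% t(f[pp, ])))
  })
  expect_lt(max(mind), 40)
})
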