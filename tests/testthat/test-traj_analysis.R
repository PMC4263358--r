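## build a minimal fake trajectory around an explicit coordinate array
fake_traj <- function(coords, times, system) {
  structure(list(times = times, coords = coords,
                 energies = matrix(0, length(times), 8),
                 final = coords[, , dim(coords)[3]],
                 protocol = NULL, system = system),
            class = "bd_trajectory")
}

test_that("MSD estimator has the exact limits", {
  ## static trajectory
  co <- array(0, c(1, 3, 50))
  tr <- fake_traj(co, seq(0, 49) * 0.1, make_fixture("bead1"))
  m <- msd_1d(tr, 1, 3)
  expect_true(all(m$msd == 0))

  ## time reversal leaves the MSD unchanged
  set.seed(51)
  z <- cumsum(rnorm(200))
  co2 <- array(0, c(1, 3, 200)); co2[1, 3, ] <- z
  co3 <- array(0, c(1, 3, 200)); co3[1, 3, ] <- rev(z)
  t200 <- seq(0, 199) * 0.1
  sys <- make_fixture("bead1")
  expect_equal(msd_1d(fake_traj(co2, t200, sys))$msd,
               msd_1d(fake_traj(co3, t200, sys))$msd)

  ## non-uniform sampling is rejected
  expect_error(msd_1d(fake_traj(co, c(seq(0, 4.8, 0.1), 6), sys)),
               "non-uniform")
})

test_that("a known random walk yields its diffusion coefficient", {
  set.seed(52)
  Dtrue <- 0.05
  dt <- 2.5
  reps <- lapply(1:10, function(i) {
    z <- cumsum(rnorm(2000, 0, sqrt(2 * Dtrue * dt)))
    co <- array(0, c(1, 3, 2000)); co[1, 3, ] <- z
    msd_1d(fake_traj(co, (0:1999) * dt, make_fixture("bead1")))
  })
  est <- apparent_d1d(reps)
  expect_equal(est$D, Dtrue, tolerance = 0.05)
  expect_equal(est$n_replicas, 10L)

  ## an exactly linear MSD curve returns slope/2
  m <- structure(data.frame(lag = 1:100, msd = 2 * 0.05 * (1:100),
                            n_pairs = 101 - (1:100)),
                 class = c("msd_curve", "data.frame"))
  expect_equal(apparent_d1d(m)$D, 0.05, tolerance = 1e-12)
})

test_that("rotation coupling reads the helical pitch off an ideal track", {
  phi <- seq(0, 6 * pi, length.out = 400)
  xyz <- cbind(20 * cos(phi), 20 * sin(phi), 33.8 * phi / (2 * pi))
  rc <- rotation_coupling(xyz)
  expect_equal(rc$slope, 33.8 / (2 * pi), tolerance = 1e-9)
  expect_equal(rc$correlation, 1, tolerance = 1e-12)

  set.seed(53)
  xyz2 <- cbind(cos(runif(10000, 0, 2 * pi)),
                sin(runif(10000, 0, 2 * pi)), rnorm(10000))
  rc2 <- rotation_coupling(xyz2)
  expect_lt(abs(rc2$correlation), 0.1)
})

test_that("hop detection counts constructed excursions exactly", {
  sys <- mini_system(20)
  nf <- 100
  co <- array(rep(sys$x, nf), c(nrow(sys$x), 3, nf))
  ## push the protein 60 A radially outward for frames 40..49 (10 ns)
  prot <- which(sys$beads$molecule == 2)
  for (f in 40:49) co[prot, 1, f] <- co[prot, 1, f] + 60
  tr <- fake_traj(co, (0:(nf - 1)) * 1.0, sys)
  ev <- detect_hops(tr, r_off = 40, min_duration = 5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 39)
  expect_gt(ev$max_dist, 40)
  ## no event at a tighter duration filter than the excursion allows
  expect_equal(nrow(detect_hops(tr, r_off = 40, min_duration = 20)), 0)
})

test_that("persistence length recovers the bending parameterization", {
  ## rigid rod: correlation 1, reported as an infinite lower bound
  dna <- build_dna(60)
  ipb <- which(dna$beads$name == "PB")
  co <- array(rep(dna$x[ipb, ], 20), c(60, 3, 20))
  pl0 <- persistence_length(co, max_lag = 20)
  expect_equal(pl0$Lp, Inf)

  ## halved stiffness halves Lp (linearity of Lp = k b / kBT)
  dna2 <- build_dna(120)
  dna2$angles$ka[dna2$angles$ka == 87.7] <- 87.7 / 2
  set.seed(54)
  ens <- sample_dna_conformations(dna2, n_sweeps = 900, n_equil = 150,
                                  sample_every = 2, max_angle = 16)
  pl <- persistence_length(ens, max_lag = 30)
  expect_equal(pl$Lp, 87.7 / 2 * 3.38 / kbt(), tolerance = 0.15)
})

test_that("lab-frame center of diffusion tracks the rigid-theory R_OC", {
  sys <- assemble_system(build_dna(20), build_protein(40, 8), azimuth = 0)
  h <- protein_hydro(40)
  ## frozen at the build pose: deterministic, matches theory directly
  co <- array(rep(sys$x, 3), c(nrow(sys$x), 3, 3))
  tr <- fake_traj(co, 0:2, sys)
  roc <- roc_from_traj(tr, h)
  expect_equal(roc$sd, 0)
  expect_gt(roc$mean, 40)
  expect_lt(roc$mean, 50)
  expect_equal(roc$mean, h$R_OC, tolerance = 1e-6)

  ## thermalized pose: jitter the protein rigidly, SD > 0, mean near R_OC
  set.seed(55)
  prot <- which(sys$beads$molecule == 2)
  nf <- 40
  co2 <- array(rep(sys$x, nf), c(nrow(sys$x), 3, nf))
  for (f in 1:nf) {
    th <- rnorm(1, 0, 0.05)
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    co2[prot, , f] <- sys$x[prot, ] %*% t(R) +
      matrix(rnorm(3, 0, 0.5), nrow = 3, ncol = 3, byrow = TRUE)
  }
  roc2 <- roc_from_traj(fake_traj(co2, seq_len(nf), sys), h)
  expect_gt(roc2$sd, 0)
  expect_equal(roc2$mean, h$R_OC, tolerance = 0.05)
})
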