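test_that("rigid-particle theory has the exact sphere limit", {
  h <- rigid_body_diffusion(matrix(0, 1, 3), 20)
  expect_equal(h$D_T, mobility_constant() / 20)
  expect_equal(h$a_T, 20)
  expect_equal(h$a_R, 20, tolerance = 1e-9)
})

test_that("rigid-particle theory reproduces the protein diffusion table", {
  ## a(PBP) = 30: no bead overlap, convention-free
  h30 <- protein_hydro(30)
  expect_equal(h30$D_T, 7.79, tolerance = 0.02)
  expect_equal(h30$a_T, 31.5, tolerance = 0.02)
  expect_equal(h30$a_R, 20.4, tolerance = 0.02)
  expect_equal(h30$R_OC, 40.4, tolerance = 1.1 / 40.4)

  ## overlap rule validated against the larger sizes
  h40 <- protein_hydro(40)
  expect_equal(h40$a_T, 40.5, tolerance = 0.02)
  expect_equal(h40$a_R, 20.6, tolerance = 0.02)
  expect_equal(h40$R_OC, 44.0, tolerance = 1.1 / 44)
  h50 <- protein_hydro(50)
  expect_equal(h50$a_T, 50.1, tolerance = 0.02)
  expect_equal(h50$R_OC, 45.8, tolerance = 1.1 / 45.8)

  ## enclosing-sphere bound and flat rotational radius
  expect_gt(h30$a_T, 30)
  expect_lt(h30$a_T, 33)
  expect_lt(h30$a_R, h30$a_T)
})

test_that("rigid-body D_T agrees with BD diffusion of a stiff dimer", {
  ## independent oracle: long-time MSD/6t of a stiff-bonded dimer under
  ## full HI should match the rigid-body translational diffusion
  sys <- make_fixture("dimer")
  sys$beads$molecule <- c(1L, 1L)
  sys$bonds <- data.frame(i = 1, j = 2, k = 20, r0 = 50)
  th <- rigid_body_diffusion(sys$x, sys$beads$stokes)
  set.seed(12)
  msds <- lapply(1:10, function(rep) {
    tr <- run_simulation(sys, bd_protocol(
      n_steps = 100000, sample_interval = 50, hi_mode = "full_hi",
      dna_mode = "none", tensor_update = 200))
    cen <- t((tr$coords[1, , ] + tr$coords[2, , ]) / 2)
    nf <- nrow(cen)
    lags <- 1:25
    data.frame(lag = lags * diff(tr$times)[1],
               msd = sapply(lags, function(m) {
                 mean(rowSums((cen[seq_len(nf - m) + m, ] -
                                 cen[seq_len(nf - m), ])^2))
               }),
               n_pairs = nf - lags)
  })
  pooled <- msds[[1]]
  pooled$msd <- rowMeans(sapply(msds, `[[`, "msd"))
  fit <- lm(msd ~ lag, data = pooled, weights = pooled$n_pairs)
  D_bd <- unname(coef(fit)[2]) / 6
  expect_equal(D_bd, th$D_T, tolerance = 0.05)
})

test_that("BBX expressions reproduce the printed 1D coefficients", {
  ## rows of the diffusive-property table: (a_T, R_OC) -> D_1D^theory
  expect_equal(bbx_d1d(40.5, 44.0), 0.041, tolerance = 0.05)
  expect_equal(bbx_d1d(31.5, 40.4), 0.074, tolerance = 0.05)
  ## corrected form with the rotational radius
  expect_equal(bbx_corrected_d1d(31.5, 20.4, 40.4), 0.109, tolerance = 0.05)
  expect_equal(bbx_corrected_d1d(40.5, 20.6, 44.0), 0.076, tolerance = 0.05)
  ## degeneracy: a_R = a_T collapses to the plain form
  expect_equal(bbx_corrected_d1d(31.5, 31.5, 40.4), bbx_d1d(31.5, 40.4))
  ## uncoupled limit: infinite pitch recovers Stokes-Einstein
  expect_equal(bbx_d1d(30, 40, pitch = 1e12), stokes_einstein_d(30),
               tolerance = 1e-6)
  ## strictly decreasing in both arguments
  expect_true(all(diff(bbx_d1d(seq(20, 60, 5), 40)) < 0))
  expect_true(all(diff(bbx_d1d(30, seq(20, 60, 5))) < 0))
})

test_that("helical sliding slows diffusion by about two orders", {
  tab <- sliding_theory_table(c(30, 40, 50))
  ratio <- tab$D_3D / tab$D_1D_theory
  expect_true(all(ratio >= 50 & ratio <= 200))
})

test_that("Zwanzig roughness factor matches the quoted reduction", {
  expect_equal(zwanzig_reduction(0), 1)
  expect_equal(zwanzig_reduction(1.1), exp(-1.21))
  expect_equal(zwanzig_reduction(1.1), 0.298, tolerance = 1e-3)
  expect_equal(zwanzig_reduction(2), exp(-4))
})

test_that("Debye length matches physiological salt and scales as I^-1/2", {
  expect_equal(debye_length(0.15), 7.8, tolerance = 0.1 / 7.8)
  expect_equal(debye_length(0.15 * 4), debye_length(0.15) / 2)
  expect_equal(debye_length(0.0375), 15.7, tolerance = 0.01)
})

test_that("search-rate theory gives the Smoluchowski scale and optimum", {
  sr <- search_rate(D_3D = 5e-6, D_1D = 5e-8, tau_1D = 1e-3,
                    tau_3D = 1e-3, f = 0.3)
  expect_equal(sr$k_smol, 3.9e8, tolerance = 0.02)
  ## maximum of k_s over tau_1D at fixed D_1D sits at tau_1D = tau_3D
  taus <- 10^seq(-5, -1, length.out = 81)
  ks <- sapply(taus, function(t1) {
    search_rate(5e-6, 5e-8, t1, 1e-3, 0.3)$k_s
  })
  expect_equal(taus[which.max(ks)], 1e-3, tolerance = 0.15)
  ## no sliding, no facilitated rate
  sr0 <- search_rate(5e-6, 0, 1e-3, 1e-3, 0.3)
  expect_equal(sr0$n_bar, 0)
  expect_equal(sr0$k_s, 0)
})
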