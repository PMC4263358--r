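test_that("RPY self block and far field match the closed forms", {
  ## self mobility of the a_T = 31.5 A protein equivalent sphere
  B <- rpy_block(c(0, 0, 0), NULL, a_i = 31.5)
  expect_equal(B, diag(3) * mobility_constant() / 31.5, tolerance = 1e-12)
  expect_equal(B[1, 1], 7.79, tolerance = 0.02)

  ## far separation approaches the Oseen tensor
  r <- c(5000, 0, 0)
  B2 <- rpy_block(r, c(0, 0, 0), 10, 20)
  pref <- mobility_constant() * 6 / (8 * 5000)
  oseen <- pref * (diag(3) + outer(c(1, 0, 0), c(1, 0, 0)))
  expect_equal(B2, oseen, tolerance = 1e-4)

  ## equal spheres: overlap and far-field branches agree at exact contact
  a <- 12
  eps <- 1e-9
  Bin <- rpy_block(c(2 * a - eps, 0, 0), c(0, 0, 0), a, a)
  Bout <- rpy_block(c(2 * a + eps, 0, 0), c(0, 0, 0), a, a)
  expect_equal(Bin, Bout, tolerance = 1e-7)

  expect_error(rpy_block(c(0, 0, 0), c(0, 0, 0), 5, 5), "singular")
})

test_that("grand matrix is symmetric positive definite even with overlaps", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 12
    x <- matrix(runif(3 * n, 0, 30), n, 3)   # dense: many overlaps
    a <- runif(n, 2, 15)
    sys <- list(beads = data.frame(stokes = a, molecule = rep(1L, n)))
    class(sys) <- "cg_system"
    D <- grand_matrix(sys, x, mode = "full_hi")
    expect_lt(max(abs(D - t(D))), 1e-12)
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), 0)
    expect_true(is.matrix(chol(D)))
  }
})

test_that("HI modes zero the right blocks and share the diagonal", {
  sys <- mini_system(10)
  Df <- grand_matrix(sys, mode = "full_hi")
  Di <- grand_matrix(sys, mode = "intra_hi")
  Dd <- grand_matrix(sys, mode = "free_draining")
  n <- nrow(sys$x)
  ## traces agree: self blocks unaffected by mode
  expect_equal(sum(diag(Df)), sum(diag(Di)))
  expect_equal(sum(diag(Df)), sum(diag(Dd)))
  ## protein-DNA blocks zero in intra mode
  prot <- which(sys$beads$molecule == 2)
  dna <- which(sys$beads$molecule == 1)
  pi3 <- as.vector(outer(1:3, (prot - 1) * 3, `+`))
  di3 <- as.vector(outer(1:3, (dna - 1) * 3, `+`))
  expect_true(all(Di[pi3, di3] == 0))
  expect_false(all(Df[pi3, di3] == 0))
  ## free draining is diagonal
  expect_true(all(Dd[row(Dd) != col(Dd)] == 0))
  ## single bead: exactly Stokes-Einstein
  b1 <- make_fixture("bead1")
  expect_equal(grand_matrix(b1, mode = "full_hi")[1, 1],
               mobility_constant() / 20)
})

test_that("rigid rotation conjugates the matrix by the block rotation", {
  set.seed(32)
  sys <- make_fixture("dimer")
  x <- sys$x
  D <- grand_matrix(sys, x)
  R <- random_rotation()
  x2 <- x %*% t(R)
  D2 <- grand_matrix(sys, x2)
  blockR <- kronecker(diag(2), R)
  expect_equal(D2, blockR %*% D %*% t(blockR), tolerance = 1e-10,
               ignore_attr = TRUE)
  ## rigid translation leaves it unchanged
  x3 <- sweep(x, 2, c(7, -2, 3), `+`)
  expect_equal(grand_matrix(sys, x3), D, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("noise draws have covariance 2 D dt and are seed-reproducible", {
  sys <- make_fixture("dimer")
  x <- sys$x
  x[2, ] <- c(45, 5, -3)   # mild asymmetry, still interacting
  D <- grand_matrix(sys, x)
  dt <- 0.25
  set.seed(99)
  draws <- t(replicate(100000, correlated_displacement(D, dt)))
  emp <- crossprod(draws) / nrow(draws)
  target <- 2 * D * dt / 1000
  expect_lt(max(abs(emp - target)) / max(abs(target)), 0.03)

  set.seed(7)
  v1 <- correlated_displacement(D, dt)
  set.seed(7)
  v2 <- correlated_displacement(D, dt)
  expect_identical(v1, v2)
})
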