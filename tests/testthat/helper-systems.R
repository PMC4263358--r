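## Small deterministic systems shared across tests.

mini_system <- function(n = 20, a_pbp = 40, q_dbp = 8) {
  assemble_system(build_dna(n), build_protein(a_pbp, q_dbp))
}

## numerical gradient of the total energy (central differences)
numerical_forces <- function(system, x, params = ff_params(),
                             restraints = NULL, bias = NULL, h = 1e-4,
                             beads = seq_len(nrow(x))) {
  en <- function(xx) total_energy_forces(system, xx, params = params,
                                         restraints = restraints,
                                         bias = bias, forces = FALSE)$total
  num <- matrix(0, length(beads), 3)
  for (q in seq_along(beads)) {
    for (c in 1:3) {
      xp <- x; xm <- x
      xp[beads[q], c] <- xp[beads[q], c] + h
      xm[beads[q], c] <- xm[beads[q], c] - h
      num[q, c] <- -(en(xp) - en(xm)) / (2 * h)
    }
  }
  num
}

## random rotation matrix
random_rotation <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}
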