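## Umbrella sampling along the protein-DNA separation and WHAM
## reconstruction of the potential of mean force; binding free energies
## from the PMF.

#' Build the umbrella-sampling system
#'
#' DNA along Z centered at the origin; protein azimuth on the X axis with
#' the PBP bead at `start_r` from the axis (the unbound side). During
#' sampling all DNA beads are restrained (k_r = 1 kcal/mol/A^2) and the
#' PBP bead is confined to the Z = 0 plane (k = 1 kcal/mol/A^2), so the
#' PBP-to-central-PB distance is effectively the in-plane separation.
#'
#' @param n_residues DNA length in pseudo-residues.
#' @param a_pbp PBP Stokes radius in A.
#' @param q_dbp DBP effective charge.
#' @param start_r Initial PBP distance from the DNA axis in A.
#' @return A `cg_system` with attributes `pbp` and `central_pb` (bead
#'   indices).
#' @export
umbrella_system <- function(n_residues = 60, a_pbp = 40, q_dbp = 8,
                            start_r = 90) {
  dna <- build_dna(n_residues)
  prot <- build_protein(a_pbp = a_pbp, q_dbp = q_dbp)
  sys <- assemble_system(dna, prot, azimuth = 0,
                         radial_offset = start_r - 47)
  pb <- which(sys$beads$name == "PB")
  central <- pb[which.min(abs(sys$x[pb, 3]))]
  attr(sys, "pbp") <- which(sys$beads$name == "PBP")
  attr(sys, "central_pb") <- central
  sys
}

#' Run umbrella-sampling windows
#'
#' Applies the umbrella potential V = 1/2 k_umb (r - r0)^2 between the PBP
#' bead and the PB bead nearest the origin, for each requested window
#' center, chaining the final configuration of each window into the next.
#' Windows are sampled either by equilibrium Metropolis MC on the
#' identical potential (fast default; equilibrium averages do not depend
#' on the hydrodynamic mode) or by the BD engine.
#'
#' The first 20% of each window is discarded as equilibration, matching
#' the reference protocol's 5/25 ns split.
#'
#' @param system A system from [umbrella_system()].
#' @param r0 Window centers in A (reference protocol: 90, 89, ..., 31).
#' @param k_umb Umbrella force constant in kcal/mol/A^2.
#' @param params An `ff_params`.
#' @param sampler `"mc"` or `"bd"`.
#' @param n_sweeps MC sweeps per window (MC sampler).
#' @param window_ns Simulated time per window in ns (BD sampler).
#' @param equil_frac Fraction of each window discarded as equilibration.
#' @param sample_every Sweeps (MC) between reaction-coordinate samples.
#' @param move_dna Sample the restrained DNA beads too (MC sampler)?
#' @param temperature Temperature in K.
#' @param seed RNG seed for the whole window chain.
#' @param hi_mode Hydrodynamic mode (BD sampler).
#' @return A list of `umbrella_window` objects (class
#'   `umbrella_sampling`), each with `r0`, `k_umb`, `samples`,
#'   `n_discarded`, `acceptance`.
#' @export
run_umbrella <- function(system, r0 = seq(90, 31, -1), k_umb = 5,
                         params = ff_params(), sampler = c("mc", "bd"),
                         n_sweeps = 4000, window_ns = 2.5,
                         equil_frac = 0.2, sample_every = 2,
                         move_dna = TRUE, temperature = 298, seed = NULL,
                         hi_mode = "free_draining") {
  sampler <- match.arg(sampler)
  stopifnot(length(r0) >= 1, k_umb > 0)
  if (!is.null(seed)) set.seed(seed)
  pbp <- attr(system, "pbp")
  cpb <- attr(system, "central_pb")
  if (is.null(pbp) || is.null(cpb)) {
    stop("system must come from umbrella_system()")
  }
  restraints <- dna_restraints(system, "restrained", system$x)
  arr <- .empty_topo_matrices(.sys_arrays(system))
  prot_beads <- which(system$beads$molecule == 2L)
  x <- unname(system$x)
  windows <- vector("list", length(r0))

  for (w in seq_along(r0)) {
    bias <- list(
      umbrella = list(i = pbp, j = cpb, k = k_umb, r0 = r0[w]),
      zplane = list(i = pbp, k = 1, z0 = 0)
    )
    if (sampler == "mc") {
      n_equil <- ceiling(equil_frac * n_sweeps)
      res <- .umbrella_mc_window(
        x, arr, params, .restraint_list(restraints, nrow(x)), bias,
        prot_beads, n_sweeps, n_equil, sample_every, temperature, move_dna)
      samples <- as.numeric(res$samples)
      x <- res$final
      acc <- res$acceptance
      nd <- n_equil
    } else {
      n_steps <- round(window_ns * 1000 / 0.25)
      proto <- bd_protocol(n_steps = n_steps, dt = 0.25,
                           sample_interval = 100, hi_mode = hi_mode,
                           dna_mode = "restrained",
                           temperature = temperature)
      traj <- run_simulation(system, proto, params = params, bias = bias,
                             x0 = x, restraints = restraints)
      rc <- sqrt(colSums((traj$coords[pbp, , ] - traj$coords[cpb, , ])^2))
      nd <- ceiling(equil_frac * length(rc))
      samples <- rc[-seq_len(nd)]
      x <- traj$final
      acc <- NA_real_
    }
    if (length(samples) == 0) {
      stop("sampling error: window r0 = ", r0[w],
           " produced no production samples")
    }
    windows[[w]] <- structure(
      list(r0 = r0[w], k_umb = k_umb, samples = samples, n_discarded = nd,
           acceptance = acc, sampler = sampler),
      class = "umbrella_window")
  }
  structure(windows, class = "umbrella_sampling")
}

#' WHAM reconstruction of the PMF from umbrella windows
#'
#' Standard self-consistent weighted-histogram iteration: the unbiased
#' density rho(b) and the window offsets f_w are alternated until every
#' offset moves by less than `tol`. The PMF is -k_B T log rho, anchored to
#' zero at its minimum; bins with fewer than `min_count` total samples are
#' reported as NA.
#'
#' @param windows An `umbrella_sampling` list (or any list of objects with
#'   `r0`, `k_umb`, `samples`).
#' @param bin_width Histogram bin width in A.
#' @param tol Convergence tolerance on the window offsets, kcal/mol.
#' @param max_iter Maximum iterations.
#' @param temperature Temperature in K.
#' @param min_count Minimum total samples for a reported bin.
#' @return A list of class `pmf_profile`: `r` (bin centers), `pmf`
#'   (kcal/mol), `counts`, `n_iter`, `residual`, `f` (window offsets).
#' @export
wham <- function(windows, bin_width = 0.5, tol = 1e-6, max_iter = 20000,
                 temperature = 298, min_count = 1) {
  stopifnot(length(windows) >= 1)
  kT <- kbt(temperature)
  allr <- unlist(lapply(windows, `[[`, "samples"))
  lo <- floor(min(allr) / bin_width) * bin_width
  hi <- ceiling(max(allr) / bin_width) * bin_width
  edges <- seq(lo, hi, by = bin_width)
  centers <- edges[-1] - bin_width / 2
  B <- length(centers)
  W <- length(windows)

  h <- matrix(0, W, B)
  for (w in seq_len(W)) {
    idx <- pmin(pmax(floor((windows[[w]]$samples - lo) / bin_width) + 1, 1), B)
    tab <- tabulate(idx, nbins = B)
    h[w, ] <- tab
  }
  n_w <- rowSums(h)

  ## overlap check between windows adjacent in r0
  ord <- order(vapply(windows, `[[`, numeric(1), "r0"))
  for (q in seq_len(W - 1)) {
    a <- ord[q]; b <- ord[q + 1]
    if (!any(h[a, ] > 0 & h[b, ] > 0)) {
      stop("ill-posed input: windows r0 = ", windows[[a]]$r0, " and r0 = ",
           windows[[b]]$r0, " share no populated histogram bin")
    }
  }

  bias <- matrix(0, W, B)
  for (w in seq_len(W)) {
    bias[w, ] <- 0.5 * windows[[w]]$k_umb * (centers - windows[[w]]$r0)^2
  }
  expb <- exp(-bias / kT)

  f <- numeric(W)    # -kT log of window normalizations
  rho <- rep(1 / B, B)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- colSums(n_w * expb * exp(f / kT))
    rho <- colSums(h) / pmax(denom, .Machine$double.xmin)
    fz <- expb %*% rho
    fnew <- -kT * log(pmax(as.numeric(fz), .Machine$double.xmin))
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol || iter >= max_iter) break
  }

  total <- colSums(h)
  pmf <- -kT * log(pmax(rho, .Machine$double.xmin))
  pmf[total < min_count] <- NA_real_
  pmf <- pmf - min(pmf, na.rm = TRUE)
  structure(
    list(r = centers, pmf = pmf, counts = total, n_iter = iter,
         residual = delta, f = f - f[1], bin_width = bin_width,
         temperature = temperature),
    class = "pmf_profile"
  )
}

#' @export
print.pmf_profile <- function(x, ...) {
  ok <- !is.na(x$pmf)
  cat("<pmf_profile>", sum(ok), "bins over [",
      format(min(x$r[ok]), digits = 4), ",",
      format(max(x$r[ok]), digits = 4), "] A;",
      x$n_iter, "WHAM iterations (residual",
      format(x$residual, digits = 3), ")\n")
  invisible(x)
}

#' Binding free energy from a PMF
#'
#' Default estimator: the mean PMF over the unbound plateau minus the PMF
#' minimum (which is the anchor, 0), with no standard-state volume
#' correction. If the plateau slope exceeds `slope_tol` the result carries
#' a not-converged warning flag. The alternative `"integral"` estimator
#' Boltzmann-averages the well instead of taking the minimum.
#'
#' @param pmf A `pmf_profile`, or a list of profiles from independent
#'   repeats (mean and standard error are then reported).
#' @param unbound_range Plateau interval in A (default 80-90).
#' @param method `"plateau"` (minimum-referenced) or `"integral"`.
#' @param slope_tol Tolerated plateau slope magnitude, kcal/mol/A.
#' @return A list with `dG` (kcal/mol), `se` (NA for a single profile),
#'   `n_repeats`, `converged`.
#' @export
binding_free_energy <- function(pmf, unbound_range = c(80, 90),
                                method = c("plateau", "integral"),
                                slope_tol = 0.05) {
  method <- match.arg(method)
  if (!inherits(pmf, "pmf_profile") && is.list(pmf)) {
    vals <- vapply(pmf, function(p) {
      binding_free_energy(p, unbound_range, method, slope_tol)$dG
    }, numeric(1))
    conv <- all(vapply(pmf, function(p) {
      binding_free_energy(p, unbound_range, method, slope_tol)$converged
    }, logical(1)))
    return(list(dG = mean(vals), se = sd(vals) / sqrt(length(vals)),
                n_repeats = length(vals), converged = conv))
  }
  sel <- pmf$r >= unbound_range[1] & pmf$r <= unbound_range[2] &
    !is.na(pmf$pmf)
  if (!any(sel) || all(is.na(pmf$pmf))) {
    stop("PMF not defined over the unbound range")
  }
  plateau <- mean(pmf$pmf[sel])
  slope <- unname(coef(lm(pmf$pmf[sel] ~ pmf$r[sel]))[2])
  converged <- is.finite(slope) && abs(slope) <= slope_tol
  if (!converged) {
    warning("plateau slope ", format(slope, digits = 3),
            " kcal/mol/A exceeds tolerance; PMF may not be converged")
  }
  dG <- if (method == "plateau") {
    plateau   # minimum is the 0 anchor
  } else {
    kT <- kbt(pmf$temperature)
    ok <- !is.na(pmf$pmf)
    well <- ok & pmf$r < unbound_range[1]
    depth <- -kT * log(mean(exp(-pmf$pmf[well] / kT)))
    plateau - depth
  }
  list(dG = dG, se = NA_real_, n_repeats = 1L, converged = converged)
}
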