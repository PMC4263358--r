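## Trajectory observables: 1D mean-squared displacement and apparent
## diffusion coefficients, rotation-translation coupling, hopping events,
## DNA persistence length, and the lab-frame center-of-diffusion distance
## from the DNA axis.

## internal: extract a bead coordinate time series (frames x 3) from a
## trajectory or accept a plain matrix
.bead_series <- function(traj, bead) {
  if (inherits(traj, "bd_trajectory")) {
    t(traj$coords[bead, , ])
  } else {
    as.matrix(traj)
  }
}

#' Sliding coordinate along the instantaneous DNA axis
#'
#' Projects a protein bead's position onto the principal axis of the PB
#' backbone at every frame. For restrained DNA this is essentially the
#' bead's z coordinate; for flexible DNA it removes the rigid-body wobble
#' of the chain from the apparent sliding motion.
#'
#' @param traj A `bd_trajectory` of a protein + DNA system.
#' @param bead Protein bead index (defaults to the PBP bead).
#' @return Numeric vector, one projected coordinate (A) per frame.
#' @export
sliding_coordinate <- function(traj, bead = NULL) {
  b <- traj$system$beads
  pb <- which(b$name == "PB")
  if (length(pb) < 3) stop("trajectory must contain a PB backbone")
  if (is.null(bead)) bead <- which(b$name == "PBP")[1]
  nf <- n_frames(traj)
  vapply(seq_len(nf), function(f) {
    xpb <- traj$coords[pb, , f]
    cen <- colMeans(xpb)
    ax <- svd(sweep(xpb, 2, cen))$v[, 1]
    if (ax[3] < 0) ax <- -ax
    sum((traj$coords[bead, , f] - cen) * ax)
  }, numeric(1))
}

#' Time-averaged 1D mean-squared displacement
#'
#' MSD(lag) averaged over all frame pairs at each lag, along one axis, for
#' lags up to `max_lag_frac` of the trajectory length.
#'
#' @param traj A `bd_trajectory`, or a frames x 3 coordinate matrix.
#' @param bead Bead index (for a trajectory input).
#' @param axis 1, 2 or 3 (x, y, z).
#' @param times Frame times in ns (taken from the trajectory if omitted).
#' @param max_lag_frac Largest lag as a fraction of the trajectory length.
#' @return A data.frame of class `msd_curve` with `lag` (ns), `msd` (A^2),
#'   `n_pairs`.
#' @export
msd_1d <- function(traj, bead = 1, axis = 3, times = NULL,
                   max_lag_frac = 0.25) {
  xs <- .bead_series(traj, bead)[, axis]
  if (is.null(times)) {
    if (!inherits(traj, "bd_trajectory")) {
      stop("times must be supplied for a plain coordinate input")
    }
    times <- traj$times
  }
  nf <- length(xs)
  if (nf < 2) stop("invalid trajectory: need at least 2 frames")
  dtv <- diff(times)
  if (max(abs(dtv - dtv[1])) > 1e-9 * max(abs(dtv))) {
    stop("invalid trajectory: non-uniform sampling interval")
  }
  dt <- dtv[1]
  max_lag <- max(1L, floor(nf * max_lag_frac))
  lag <- seq_len(max_lag)
  msd <- vapply(lag, function(m) mean((xs[seq_len(nf - m) + m] -
                                         xs[seq_len(nf - m)])^2), numeric(1))
  structure(
    data.frame(lag = lag * dt, msd = msd, n_pairs = nf - lag),
    class = c("msd_curve", "data.frame")
  )
}

#' Apparent 1D diffusion coefficient from an MSD curve
#'
#' Weighted least-squares fit of MSD = 2 D lag over a lag window (weights
#' proportional to the number of frame pairs per lag); D = slope / 2.
#' When multiple replica curves are supplied, D is estimated per replica
#' and the spread across replicas gives the standard error.
#'
#' @param msd An `msd_curve`, or a list of them (replicas).
#' @param fit_window Lag interval in ns, `c(lo, hi)`; defaults to the
#'   central 10-50% span of available lags.
#' @param intercept Allow a free intercept in the fit.
#' @return A list with `D` (A^2/ns), `se`, `n_replicas`, `fit_window`.
#' @export
apparent_d1d <- function(msd, fit_window = NULL, intercept = TRUE) {
  one <- function(m) {
    if (is.null(fit_window)) {
      fit_window <- c(max(m$lag[1], 0.1 * max(m$lag)), 0.5 * max(m$lag))
    }
    sel <- m$lag >= fit_window[1] & m$lag <= fit_window[2]
    if (sum(sel) < 5) stop("fit window contains fewer than 5 lags")
    fit <- if (intercept) {
      lm(msd ~ lag, data = m[sel, ], weights = m$n_pairs[sel])
    } else {
      lm(msd ~ lag + 0, data = m[sel, ], weights = m$n_pairs[sel])
    }
    sl <- coef(fit)[["lag"]]
    if (sl < 0) {
      warning("negative fitted MSD slope (", format(sl, digits = 3),
              "); reporting as-is")
    }
    list(D = sl / 2, window = fit_window)
  }
  if (inherits(msd, "msd_curve")) {
    r <- one(msd)
    return(list(D = r$D, se = NA_real_, n_replicas = 1L,
                fit_window = r$window))
  }
  fits <- lapply(msd, one)
  Ds <- vapply(fits, `[[`, numeric(1), "D")
  list(D = mean(Ds), se = sd(Ds) / sqrt(length(Ds)),
       n_replicas = length(Ds), fit_window = fits[[1]]$window)
}

#' Rotation-translation coupling of sliding
#'
#' Regresses the protein center's axial position z against its unwrapped
#' azimuthal angle phi about the DNA axis. Rotation-coupled sliding on an
#' ideal helical track gives slope = pitch / 2 pi = 5.38 A/rad with
#' correlation 1.
#'
#' @param traj A `bd_trajectory`, or a frames x 3 matrix of protein-center
#'   positions.
#' @param bead Bead index used as the protein center (trajectory input).
#' @param bound Optional logical vector selecting analyzed (bound) frames.
#' @return A list with `slope` (A/rad), `correlation`, `n_frames`.
#' @export
rotation_coupling <- function(traj, bead = NULL, bound = NULL) {
  if (inherits(traj, "bd_trajectory") && is.null(bead)) {
    bead <- which(traj$system$beads$name == "PBP")[1]
  }
  xyz <- .bead_series(traj, bead)
  if (!is.null(bound)) {
    if (!any(bound)) stop("no bound frames to analyze")
    xyz <- xyz[bound, , drop = FALSE]
  }
  phi_raw <- atan2(xyz[, 2], xyz[, 1])
  dphi <- diff(phi_raw)
  dphi <- ifelse(dphi > pi, dphi - 2 * pi,
                 ifelse(dphi < -pi, dphi + 2 * pi, dphi))
  phi <- cumsum(c(phi_raw[1], dphi))
  z <- xyz[, 3]
  if (sd(phi) == 0) {
    return(list(slope = NA_real_, correlation = NA_real_,
                n_frames = nrow(xyz)))
  }
  fit <- lm(z ~ phi)
  list(slope = unname(coef(fit)[2]),
       correlation = suppressWarnings(stats::cor(z, phi)),
       n_frames = nrow(xyz))
}

#' Detect hopping events (microscopic detachments)
#'
#' An event opens when the minimum DBP-to-PP center distance exceeds
#' `r_off` for at least `min_duration`, and closes on re-approach. The
#' default threshold is the 40 A nonbonded cutoff: beyond it the protein
#' feels no DNA attraction, an unambiguous detachment.
#'
#' @param traj A `bd_trajectory` of a protein + DNA system.
#' @param r_off Detachment threshold in A.
#' @param min_duration Minimum event duration in ns.
#' @return A data.frame with one row per event: `start`, `end` (ns),
#'   `z_before`, `z_after`, `max_dist` (A).
#' @export
detect_hops <- function(traj, r_off = 40, min_duration = 0) {
  b <- traj$system$beads
  dbp <- which(b$name == "DBP")
  pp <- which(b$name == "PP")
  if (length(dbp) == 0 || length(pp) == 0) {
    stop("trajectory must contain DBP and PP beads")
  }
  nf <- n_frames(traj)
  mind <- numeric(nf)
  zc <- numeric(nf)
  for (f in seq_len(nf)) {
    xp <- traj$coords[pp, , f]
    dmin <- Inf
    for (d in dbp) {
      dd <- sqrt(rowSums((xp - matrix(traj$coords[d, , f], length(pp), 3,
                                      byrow = TRUE))^2))
      dmin <- min(dmin, dd)
    }
    mind[f] <- dmin
    zc[f] <- mean(traj$coords[dbp, 3, f])
  }
  off <- mind > r_off
  events <- list()
  f <- 1
  while (f <= nf) {
    if (off[f]) {
      g <- f
      while (g < nf && off[g + 1]) g <- g + 1
      dur <- traj$times[g] - traj$times[f]
      if (dur >= min_duration) {
        events[[length(events) + 1]] <- data.frame(
          start = traj$times[f], end = traj$times[g],
          z_before = zc[max(f - 1, 1)], z_after = zc[min(g + 1, nf)],
          max_dist = max(mind[f:g]))
      }
      f <- g + 1
    } else {
      f <- f + 1
    }
  }
  if (length(events) == 0) {
    data.frame(start = numeric(), end = numeric(), z_before = numeric(),
               z_after = numeric(), max_dist = numeric())
  } else {
    do.call(rbind, events)
  }
}

#' DNA persistence length from tangent correlations
#'
#' Fits exp(-n b / Lp) to the backbone tangent autocorrelation
#' <t(s) . t(s+n)> of the PB beads, excluding `trim` residues at each end.
#' Accepts a `dna_ensemble` from [sample_dna_conformations()], a
#' `bd_trajectory` of a DNA system, or a residues x 3 x frames array of PB
#' positions.
#'
#' @param dna_traj Conformational ensemble (see above).
#' @param max_lag Largest tangent separation (residues) in the fit.
#' @param trim Residues excluded at each end.
#' @param rise Residue rise b in A.
#' @return A list with `Lp` (A), `se` (A, from the fit), `correlation`
#'   (data.frame of lag and C(n)). A rigid (non-decaying) ensemble reports
#'   `Lp = Inf` as a lower bound.
#' @export
persistence_length <- function(dna_traj, max_lag = 40, trim = 5,
                               rise = bd_constants$residue_rise) {
  frames <- if (inherits(dna_traj, "dna_ensemble")) {
    dna_traj$pb_frames
  } else if (inherits(dna_traj, "bd_trajectory")) {
    pb <- which(dna_traj$system$beads$name == "PB")
    dna_traj$coords[pb, , , drop = FALSE]
  } else {
    dna_traj
  }
  nres <- dim(frames)[1]
  nf <- dim(frames)[3]
  keep <- (trim + 1):(nres - trim)          # residues entering tangents
  if (length(keep) < max_lag + 2) {
    stop("chain too short for the requested max_lag after trimming")
  }
  corr <- numeric(max_lag)
  cnt <- numeric(max_lag)
  for (f in seq_len(nf)) {
    xyz <- frames[, , f]
    tg <- diff(xyz)
    tg <- tg / sqrt(rowSums(tg^2))
    tg <- tg[keep[keep <= nrow(tg)], , drop = FALSE]
    m <- nrow(tg)
    for (n in seq_len(max_lag)) {
      if (m - n < 1) break
      corr[n] <- corr[n] + sum(tg[seq_len(m - n), ] * tg[seq_len(m - n) + n, ])
      cnt[n] <- cnt[n] + (m - n)
    }
  }
  C <- corr / cnt
  first_bad <- which(C <= 0.05)[1]
  usable <- seq_len(if (is.na(first_bad)) max_lag else first_bad - 1)
  if (length(usable) < 3 || any(C[seq_len(min(3, max_lag))] <= 0)) {
    stop("fit error: tangent correlation non-positive before lag 3 ",
         "(chain too short or stiffness mismatch)")
  }
  if (min(C[usable]) > 0.999) {
    return(list(Lp = Inf, se = NA_real_,
                correlation = data.frame(lag = seq_len(max_lag), C = C)))
  }
  nfit <- usable
  fit <- lm(log(C[nfit]) ~ nfit + 0)
  slope <- coef(fit)[[1]]
  Lp <- -rise / slope
  se <- rise / slope^2 * summary(fit)$coefficients[1, 2]
  list(Lp = Lp, se = se,
       correlation = data.frame(lag = seq_len(max_lag), C = C))
}

#' Center-of-diffusion distance from the DNA axis along a trajectory
#'
#' Maps the protein's body-frame center of diffusion (from rigid-particle
#' theory) into the lab frame at every frame and measures its distance
#' from the DNA axis (Z axis). The body frame is defined by the three
#' protein beads: origin at PBP, x toward the DBP midpoint, z along the
#' DBP-DBP direction.
#'
#' @param traj A `bd_trajectory` containing the 3-bead protein.
#' @param hydro A `rigid_body_hydro` for the same protein (from
#'   [protein_hydro()]); computed from the trajectory's `a_pbp` if omitted.
#' @return A list with `mean`, `sd` (A) and the per-frame distances.
#' @export
roc_from_traj <- function(traj, hydro = NULL) {
  b <- traj$system$beads
  pbp <- which(b$name == "PBP")[1]
  dbp <- which(b$name == "DBP")
  if (length(dbp) != 2 || is.na(pbp)) {
    stop("trajectory must contain the 3-bead protein")
  }
  if (is.null(hydro)) hydro <- protein_hydro(b$stokes[pbp])

  body_frame <- function(xp, xd1, xd2) {
    zax <- xd1 - xd2
    zax <- zax / sqrt(sum(zax^2))
    mid <- (xd1 + xd2) / 2
    xax <- mid - xp
    xax <- xax - sum(xax * zax) * zax
    xax <- xax / sqrt(sum(xax^2))
    yax <- c(zax[2] * xax[3] - zax[3] * xax[2],
             zax[3] * xax[1] - zax[1] * xax[3],
             zax[1] * xax[2] - zax[2] * xax[1])
    cbind(xax, yax, zax)
  }

  ## body-frame coordinates of the center of diffusion from the build
  ref <- build_protein(a_pbp = b$stokes[pbp], q_dbp = 0)$x
  Rb <- body_frame(ref[1, ], ref[2, ], ref[3, ])
  cod_body <- as.numeric(t(Rb) %*% (hydro$cod - ref[1, ]))

  nf <- n_frames(traj)
  d <- numeric(nf)
  for (f in seq_len(nf)) {
    xp <- traj$coords[pbp, , f]
    R <- body_frame(xp, traj$coords[dbp[1], , f], traj$coords[dbp[2], , f])
    lab <- xp + as.numeric(R %*% cod_body)
    d[f] <- sqrt(sum(lab[1:2]^2))
  }
  list(mean = mean(d), sd = sd(d), distances = d)
}
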