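## Configuration files, fixtures, and trajectory/model I/O.

.default_config <- function() {
  list(
    model = list(n_residues = 200, a_pbp = 40, q_dbp = 8, theta0_pb = 180),
    forcefield = list(kex = 1, eps = 78.5, debye_length = 7.8, cutoff = 40,
                      excl_sep = 4, use_dlvo = TRUE),
    protocol = list(dt = 0.25, n_steps = 100000000, tensor_update = 200,
                    sample_interval = 10000, hi_mode = "full_hi",
                    dna_mode = "restrained", temperature = 298,
                    max_disp = 5),
    umbrella = list(r0_max = 90, r0_min = 31, r0_step = 1, k_umb = 5,
                    n_repeats = 5),
    analysis = list(fit_window = c(10, 250), hop_threshold = 40,
                    msd_max_lag_frac = 0.25),
    output = list(prefix = "bdslide"),
    seeds = list(base_seed = 1, n_replicas = 10)
  )
}

.check_keys <- function(user, ref, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(ref)) {
      stop("config error: unknown key '", full, "'")
    }
    if (is.list(ref[[key]]) && !is.null(names(ref[[key]]))) {
      if (!is.null(user[[key]]) && !is.list(user[[key]])) {
        stop("config error: '", full, "' must be a section")
      }
      .check_keys(user[[key]], ref[[key]], full)
    }
  }
}

#' Load a run configuration
#'
#' Reads a YAML configuration, validates it against the known schema
#' (unknown keys are rejected by name) and fills unset values with the
#' reference-protocol defaults (dt = 0.25 ps, cutoff 40 A, eps = 78.5,
#' Debye length 7.8 A, ...). An empty file yields the full default
#' configuration. Resolve -> dump -> load round-trips are idempotent.
#'
#' @param path Path to a YAML file.
#' @return A fully resolved list of class `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config error: file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  ref <- .default_config()
  .check_keys(user, ref)
  merged <- modifyList(ref, user)
  structure(merged, class = "run_config")
}

#' Write a resolved configuration
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Named small test systems
#'
#' Deterministic fixtures: `"bead1"` (one bead, a = 20 A), `"dimer"` (two
#' beads, a = 20 A, 50 A apart), `"dna20"` (20-residue DNA), `"protein40"`
#' (3-bead protein, a(PBP) = 40), `"mini"` (20-residue DNA + protein,
#' 43 beads).
#'
#' @param name Fixture name.
#' @return A `cg_system`.
#' @export
make_fixture <- function(name) {
  single <- function(a, x) {
    structure(
      list(x = matrix(x, 1, 3), beads = data.frame(
        name = "PBP", sigma = a, stokes = a, charge = 0,
        molecule = 1L, residue = 0L),
        bonds = data.frame(i = integer(), j = integer(), k = numeric(),
                           r0 = numeric()),
        angles = data.frame(i = integer(), j = integer(), k = integer(),
                            ka = numeric(), theta0 = numeric()),
        torsions = data.frame(i = integer(), j = integer(), k = integer(),
                              l = integer(), kt = numeric(),
                              phi0 = numeric()),
        meta = list(fixture = TRUE)),
      class = "cg_system")
  }
  switch(
    name,
    bead1 = single(20, c(0, 0, 0)),
    dimer = {
      s <- single(20, c(0, 0, 0))
      s$x <- rbind(s$x, c(50, 0, 0))
      s$beads <- rbind(s$beads, transform(s$beads, molecule = 2L))
      rownames(s$beads) <- NULL
      s
    },
    dna20 = build_dna(20),
    protein40 = build_protein(a_pbp = 40, q_dbp = 8),
    mini = assemble_system(build_dna(20), build_protein(40, 8)),
    stop("unknown fixture name: ", name)
  )
}

#' Export a trajectory as multi-frame XYZ or multi-model PDB
#'
#' XYZ uses the bead name as the element field; PDB writes one MODEL per
#' frame with bead names as atom names and CONECT records for the bonds.
#'
#' @param traj A `bd_trajectory`.
#' @param path Output file path.
#' @param format `"xyz"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(traj, path, format = c("xyz", "pdb")) {
  format <- match.arg(format)
  nf <- n_frames(traj)
  if (nf == 0) stop("empty trajectory")
  names <- traj$system$beads$name
  n <- length(names)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "xyz") {
    for (f in seq_len(nf)) {
      writeLines(c(as.character(n),
                   sprintf("frame %d t= %.6f ns", f, traj$times[f])), con)
      xyz <- traj$coords[, , f]
      writeLines(sprintf("%-4s %12.5f %12.5f %12.5f", names,
                         xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
  } else {
    for (f in seq_len(nf)) {
      writeLines(sprintf("MODEL     %4d", f), con)
      xyz <- traj$coords[, , f]
      writeLines(sprintf(
        "ATOM  %5d %-4s BEA A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        seq_len(n), substr(names, 1, 4),
        traj$system$beads$residue + 1L, xyz[, 1], xyz[, 2], xyz[, 3]), con)
      writeLines("ENDMDL", con)
    }
    if (nrow(traj$system$bonds) > 0) {
      writeLines(sprintf("CONECT%5d%5d", traj$system$bonds$i,
                         traj$system$bonds$j), con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

#' Write a system (model + topology) as a PDB file
#'
#' One bead per ATOM record; bead names in the atom-name and element
#' columns; CONECT records for bonds.
#'
#' @param system A `cg_system`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(system, path) {
  n <- nrow(system$x)
  lines <- c(
    sprintf("ATOM  %5d %-4s BEA A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            seq_len(n), substr(system$beads$name, 1, 4),
            system$beads$residue + 1L,
            system$x[, 1], system$x[, 2], system$x[, 3]),
    if (nrow(system$bonds) > 0) {
      sprintf("CONECT%5d%5d", system$bonds$i, system$bonds$j)
    },
    "END")
  writeLines(lines, path)
  invisible(path)
}

## full-precision number formatting for the native format
.fmt <- function(x) sprintf("%.17g", x)

#' Write a system in the native structured-text format
#'
#' Stores bead specifications, coordinates and all topology tables at full
#' double precision so that a read-back is bit-exact.
#'
#' @param system A `cg_system`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_system <- function(system, path) {
  con <- file(path, "w")
  on.exit(close(con))
  b <- system$beads
  writeLines(c("# bdslide system v1",
               paste("nbeads", nrow(b)),
               paste("nresidues", if (is.null(system$n_residues)) 0
                     else system$n_residues)), con)
  writeLines("[beads] name sigma stokes charge molecule residue x y z", con)
  writeLines(paste(b$name, .fmt(b$sigma), .fmt(b$stokes), .fmt(b$charge),
                   b$molecule, b$residue, .fmt(system$x[, 1]),
                   .fmt(system$x[, 2]), .fmt(system$x[, 3])), con)
  writeLines("[bonds] i j k r0", con)
  if (nrow(system$bonds)) {
    writeLines(paste(system$bonds$i, system$bonds$j, .fmt(system$bonds$k),
                     .fmt(system$bonds$r0)), con)
  }
  writeLines("[angles] i j k ka theta0", con)
  if (nrow(system$angles)) {
    writeLines(paste(system$angles$i, system$angles$j, system$angles$k,
                     .fmt(system$angles$ka), .fmt(system$angles$theta0)),
               con)
  }
  writeLines("[torsions] i j k l kt phi0", con)
  if (nrow(system$torsions)) {
    writeLines(paste(system$torsions$i, system$torsions$j,
                     system$torsions$k, system$torsions$l,
                     .fmt(system$torsions$kt), .fmt(system$torsions$phi0)),
               con)
  }
  invisible(path)
}

#' Read a system written by [write_system()]
#'
#' @param path Path to a native system file.
#' @return A `cg_system`.
#' @export
read_system <- function(path) {
  lines <- readLines(path)
  sec <- function(tag) {
    start <- grep(paste0("^\\[", tag, "\\]"), lines)
    if (length(start) != 1) stop("corrupt system file: missing ", tag)
    stops <- c(grep("^\\[", lines), length(lines) + 1)
    end <- min(stops[stops > start]) - 1
    if (end < start + 1) return(character())
    lines[(start + 1):end]
  }
  nres <- as.integer(strsplit(lines[3], " ")[[1]][2])
  bl <- strsplit(sec("beads"), " ")
  beads <- data.frame(
    name = vapply(bl, `[[`, "", 1),
    sigma = as.numeric(vapply(bl, `[[`, "", 2)),
    stokes = as.numeric(vapply(bl, `[[`, "", 3)),
    charge = as.numeric(vapply(bl, `[[`, "", 4)),
    molecule = as.integer(vapply(bl, `[[`, "", 5)),
    residue = as.integer(vapply(bl, `[[`, "", 6)),
    stringsAsFactors = FALSE)
  x <- cbind(as.numeric(vapply(bl, `[[`, "", 7)),
             as.numeric(vapply(bl, `[[`, "", 8)),
             as.numeric(vapply(bl, `[[`, "", 9)))
  parse_tab <- function(tag, cols, ints) {
    rows <- strsplit(sec(tag), " ")
    if (length(rows) == 0) {
      out <- as.data.frame(setNames(rep(list(numeric()), length(cols)),
                                    cols))
      for (cc in ints) out[[cc]] <- integer()
      return(out)
    }
    out <- as.data.frame(do.call(rbind, lapply(rows, as.numeric)))
    names(out) <- cols
    for (cc in ints) out[[cc]] <- as.integer(out[[cc]])
    out
  }
  structure(
    list(x = x, beads = beads,
         bonds = parse_tab("bonds", c("i", "j", "k", "r0"), c("i", "j")),
         angles = parse_tab("angles", c("i", "j", "k", "ka", "theta0"),
                            c("i", "j", "k")),
         torsions = parse_tab("torsions",
                              c("i", "j", "k", "l", "kt", "phi0"),
                              c("i", "j", "k", "l")),
         n_residues = if (nres > 0) nres else NULL,
         meta = list()),
    class = "cg_system"
  )
}
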