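# Core trajectory container and I/O.
#
# Units are fixed package-wide: coordinates and box lengths in nm, times in ps.
# External readers (PDB/GRO/DCD) convert at the boundary.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

#' Classify protein oxygen atoms
#'
#' Pure lookup on `(residue_name, atom_name)` covering the 20 standard amino
#' acids. Backbone carbonyl oxygens (`O`, and the C-terminal `OXT`) are
#' distinguished from side-chain carboxylate oxygens (Asp `OD1`/`OD2`, Glu
#' `OE1`/`OE2`) and from the remaining polar side-chain oxygens (Ser/Thr/Tyr
#' hydroxyls, Asn/Gln amide carbonyls). Anything that is not an oxygen of a
#' standard residue is classified `"none"`.
#'
#' @param residue_name character vector of 3-letter residue codes.
#' @param atom_name character vector of PDB atom names, same length.
#' @return character vector with values in
#'   `c("none", "backbone_carbonyl", "sidechain_carboxylate",
#'      "sidechain_other_polar")`.
#' @export
classify_oxygen <- function(residue_name, atom_name) {
  stopifnot(length(residue_name) == length(atom_name))
  res <- toupper(trimws(residue_name))
  atm <- toupper(trimws(atom_name))
  out <- rep("none", length(res))
  std <- res %in% STANDARD_AA
  out[std & atm %in% c("O", "OXT")] <- "backbone_carbonyl"
  out[res == "ASP" & atm %in% c("OD1", "OD2")] <- "sidechain_carboxylate"
  out[res == "GLU" & atm %in% c("OE1", "OE2")] <- "sidechain_carboxylate"
  out[res == "ASN" & atm == "OD1"] <- "sidechain_other_polar"
  out[res == "GLN" & atm == "OE1"] <- "sidechain_other_polar"
  out[res == "SER" & atm == "OG"]  <- "sidechain_other_polar"
  out[res == "THR" & atm == "OG1"] <- "sidechain_other_polar"
  out[res == "TYR" & atm == "OH"]  <- "sidechain_other_polar"
  out
}

#' Build an atom metadata table
#'
#' @param atom_id integer atom indices (unique).
#' @param residue_id integer residue numbers.
#' @param residue_name 3-letter residue codes.
#' @param atom_name atom names.
#' @param element element symbols; guessed from the atom name when `NULL`.
#' @return data.frame with columns `atom_id`, `residue_id`, `residue_name`,
#'   `atom_name`, `element`, `is_heavy`, `oxygen_class`.
#' @export
atom_meta <- function(atom_id, residue_id, residue_name, atom_name,
                      element = NULL) {
  n <- length(atom_id)
  stopifnot(length(residue_id) == n, length(residue_name) == n,
            length(atom_name) == n)
  if (anyDuplicated(atom_id)) stop("atom_id values must be unique")
  if (is.null(element)) element <- guess_element(atom_name)
  meta <- data.frame(
    atom_id = as.integer(atom_id),
    residue_id = as.integer(residue_id),
    residue_name = toupper(trimws(residue_name)),
    atom_name = toupper(trimws(atom_name)),
    element = toupper(trimws(element)),
    stringsAsFactors = FALSE
  )
  meta$is_heavy <- meta$element != "H"
  meta$oxygen_class <- classify_oxygen(meta$residue_name, meta$atom_name)
  bad <- meta$oxygen_class != "none" & meta$element != "O"
  if (any(bad)) stop("oxygen_class != 'none' assigned to a non-oxygen atom")
  meta
}

# Element from an atom name: strip digits, first letter, with the usual
# two-letter exceptions that occur in protein/ion systems.
guess_element <- function(atom_name) {
  nm <- toupper(trimws(atom_name))
  stripped <- gsub("[0-9'+-]", "", nm)
  two <- c("CL", "NA", "MG", "ZN", "FE", "BR", "MN")
  el <- substr(stripped, 1, 1)
  el[stripped %in% two] <- stripped[stripped %in% two]
  # a lone "CA" atom name inside a standard residue is a C-alpha carbon;
  # callers dealing with calcium ions pass element explicitly
  el
}

#' Construct a trajectory object
#'
#' The container used by every analysis step. One protein plus one or more
#' tracked ions, orthorhombic periodic box, uniform time grid.
#'
#' @param times numeric vector of frame times (ps), strictly increasing and
#'   uniformly spaced.
#' @param box per-frame box lengths in nm: an `n_frames x 3` matrix, or a
#'   length-3 vector (constant box), or a scalar (cubic constant box).
#' @param protein_coords protein coordinates in nm. Either an
#'   `n_frames x n_atoms x 3` array, or an `n_atoms x 3` matrix for a protein
#'   that is rigid/static over the whole trajectory.
#' @param ion_coords named list of `n_frames x 3` matrices, one per tracked
#'   ion; names are the ion labels.
#' @param atoms atom metadata data.frame as returned by [atom_meta()]; one row
#'   per protein atom (may have zero rows for protein-free systems).
#' @param dt_tol relative tolerance on time-step uniformity.
#' @return an object of class `"ion_traj"`.
#' @export
ion_trajectory <- function(times, box, protein_coords, ion_coords, atoms,
                           dt_tol = 1e-6) {
  times <- as.numeric(times)
  n <- length(times)
  if (n < 1L) stop("trajectory must contain at least one frame")
  if (n > 1L) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("times must be strictly increasing")
    if (diff(range(dts)) > dt_tol * mean(dts))
      stop("non-uniform time step beyond tolerance; resampling is not supported")
  }
  if (is.null(dim(box))) {
    box <- matrix(rep(as.numeric(box), length.out = 3L), nrow = n, ncol = 3L,
                  byrow = TRUE)
  }
  box <- as.matrix(box)
  if (nrow(box) != n || ncol(box) != 3L)
    stop("box must be n_frames x 3 (or a constant length-3 / scalar)")
  if (any(box <= 0)) stop("box lengths must be positive")

  static <- is.matrix(protein_coords)
  if (static) {
    if (nrow(protein_coords) != nrow(atoms))
      stop("protein_coords rows must match atom metadata rows")
  } else if (length(protein_coords) == 0L && nrow(atoms) == 0L) {
    static <- TRUE
    protein_coords <- matrix(numeric(0), 0L, 3L)
  } else {
    d <- dim(protein_coords)
    if (length(d) != 3L || d[1] != n || d[2] != nrow(atoms) || d[3] != 3L)
      stop("protein_coords must be n_frames x n_atoms x 3 (or n_atoms x 3 if static)")
  }

  if (!is.list(ion_coords) || is.null(names(ion_coords)) ||
      any(names(ion_coords) == ""))
    stop("ion_coords must be a named list of per-ion coordinate matrices")
  ion_coords <- lapply(ion_coords, function(m) {
    m <- as.matrix(m)
    if (nrow(m) != n || ncol(m) != 3L)
      stop("each ion coordinate matrix must be n_frames x 3")
    storage.mode(m) <- "double"
    dimnames(m) <- NULL
    m
  })

  structure(
    list(times = times, box = box, protein_coords = protein_coords,
         ion_coords = ion_coords, atoms = atoms, static_protein = static),
    class = "ion_traj"
  )
}

#' @export
print.ion_traj <- function(x, ...) {
  n <- length(x$times)
  cat("ion_traj:", n, "frames,", nrow(x$atoms), "protein atoms,",
      length(x$ion_coords), "ion(s) [", paste(names(x$ion_coords),
      collapse = ", "), "]\n")
  if (n > 1L)
    cat("  dt =", format(x$times[2] - x$times[1]), "ps, span",
        format(x$times[n] - x$times[1]), "ps\n")
  cat("  box (frame 1):", paste(format(x$box[1, ]), collapse = " x "), "nm",
      if (x$static_protein) " | protein: static\n" else "\n")
  invisible(x)
}

#' Number of frames of a trajectory
#' @param traj an `ion_traj` object.
#' @export
n_frames <- function(traj) length(traj$times)

#' Time step of a trajectory (ps)
#' @param traj an `ion_traj` object.
#' @export
time_step <- function(traj) {
  if (length(traj$times) < 2L) stop("time step undefined for a single frame")
  traj$times[2] - traj$times[1]
}

# protein coordinates for one frame as an n_atoms x 3 matrix
protein_frame <- function(traj, i) {
  if (traj$static_protein) traj$protein_coords
  else {
    m <- traj$protein_coords[i, , , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 3L)
    m
  }
}

#' Analysis configuration
#'
#' Bundles the tunable parameters shared by the shell, residence, diffusion
#' and encounter stages.
#'
#' @param shell_boundaries outer shell boundaries from the protein surface
#'   (nm), strictly increasing. The default follows the 2.5 Angstrom shell
#'   scheme: first shell below 0.35 nm, then consecutive 0.25 nm layers out
#'   to 2.1 nm; beyond the last boundary is bulk.
#' @param contact_cutoff ion-atom distance defining a residue contact (nm).
#' @param grace_time short-excursion bridging time (ps): interruptions of a
#'   residence (or contact) no longer than this are not counted as
#'   termination.
#' @param msd_fit_window lag-time window (ps) for the linear MSD fit.
#' @param min_fit_count survival-curve points with counts at or below this
#'   value are excluded from exponential fitting.
#' @param heavy_atoms_only if `TRUE` hydrogens are ignored in all distance
#'   work.
#' @param seed integer seed forwarded to any stochastic step.
#' @return list of class `"analysis_config"`.
#' @export
analysis_config <- function(shell_boundaries = c(0.35, 0.60, 0.85, 1.10,
                                                 1.35, 1.60, 1.85, 2.10),
                            contact_cutoff = 0.35,
                            grace_time = 2,
                            msd_fit_window = c(10, 100),
                            min_fit_count = 10L,
                            heavy_atoms_only = TRUE,
                            seed = 1L) {
  if (any(diff(shell_boundaries) <= 0))
    stop("shell_boundaries must be strictly increasing")
  if (grace_time < 0) stop("grace_time must be >= 0")
  if (min_fit_count < 1L) stop("min_fit_count must be >= 1")
  if (length(msd_fit_window) != 2L || msd_fit_window[1] >= msd_fit_window[2])
    stop("msd_fit_window must be (lo, hi) with lo < hi")
  structure(list(shell_boundaries = shell_boundaries,
                 contact_cutoff = contact_cutoff,
                 grace_time = grace_time,
                 msd_fit_window = msd_fit_window,
                 min_fit_count = as.integer(min_fit_count),
                 heavy_atoms_only = heavy_atoms_only,
                 seed = as.integer(seed)),
            class = "analysis_config")
}
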