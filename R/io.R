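# Readers for standard structure/trajectory formats and the internal tabular
# trajectory format.
#
# PDB topologies and DCD coordinate sets go through bio3d (Angstrom in, nm
# out). GRO files are parsed directly (fixed-column text; nm native).
# XTC/TRR are not supported and are refused with a clear error.

#' Load a trajectory from standard files
#'
#' Reads a topology (PDB or GRO), optionally a coordinate trajectory (DCD, or
#' a multi-model PDB used as its own trajectory), splits the tracked ion(s)
#' from the protein and derives atom metadata, including the oxygen
#' classification used by the per-atom encounter bookkeeping.
#'
#' @param topology_path path to a `.pdb` or `.gro` file.
#' @param trajectory_path optional path to a `.dcd` file; if `NULL`, the
#'   frames of the topology file itself (1 for GRO, all MODELs for PDB) are
#'   used.
#' @param ion_selection residue name(s) identifying the tracked ion(s),
#'   e.g. `"CA"` for a calcium ion. Matched against residues that are not
#'   standard amino acids, so a calcium ion named CA is not confused with
#'   C-alpha atoms.
#' @param dt frame spacing in ps for trajectory formats that do not store
#'   times (DCD, multi-model PDB).
#' @param box optional override of the box lengths (nm, scalar or length 3)
#'   when the files carry no box information.
#' @param ion_element element symbol recorded for the ion atoms.
#' @return an [ion_trajectory()] object.
#' @export
load_trajectory <- function(topology_path, trajectory_path = NULL,
                            ion_selection = "CA", dt = 1, box = NULL,
                            ion_element = "CA") {
  if (!file.exists(topology_path)) stop("topology file not found: ",
                                        topology_path)
  ext <- tolower(tools::file_ext(topology_path))
  top <- switch(ext,
    pdb = read_pdb_topology(topology_path),
    gro = read_gro(topology_path),
    stop("unsupported topology format '.", ext, "' (use PDB or GRO)"))

  if (!is.null(trajectory_path)) {
    text <- tolower(tools::file_ext(trajectory_path))
    if (text %in% c("xtc", "trr"))
      stop("XTC/TRR trajectories are not supported; convert to DCD or to ",
           "the internal tabular format (see write_internal)")
    if (text != "dcd")
      stop("unsupported trajectory format '.", text, "' (use DCD)")
    if (!file.exists(trajectory_path))
      stop("trajectory file not found: ", trajectory_path)
    dcd <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
    # read.dcd returns frames x (x1 y1 z1 x2 ...) in Angstrom; reshape to nm
    coords <- aperm(array(t(dcd) / 10, dim = c(3L, ncol(dcd) / 3L, nrow(dcd))),
                    c(3L, 2L, 1L))
    if (dim(coords)[2] != nrow(top$meta))
      stop("atom-count mismatch: topology has ", nrow(top$meta),
           " atoms, trajectory has ", dim(coords)[2])
  } else {
    coords <- top$coords  # n_frames x n_atoms x 3
  }

  n <- dim(coords)[1]
  times <- (seq_len(n) - 1) * dt

  if (is.null(box)) box <- top$box
  if (is.null(box))
    stop("no box information in input files; pass `box=` explicitly")

  meta <- top$meta
  is_ion <- meta$residue_name %in% toupper(ion_selection) &
    !(meta$residue_name %in% STANDARD_AA)
  if (!any(is_ion))
    stop("no atom matches ion_selection ",
         paste(sQuote(ion_selection), collapse = ", "))
  ion_idx <- which(is_ion)
  labels <- make.unique(paste0(meta$residue_name[ion_idx],
                               meta$residue_id[ion_idx]), sep = "_")
  ion_coords <- stats::setNames(lapply(ion_idx, function(j) {
    m <- coords[, j, , drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = 3L)
    m
  }), labels)

  prot_idx <- which(!is_ion)
  pmeta <- atom_meta(meta$atom_id[prot_idx], meta$residue_id[prot_idx],
                     meta$residue_name[prot_idx], meta$atom_name[prot_idx],
                     meta$element[prot_idx])
  pc <- coords[, prot_idx, , drop = FALSE]
  # collapse to a static matrix when there is a single frame
  if (n == 1L) pc <- matrix(pc[1, , ], ncol = 3L)
  ion_trajectory(times, box, pc, ion_coords, pmeta)
}

read_pdb_topology <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  a <- pdb$atom
  el <- a$elesy
  if (is.null(el) || all(is.na(el)) || all(trimws(el) == ""))
    el <- guess_element(a$elety)
  el[is.na(el) | trimws(el) == ""] <- guess_element(a$elety)[is.na(el) |
                                                             trimws(el) == ""]
  meta <- data.frame(atom_id = seq_len(nrow(a)),
                     residue_id = as.integer(a$resno),
                     residue_name = toupper(trimws(a$resid)),
                     atom_name = toupper(trimws(a$elety)),
                     element = toupper(trimws(el)),
                     stringsAsFactors = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n <- nrow(xyz)
  coords <- aperm(array(t(xyz) / 10, dim = c(3L, nrow(meta), n)), c(3L, 2L, 1L))
  # CRYST1 parsed from the raw file (not all readers surface it)
  box <- NULL
  cl <- grep("^CRYST1", readLines(path, n = 500L), value = TRUE)
  if (length(cl)) {
    abc <- as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
                        substr(cl[1], 25, 33)))
    abg <- as.numeric(c(substr(cl[1], 34, 40), substr(cl[1], 41, 47),
                        substr(cl[1], 48, 54)))
    if (all(is.finite(abc)) && all(abc > 0)) {
      if (all(is.finite(abg)) && any(abs(abg - 90) > 1e-3))
        stop("triclinic box in CRYST1; only orthorhombic boxes are supported")
      box <- abc / 10
    }
  }
  list(meta = meta, coords = coords, box = box)
}

#' Read a GROMACS .gro structure file
#'
#' Fixed-column single-frame reader (velocities ignored). Coordinates and the
#' box line are native nm. Triclinic boxes (a .gro box line with more than
#' three numbers, any off-diagonal nonzero) are rejected.
#'
#' @param path file path.
#' @return list with `meta` (atom metadata-like data.frame), `coords`
#'   (`1 x n_atoms x 3` array, nm) and `box` (length-3, nm).
#' @export
read_gro <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed GRO file: fewer than 3 lines")
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 1L) stop("malformed GRO file: bad atom count line")
  if (length(lines) < 2L + n + 1L) stop("truncated GRO file")
  al <- lines[3:(2 + n)]
  resno <- as.integer(substr(al, 1, 5))
  resnm <- toupper(trimws(substr(al, 6, 10)))
  atnm <- toupper(trimws(substr(al, 11, 15)))
  x <- as.numeric(substr(al, 21, 28))
  y <- as.numeric(substr(al, 29, 36))
  z <- as.numeric(substr(al, 37, 44))
  if (anyNA(c(x, y, z))) stop("malformed GRO coordinate field")
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[3 + n]),
                                               "\\s+")[[1]]))
  if (length(boxv) < 3L || anyNA(boxv[1:3]))
    stop("malformed GRO box line")
  if (length(boxv) > 3L && any(abs(boxv[-(1:3)]) > 1e-12))
    stop("triclinic box in GRO file; only orthorhombic boxes are supported")
  meta <- data.frame(atom_id = seq_len(n), residue_id = resno,
                     residue_name = resnm, atom_name = atnm,
                     element = guess_element(atnm), stringsAsFactors = FALSE)
  coords <- array(0, dim = c(1L, n, 3L))
  coords[1, , ] <- cbind(x, y, z)
  list(meta = meta, coords = coords, box = boxv[1:3])
}

# ---------------------------------------------------------------------------
# Internal tabular trajectory format (plain text, diffable):
#
#   # ionshells trajectory v1
#   # n_frames: <N>   # n_atoms: <M>   # n_ions: <K>  (one per line)
#   # static_protein: TRUE|FALSE
#   # ions: <label> <label> ...
#   # atoms:
#   <M metadata lines: atom_id residue_id residue_name atom_name element
#      is_heavy oxygen_class>
#   [static protein: one block of M coordinate lines after "# static_coords:"]
#   then per frame:
#   FRAME <time> <bx> <by> <bz>
#   <M protein coordinate lines "x y z">      (omitted if static_protein)
#   ION <label> <x> <y> <z>                    (K lines)
#
# All floats are written with %.9f, making the round trip exact to 1e-9 nm.
# ---------------------------------------------------------------------------

fmt9 <- function(x) sprintf("%.9f", x)

#' Write a trajectory in the internal tabular format
#'
#' @param traj an `ion_traj` object with at least one frame.
#' @param path output file path.
#' @return invisibly, `path`.
#' @seealso [read_internal()]
#' @export
write_internal <- function(traj, path) {
  stopifnot(inherits(traj, "ion_traj"))
  n <- n_frames(traj)
  if (n == 0L) stop("refusing to write an empty trajectory")
  m <- nrow(traj$atoms)
  k <- length(traj$ion_coords)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# ionshells trajectory v1")
  w("# n_frames: ", n)
  w("# n_atoms: ", m)
  w("# n_ions: ", k)
  w("# static_protein: ", traj$static_protein)
  w("# ions: ", paste(names(traj$ion_coords), collapse = " "))
  w("# atoms:")
  if (m > 0L) {
    a <- traj$atoms
    writeLines(paste(a$atom_id, a$residue_id, a$residue_name, a$atom_name,
                     a$element, a$is_heavy, a$oxygen_class), con)
  }
  if (traj$static_protein && m > 0L) {
    w("# static_coords:")
    pc <- traj$protein_coords
    writeLines(paste(fmt9(pc[, 1]), fmt9(pc[, 2]), fmt9(pc[, 3])), con)
  }
  for (i in seq_len(n)) {
    w("FRAME ", fmt9(traj$times[i]), " ", fmt9(traj$box[i, 1]), " ",
      fmt9(traj$box[i, 2]), " ", fmt9(traj$box[i, 3]))
    if (!traj$static_protein && m > 0L) {
      pc <- protein_frame(traj, i)
      writeLines(paste(fmt9(pc[, 1]), fmt9(pc[, 2]), fmt9(pc[, 3])), con)
    }
    for (lab in names(traj$ion_coords)) {
      xi <- traj$ion_coords[[lab]][i, ]
      w("ION ", lab, " ", fmt9(xi[1]), " ", fmt9(xi[2]), " ", fmt9(xi[3]))
    }
  }
  invisible(path)
}

#' Read a trajectory written by [write_internal()]
#'
#' @param path file path.
#' @return an `ion_traj` object.
#' @export
read_internal <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 7L || lines[1] != "# ionshells trajectory v1")
    stop("malformed header: not an ionshells internal trajectory")
  hval <- function(key) {
    i <- grep(paste0("^# ", key, ":"), lines[1:8])
    if (!length(i)) stop("malformed header: missing '", key, "'")
    trimws(sub(paste0("^# ", key, ":"), "", lines[i[1]]))
  }
  n <- as.integer(hval("n_frames"))
  m <- as.integer(hval("n_atoms"))
  k <- as.integer(hval("n_ions"))
  static <- as.logical(hval("static_protein"))
  labels <- strsplit(hval("ions"), "\\s+")[[1]]
  if (n < 1L) stop("empty trajectory (0 frames)")
  if (length(labels) != k) stop("malformed header: ion label count mismatch")
  cur <- grep("^# atoms:", lines)[1] + 1L

  atoms <- if (m > 0L) {
    fl <- strsplit(lines[cur:(cur + m - 1L)], "\\s+")
    am <- do.call(rbind, fl)
    atom_meta(as.integer(am[, 1]), as.integer(am[, 2]), am[, 3], am[, 4],
              am[, 5])
  } else atom_meta(integer(0), integer(0), character(0), character(0),
                   character(0))
  cur <- cur + m

  parse_xyz <- function(ls) {
    v <- as.numeric(unlist(strsplit(trimws(ls), "\\s+")))
    matrix(v, ncol = 3L, byrow = TRUE)
  }

  static_pc <- NULL
  if (static && m > 0L) {
    if (!grepl("^# static_coords:", lines[cur])) stop("malformed header: ",
      "expected static_coords block")
    static_pc <- parse_xyz(lines[(cur + 1L):(cur + m)])
    cur <- cur + m + 1L
  }

  times <- numeric(n); box <- matrix(0, n, 3L)
  pc <- if (!static && m > 0L) array(0, dim = c(n, m, 3L)) else NULL
  ions <- stats::setNames(lapply(labels, function(l) matrix(0, n, 3L)), labels)
  for (i in seq_len(n)) {
    if (cur > length(lines) || !startsWith(lines[cur], "FRAME "))
      stop("truncated frame block at frame ", i)
    hv <- as.numeric(strsplit(lines[cur], "\\s+")[[1]][-1])
    times[i] <- hv[1]; box[i, ] <- hv[2:4]
    cur <- cur + 1L
    if (!static && m > 0L) {
      if (cur + m - 1L > length(lines)) stop("truncated frame block at frame ", i)
      pc[i, , ] <- parse_xyz(lines[cur:(cur + m - 1L)])
      cur <- cur + m
    }
    for (j in seq_len(k)) {
      if (cur > length(lines) || !startsWith(lines[cur], "ION "))
        stop("truncated frame block at frame ", i)
      fv <- strsplit(lines[cur], "\\s+")[[1]]
      lab <- fv[2]
      if (!lab %in% labels) stop("unknown ion label in frame ", i, ": ", lab)
      ions[[lab]][i, ] <- as.numeric(fv[3:5])
      cur <- cur + 1L
    }
  }
  prot <- if (m == 0L) matrix(numeric(0), 0L, 3L)
          else if (static) static_pc else pc
  ion_trajectory(times, box, prot, ions, atoms)
}
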