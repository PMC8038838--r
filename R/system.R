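#' @title Molecular system and trajectory containers
#' @description Lightweight S3 containers shared by every analysis in the
#'   package. Internal units are nanometres for coordinates and picoseconds
#'   for time throughout, matching GROMACS conventions.
#' @name memtraj-containers
NULL

#' Construct a MolecularSystem from an atom table
#'
#' A \code{MolecularSystem} holds the atom table (one row per atom, in file
#' order) and a derived residue table. Residues are distinguished by the
#' combination of chain, author residue number and insertion code, so
#' insertion-coded residues are kept apart even when they share a number.
#'
#' @param atoms data.frame with columns \code{name}, \code{element},
#'   \code{residue_name}, \code{residue_seq}, \code{chain}, \code{icode}.
#'   Missing \code{chain}/\code{icode} columns are filled with \code{""}.
#'   A \code{group_role} column is added (default \code{"other"}) if absent.
#' @return object of class \code{MolecularSystem}: a list with elements
#'   \code{atoms} (with 0-based \code{index} and \code{residue_index}
#'   columns added), \code{residues} (per-residue table with 0-based
#'   first/last atom indices) and \code{n_protein_residues}.
#' @export
molecular_system <- function(atoms) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  need <- c("name", "element", "residue_name", "residue_seq")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  }
  if (is.null(atoms$chain)) atoms$chain <- ""
  if (is.null(atoms$icode)) atoms$icode <- ""
  atoms$chain[is.na(atoms$chain)] <- ""
  atoms$icode[is.na(atoms$icode)] <- ""
  if (is.null(atoms$group_role)) atoms$group_role <- "other"
  atoms$name <- trimws(atoms$name)
  atoms$residue_name <- trimws(atoms$residue_name)
  atoms$index <- seq_len(nrow(atoms)) - 1L

  # residue identity = (chain, seq, icode); new residue whenever the triple
  # changes between consecutive atoms (file order), so residue_index is
  # non-decreasing by construction
  key <- paste(atoms$chain, atoms$residue_seq, atoms$icode, sep = "\r")
  newres <- c(TRUE, key[-1] != key[-length(key)])
  atoms$residue_index <- cumsum(newres) - 1L

  first <- which(newres)
  last <- c(first[-1] - 1L, nrow(atoms))
  residues <- data.frame(
    residue_index = atoms$residue_index[first],
    name = atoms$residue_name[first],
    seq = atoms$residue_seq[first],
    icode = atoms$icode[first],
    chain = atoms$chain[first],
    first = first - 1L,
    last = last - 1L,
    stringsAsFactors = FALSE
  )
  sys <- structure(
    list(atoms = atoms, residues = residues, n_protein_residues = 0L),
    class = "MolecularSystem"
  )
  sys$n_protein_residues <- sum(residue_roles(sys) == "protein")
  sys
}

#' @export
print.MolecularSystem <- function(x, ...) {
  cat("MolecularSystem:", nrow(x$atoms), "atoms,", nrow(x$residues),
      "residues,", x$n_protein_residues, "protein residues\n")
  tab <- table(x$atoms$group_role)
  cat("  group roles:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

# dominant group role per residue (first atom's role; roles are assigned
# per-residue for everything except lipids, where tail/head split a residue)
residue_roles <- function(system) {
  system$atoms$group_role[system$residues$first + 1L]
}

#' Atom indices (0-based) of one residue
#'
#' @param system MolecularSystem
#' @param residue_index 0-based residue index
#' @param heavy_only drop hydrogens
#' @return integer vector of 0-based atom indices
#' @export
residue_atoms <- function(system, residue_index, heavy_only = FALSE) {
  r <- system$residues[system$residues$residue_index == residue_index, ]
  if (nrow(r) != 1) stop("no residue with residue_index ", residue_index)
  idx <- seq.int(r$first, r$last)
  if (heavy_only) {
    idx <- idx[system$atoms$element[idx + 1L] != "H"]
  }
  idx
}

#' Atom indices (0-based) of a particle group
#'
#' @param system MolecularSystem
#' @param role one of the group roles (\code{"protein"}, \code{"water"},
#'   \code{"lipid_tail"}, \code{"lipid_other"}, \code{"ion"},
#'   \code{"ligand"}, \code{"other"})
#' @param heavy_only drop hydrogens
#' @return integer vector of 0-based atom indices
#' @export
group_atoms <- function(system, role, heavy_only = FALSE) {
  idx <- which(system$atoms$group_role == role) - 1L
  if (heavy_only) idx <- idx[system$atoms$element[idx + 1L] != "H"]
  idx
}

#' Protein residue indices of a system
#'
#' @param system MolecularSystem
#' @return 0-based residue indices whose atoms carry the protein role
#' @export
protein_residues <- function(system) {
  system$residues$residue_index[residue_roles(system) == "protein"]
}

#' Construct a Trajectory
#'
#' @param system MolecularSystem the frames refer to
#' @param coords numeric array \code{c(n_atoms, 3, n_frames)}, nm
#' @param box numeric array \code{c(3, 3, n_frames)} of triclinic box row
#'   vectors, nm
#' @param times numeric vector of frame times, ps, strictly increasing
#' @return object of class \code{Trajectory} with the inferred frame
#'   interval \code{dt} (0, with a warning, for single-frame input)
#' @export
trajectory <- function(system, coords, box, times) {
  stopifnot(inherits(system, "MolecularSystem"))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    stop("coords must be an (n_atoms, 3, n_frames) array")
  }
  if (dim(coords)[1] != nrow(system$atoms)) {
    stop("coordinate count ", dim(coords)[1], " does not match system atom count ",
         nrow(system$atoms))
  }
  nf <- dim(coords)[3]
  if (length(times) != nf) stop("times length does not match frame count")
  if (nf > 1) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("frame times must be strictly increasing")
    dt <- dts[1]
    if (any(abs(dts - dt) > 1e-6 * dt)) {
      stop("non-uniform frame interval: observed spacings ",
           paste(signif(unique(round(dts, 9)), 6), collapse = ", "), " ps")
    }
  } else {
    dt <- 0
    warning("single-frame trajectory: dt undefined, stored as 0")
  }
  structure(list(system = system, coords = coords, box = box,
                 times = as.numeric(times), dt = dt),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", n_frames(x), "frames,", dim(x$coords)[1], "atoms, dt =",
      x$dt, "ps, span", x$times[1], "-", x$times[n_frames(x)], "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj Trajectory
#' @return integer frame count
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame
#'
#' @param traj Trajectory
#' @param i frame number (1-based)
#' @return list with \code{coordinates} (n_atoms x 3, nm), \code{box}
#'   (3 x 3 row vectors, nm) and \code{time} (ps), class \code{Frame}
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  structure(list(coordinates = traj$coords[, , i, drop = TRUE],
                 box = traj$box[, , i, drop = TRUE],
                 time = traj$times[i]),
            class = "Frame")
}

#' Indices of frames at or after a start time
#' @param traj Trajectory
#' @param start_time ps; frames with \code{time >= start_time} are kept
#' @return integer vector of 1-based frame numbers
#' @export
analyzed_frames <- function(traj, start_time = 0) {
  which(traj$times >= start_time - 1e-9)
}

#' Discard the equilibration segment of a trajectory
#'
#' Removes all frames before \code{start_time} (the hard equilibration trim;
#' 50 ns in a typical 100 ns production run).
#'
#' @param traj Trajectory
#' @param start_time ps
#' @return trimmed Trajectory
#' @export
trim_trajectory <- function(traj, start_time) {
  keep <- analyzed_frames(traj, start_time)
  if (length(keep) == 0) stop("start_time ", start_time, " ps is beyond the trajectory")
  if (length(keep) == n_frames(traj)) return(traj)
  suppressWarnings(trajectory(traj$system,
             traj$coords[, , keep, drop = FALSE],
             traj$box[, , keep, drop = FALSE],
             traj$times[keep]))
}

# coordinates of atoms `idx` (1-based) in frame f, always an n x 3 matrix
frame_coords <- function(traj, idx, f) {
  matrix(traj$coords[idx, , f], ncol = 3)
}

# run a block with a private RNG stream, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
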