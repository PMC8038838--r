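#' @title Structure and trajectory readers
#' @description PDB structures (including multi-model files) are read with
#'   bio3d and converted to nm; GRO files are parsed directly (single- and
#'   multi-frame, fixed-column format, velocities ignored); DCD binary
#'   trajectories are read with bio3d and converted from Angstrom.
#' @name memtraj-io
NULL

#' Load a structure file into a MolecularSystem
#'
#' @param path file path
#' @param dialect \code{"pdb"} or \code{"gro"}; guessed from the file
#'   extension when missing
#' @return MolecularSystem (atoms in file order, no group roles assigned);
#'   the first frame's coordinates (nm) are attached as attribute
#'   \code{"frame"} (class \code{Frame})
#' @export
load_structure <- function(path, dialect = c("auto", "pdb", "gro")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "pdb") {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    at <- pdb$atom
    if (nrow(at) == 0) stop("zero atoms in ", path)
    atoms <- data.frame(
      name = at$elety,
      element = ifelse(is.na(at$elesy) | at$elesy == "",
                       guess_element(at$elety), trimws(at$elesy)),
      residue_name = at$resid,
      residue_seq = at$resno,
      chain = ifelse(is.na(at$chain), "", at$chain),
      icode = ifelse(is.na(at$insert), "", at$insert),
      stringsAsFactors = FALSE
    )
    sys <- molecular_system(atoms)
    coords <- cbind(at$x, at$y, at$z) / 10     # Angstrom -> nm
    ext <- apply(coords, 2, function(v) diff(range(v)))
    box <- diag(pmax(ext + 2, 1))               # placeholder box for PBC-free use
    attr(sys, "frame") <- structure(
      list(coordinates = coords, box = box, time = 0), class = "Frame")
    return(sys)
  }
  g <- parse_gro_frames(path, first_only = TRUE)
  fr <- g$frames[[1]]
  sys <- molecular_system(g$atoms)
  attr(sys, "frame") <- structure(
    list(coordinates = fr$coordinates, box = fr$box, time = fr$time),
    class = "Frame")
  sys
}

guess_element <- function(name) {
  nm <- gsub("[0-9'\"]+", "", trimws(name))
  two <- toupper(substr(nm, 1, 2))
  el <- substr(nm, 1, 1)
  known2 <- c("CL", "NA", "MG", "ZN", "FE", "CA", "BR")
  # two-letter elements only when the full stripped name is that element
  ifelse(toupper(nm) %in% known2 & nchar(nm) == 2, two, toupper(el))
}

# parse a (possibly multi-frame) GRO file; returns atoms table (from frame 1)
# and a list of frames with coordinates (nm), box (3x3) and time (ps, NA if
# no "t=" tag in the title line)
parse_gro_frames <- function(path, first_only = FALSE) {
  lines <- readLines(path)
  frames <- list(); atoms <- NULL
  i <- 1L; fno <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat <= 0) {
      stop("GRO parse failure at line ", i + 1L, ": bad atom count")
    }
    if (i + 1L + nat + 1L > length(lines)) {
      stop("GRO parse failure: truncated frame starting at line ", i)
    }
    al <- lines[(i + 2L):(i + 1L + nat)]
    x <- as.numeric(substr(al, 21, 28))
    y <- as.numeric(substr(al, 29, 36))
    z <- as.numeric(substr(al, 37, 44))
    if (anyNA(x) || anyNA(y) || anyNA(z)) {
      stop("GRO parse failure near line ", i + 1L + which(is.na(x + y + z))[1])
    }
    bl <- as.numeric(strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1]])
    box <- gro_box(bl, line = i + 2L + nat)
    tm <- NA_real_
    m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(m) == 1) tm <- as.numeric(sub("t=\\s*", "", m))
    fno <- fno + 1L
    co <- cbind(x, y, z)
    dimnames(co) <- NULL
    frames[[fno]] <- list(coordinates = co, box = box, time = tm)
    if (is.null(atoms)) {
      nm <- trimws(substr(al, 11, 15))
      atoms <- data.frame(
        name = nm,
        element = guess_element(nm),
        residue_name = trimws(substr(al, 6, 10)),
        residue_seq = as.integer(substr(al, 1, 5)),
        chain = "",
        icode = "",
        stringsAsFactors = FALSE
      )
    } else if (nat != nrow(atoms)) {
      stop("GRO frame ", fno, " has ", nat, " atoms; expected ", nrow(atoms))
    }
    i <- i + nat + 3L
    if (first_only) break
  }
  if (is.null(atoms)) stop("zero atoms parsed from ", path)
  list(atoms = atoms, frames = frames)
}

# GROMACS box line: "xx yy zz" or "xx yy zz xy xz yx yz zx zy" (here named
# v1x v2y v3z v1y v1z v2x v2z v3x v3y), row-vector convention
gro_box <- function(b, line = NA) {
  if (length(b) == 3) return(diag(b))
  if (length(b) == 9) {
    m <- matrix(0, 3, 3)
    m[1, 1] <- b[1]; m[2, 2] <- b[2]; m[3, 3] <- b[3]
    m[1, 2] <- b[4]; m[1, 3] <- b[5]
    m[2, 1] <- b[6]; m[2, 3] <- b[7]
    m[3, 1] <- b[8]; m[3, 2] <- b[9]
    return(m)
  }
  stop("GRO parse failure at line ", line, ": bad box line")
}

#' Load a trajectory into the common data model
#'
#' Coordinates are converted to nm regardless of the source convention
#' (PDB and DCD store Angstrom). Multi-frame GRO files carry timestamps in
#' their title lines (\code{t=}), from which the frame interval is inferred
#' and checked for uniformity; multi-model PDB and DCD files carry no
#' usable timestamps, so the frame interval is taken from \code{dt}.
#'
#' @param path file path
#' @param system MolecularSystem the frames must match
#' @param format \code{"multigro"}, \code{"multipdb"} or \code{"dcd"}
#'   (guessed from the extension when \code{"auto"}); \code{"xtc"} and
#'   \code{"trr"} are recognized but unsupported
#' @param dt frame interval, ps, used when the file carries no timestamps
#'   (default 10 ps, the usual save interval)
#' @return Trajectory
#' @export
load_trajectory <- function(path, system,
                            format = c("auto", "multigro", "multipdb", "dcd",
                                       "xtc", "trr"),
                            dt = 10) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gro = "multigro", pdb = "multipdb", dcd = "dcd",
                     xtc = "xtc", trr = "trr",
                     stop("cannot guess trajectory format from '", ext, "'"))
  }
  if (format %in% c("xtc", "trr")) {
    stop("compressed GROMACS binary trajectories (", format,
         ") are not supported; convert to multi-frame GRO, multi-model PDB ",
         "or DCD first (e.g. 'gmx trjconv -f traj.xtc -o traj.gro')")
  }
  nat <- nrow(system$atoms)
  if (format == "multigro") {
    g <- parse_gro_frames(path)
    for (k in seq_along(g$frames)) {
      if (nrow(g$frames[[k]]$coordinates) != nat) {
        stop("frame ", k, " has ", nrow(g$frames[[k]]$coordinates),
             " atoms; system has ", nat)
      }
    }
    nf <- length(g$frames)
    coords <- array(0, c(nat, 3, nf)); box <- array(0, c(3, 3, nf))
    times <- numeric(nf)
    for (k in seq_len(nf)) {
      coords[, , k] <- g$frames[[k]]$coordinates
      box[, , k] <- g$frames[[k]]$box
      times[k] <- g$frames[[k]]$time
    }
    if (anyNA(times)) times <- (seq_len(nf) - 1) * dt
    return(trajectory(system, coords, box, times))
  }
  if (format == "multipdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    nf <- nrow(xyz)
    if (ncol(xyz) != 3 * nat) {
      stop("frame 1 has ", ncol(xyz) / 3, " atoms; system has ", nat)
    }
    coords <- array(0, c(nat, 3, nf))
    for (k in seq_len(nf)) {
      coords[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE) / 10
    }
    box <- array(rep(pdb_placeholder_box(coords), nf), c(3, 3, nf))
    return(trajectory(system, coords, box, (seq_len(nf) - 1) * dt))
  }
  # dcd
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  nf <- nrow(xyz)
  if (ncol(xyz) != 3 * nat) {
    stop("DCD frame 1 has ", ncol(xyz) / 3, " atoms; system has ", nat)
  }
  coords <- array(0, c(nat, 3, nf))
  for (k in seq_len(nf)) {
    coords[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE) / 10
  }
  box <- array(rep(pdb_placeholder_box(coords), nf), c(3, 3, nf))
  trajectory(system, coords, box, (seq_len(nf) - 1) * dt)
}

# generous orthorhombic box for formats that do not record one
pdb_placeholder_box <- function(coords) {
  ext <- apply(coords, 2, function(m) diff(range(m)))
  diag(pmax(ext + 2, 1))
}
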