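#' @title Structure and trajectory writers
#' @name memtraj-io-write
NULL

#' Write a structure snapshot
#'
#' Writes a single frame as PDB (coordinates converted to Angstrom) or GRO
#' (nm). Atom order, names and residue numbering are preserved so a
#' round-trip through \code{\link{load_structure}} reproduces the system to
#' format precision.
#'
#' @param system MolecularSystem
#' @param frame Frame (defaults to the frame attached by
#'   \code{\link{load_structure}})
#' @param path output path
#' @param dialect \code{"pdb"} or \code{"gro"}; guessed from the extension
#' @return \code{path}, invisibly
#' @export
write_structure <- function(system, frame = attr(system, "frame"), path,
                            dialect = c("auto", "pdb", "gro")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  }
  if (is.null(frame)) stop("no frame supplied and none attached to the system")
  at <- system$atoms
  X <- frame$coordinates
  if (dialect == "pdb") {
    ser <- (at$index %% 99999L) + 1L
    nm <- ifelse(nchar(at$name) <= 3, sprintf(" %-3s", at$name),
                 sprintf("%-4s", at$name))
    lines <- sprintf(
      "ATOM  %5d %4s %-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ser, nm, substr(at$residue_name, 1, 4),
      substr(paste0(at$chain, " "), 1, 1),
      at$residue_seq %% 10000L, substr(paste0(at$icode, " "), 1, 1),
      X[, 1] * 10, X[, 2] * 10, X[, 3] * 10, 1, 0, at$element)
    writeLines(c(lines, "END"), path)
  } else {
    writeLines(gro_frame_lines(system, X, frame$box, frame$time,
                               title = "memtraj snapshot"), path)
  }
  invisible(path)
}

gro_frame_lines <- function(system, X, box, time, title = "memtraj") {
  at <- system$atoms
  head <- if (is.na(time)) title else sprintf("%s t= %.5f", title, time)
  body <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                  at$residue_seq %% 100000L,
                  substr(at$residue_name, 1, 5),
                  formatC(substr(at$name, 1, 5), width = 5),
                  (at$index %% 99999L) + 1L,
                  X[, 1], X[, 2], X[, 3])
  if (is_orthorhombic(box)) {
    bl <- sprintf("%10.5f%10.5f%10.5f", box[1, 1], box[2, 2], box[3, 3])
  } else {
    bl <- paste(sprintf("%10.5f", c(box[1, 1], box[2, 2], box[3, 3],
                                    box[1, 2], box[1, 3], box[2, 1],
                                    box[2, 3], box[3, 1], box[3, 2])),
                collapse = "")
  }
  c(head, sprintf("%5d", nrow(at)), body, bl)
}

#' Write a trajectory as a multi-frame GRO file
#'
#' Frame times are recorded in each title line (\code{t=}), so a round trip
#' through \code{\link{load_trajectory}} recovers the frame interval.
#'
#' @param traj Trajectory
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_trajectory_gro <- function(traj, path) {
  out <- vector("list", n_frames(traj))
  for (k in seq_len(n_frames(traj))) {
    out[[k]] <- gro_frame_lines(traj$system, traj$coords[, , k],
                                traj$box[, , k], traj$times[k])
  }
  writeLines(unlist(out), path)
  invisible(path)
}
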