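#' @title Per-residue helicity from i to i+4 backbone hydrogen-bond geometry
#' @description The helicity metric is the mean distance between the
#'   backbone carbonyl oxygen of residue n and the backbone amide nitrogen
#'   of residue n+4, the donor-acceptor pair of the alpha-helical hydrogen
#'   bond. Distances below 0.35 nm indicate a formed hydrogen bond, i.e.
#'   helical structure at residue n. The heavy-atom O...N distance is used
#'   so the metric is defined on structures without hydrogens.
#' @name memtraj-helicity
NULL

# 0-based atom index of a named backbone atom per residue (NA if absent)
backbone_atom_index <- function(system, residues, atom_name) {
  vapply(residues, function(ri) {
    idx <- residue_atoms(system, ri)
    hit <- idx[system$atoms$name[idx + 1L] == atom_name]
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, integer(1))
}

#' Per-residue helicity profile
#'
#' For each protein residue n that has a residue n+4 in the same chain, the
#' minimum-image O(n)...N(n+4) distance is averaged over all analyzed
#' frames (time >= \code{start_time}). Residues with a missing backbone O
#' or N are reported as NA rather than raising an error.
#'
#' @param traj a Trajectory, or a list of Trajectories (replica runs); for
#'   a list, the profile is the mean of per-run mean distances
#' @param residues 0-based protein residue indices (default: all residues
#'   with role \code{protein}, or all residues when no roles are assigned)
#' @param start_time analyze frames with time >= this, ps (default 0)
#' @return data.frame of class \code{HelicityProfile} with columns
#'   \code{residue_index}, \code{residue_seq}, \code{residue_name},
#'   \code{mean_distance} (nm) and \code{n_frames}
#' @export
helicity_profile <- function(traj, residues = NULL, start_time = 0) {
  if (!inherits(traj, "Trajectory") && is.list(traj)) {
    profs <- lapply(traj, helicity_profile, residues = residues,
                    start_time = start_time)
    out <- profs[[1]]
    out$mean_distance <- rowMeans(
      do.call(cbind, lapply(profs, `[[`, "mean_distance")))
    out$n_frames <- Reduce(`+`, lapply(profs, `[[`, "n_frames"))
    return(out)
  }
  sys <- traj$system
  if (is.null(residues)) {
    residues <- protein_residues(sys)
    if (length(residues) == 0) residues <- sys$residues$residue_index
  }
  residues <- sort(residues)
  n <- length(residues)
  if (n < 5) stop("need at least 5 consecutive residues for an i,i+4 metric")
  frames <- analyzed_frames(traj, start_time)
  if (length(frames) == 0) stop("start_time is beyond the trajectory")

  donors <- residues[seq_len(n - 4)]            # residue n (carbonyl O)
  acceptors <- residues[seq_len(n - 4) + 4]     # residue n+4 (amide N)
  # only pairs within one chain and with consecutive numbering
  chain_of <- sys$residues$chain[match(residues, sys$residues$residue_index)]
  ok_pair <- chain_of[seq_len(n - 4)] == chain_of[seq_len(n - 4) + 4] &
    (acceptors - donors == 4L)
  oi <- backbone_atom_index(sys, donors, "O")
  ni <- backbone_atom_index(sys, acceptors, "N")
  valid <- ok_pair & !is.na(oi) & !is.na(ni)

  md <- rep(NA_real_, length(donors))
  if (any(valid)) {
    ov <- oi[valid] + 1L; nv <- ni[valid] + 1L
    acc <- rep(0, sum(valid))
    for (f in frames) {
      D <- frame_coords(traj, ov, f) - frame_coords(traj, nv, f)
      acc <- acc + sqrt(min_image_sqdist(D, traj$box[, , f]))
    }
    md[valid] <- acc / length(frames)
  }
  ri <- match(donors, sys$residues$residue_index)
  structure(data.frame(residue_index = donors,
                       residue_seq = sys$residues$seq[ri],
                       residue_name = sys$residues$name[ri],
                       mean_distance = md,
                       n_frames = length(frames)),
            class = c("HelicityProfile", "data.frame"))
}

#' Classify residues as helical
#'
#' A residue is helical when its mean O(n)...N(n+4) distance lies strictly
#' below the hydrogen-bond threshold.
#'
#' @param profile HelicityProfile
#' @param threshold nm (default 0.35)
#' @return logical vector (NA where the profile is undefined)
#' @export
classify_helical <- function(profile, threshold = 0.35) {
  profile$mean_distance < threshold
}

#' Call helical segments from a per-residue classification
#'
#' Maximal runs of helical residues, tolerating interruptions of up to
#' \code{max_gap} non-helical residues ("primarily helical"), discarding
#' runs shorter than \code{min_length}. NA entries count as non-helical.
#'
#' @param helical logical vector over consecutive residues
#' @param min_length minimum segment length, residues (default 5)
#' @param max_gap largest tolerated interruption, residues (default 2)
#' @return data.frame of class \code{HelixSegments} with 1-based
#'   \code{start}, \code{end} positions into \code{helical}, and
#'   \code{length}
#' @export
call_segments <- function(helical, min_length = 5, max_gap = 2) {
  h <- !is.na(helical) & helical
  empty <- data.frame(start = integer(0), end = integer(0),
                      length = integer(0))
  class(empty) <- c("HelixSegments", "data.frame")
  if (!any(h)) return(empty)
  r <- rle(h)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  true_runs <- which(r$values)
  # merge TRUE runs separated by FALSE runs of length <= max_gap
  seg_start <- starts[true_runs[1]]
  seg_end <- ends[true_runs[1]]
  segs <- list()
  for (k in true_runs[-1]) {
    gap <- starts[k] - seg_end - 1L
    if (gap <= max_gap) {
      seg_end <- ends[k]
    } else {
      segs[[length(segs) + 1L]] <- c(seg_start, seg_end)
      seg_start <- starts[k]; seg_end <- ends[k]
    }
  }
  segs[[length(segs) + 1L]] <- c(seg_start, seg_end)
  m <- do.call(rbind, segs)
  out <- data.frame(start = m[, 1], end = m[, 2],
                    length = m[, 2] - m[, 1] + 1L)
  out <- out[out$length >= min_length, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("HelixSegments", "data.frame")
  out
}

#' Write a helicity profile as TSV
#'
#' @param profile HelicityProfile
#' @param path output path
#' @param threshold helical threshold recorded alongside, nm
#' @return \code{path}, invisibly
#' @export
write_helicity_tsv <- function(profile, path, threshold = 0.35) {
  df <- data.frame(residue_seq = profile$residue_seq,
                   residue_name = profile$residue_name,
                   mean_distance_nm = round(profile$mean_distance, 6),
                   helical = as.integer(classify_helical(profile, threshold)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write helix segments as BED-like intervals
#'
#' Intervals are 0-based half-open over residue positions, BED convention.
#'
#' @param segments HelixSegments
#' @param path output path
#' @param name interval name stem
#' @return \code{path}, invisibly
#' @export
write_segments_bed <- function(segments, path, name = "helix") {
  df <- data.frame(chrom = "protein",
                   start = segments$start - 1L,
                   end = segments$end,
                   name = paste0(name, seq_len(nrow(segments))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
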