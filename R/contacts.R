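#' @title Residue-group contact statistics: proximity, binding events and
#'   residence times
#' @description The central statistics of the package. For each protein
#'   residue and particle group (water, lipid tails, ions, ligand), the
#'   per-frame minimum distance from any residue atom to any group atom
#'   defines a contact when it drops strictly below the cutoff (0.4 nm by
#'   default). Proximity is the fraction of frames in contact; a binding
#'   event is a frame in contact immediately preceded by a frame out of
#'   contact; the residence time of an event is the length of the
#'   consecutive in-contact stretch it starts.
#' @name memtraj-contacts
NULL

#' Per-frame contact series of one residue against one group
#'
#' @param traj Trajectory
#' @param residue 0-based residue index
#' @param group group role name (see \code{\link{assign_groups}})
#' @param cutoff contact cutoff, nm (default 0.4); contact is strict
#'   (distance < cutoff)
#' @param start_time analyze frames with time >= this, ps
#' @param heavy_only use heavy atoms only on both sides (default FALSE:
#'   all atoms)
#' @return list of class \code{ContactSeries}: \code{residue},
#'   \code{group}, \code{distance} (nm per frame), \code{contact}
#'   (logical), \code{cutoff}, \code{dt} (ps), \code{times}
#' @export
contact_series <- function(traj, residue, group, cutoff = 0.4,
                           start_time = 0, heavy_only = FALSE) {
  sys <- traj$system
  ra <- residue_atoms(sys, residue, heavy_only = heavy_only)
  ga <- group_atoms(sys, group, heavy_only = heavy_only)
  if (length(ga) == 0) stop("group '", group, "' contains no atoms")
  frames <- analyzed_frames(traj, start_time)
  A1 <- ra + 1L; B1 <- ga + 1L
  d <- vapply(frames, function(f) {
    sqrt(min(cross_min_sqdist(frame_coords(traj, A1, f),
                              frame_coords(traj, B1, f),
                              traj$box[, , f])))
  }, numeric(1))
  structure(list(residue = residue, group = group, distance = d,
                 contact = d < cutoff, cutoff = cutoff, dt = traj$dt,
                 times = traj$times[frames]),
            class = "ContactSeries")
}

#' Per-molecule contact series of one residue against each group molecule
#'
#' Optional finer-grained mode: one contact series per molecule (residue)
#' of the group, so exchange kinetics of individual molecules can be
#' inspected. The group-level series of \code{\link{contact_series}} is
#' the per-frame minimum over these.
#'
#' @inheritParams contact_series
#' @return named list of \code{ContactSeries}, one per group molecule
#'   (names = group residue indices)
#' @export
contact_series_by_molecule <- function(traj, residue, group, cutoff = 0.4,
                                       start_time = 0, heavy_only = FALSE) {
  sys <- traj$system
  ga <- group_atoms(sys, group, heavy_only = heavy_only)
  if (length(ga) == 0) stop("group '", group, "' contains no atoms")
  mol <- sys$atoms$residue_index[ga + 1L]
  ra <- residue_atoms(sys, residue, heavy_only = heavy_only)
  frames <- analyzed_frames(traj, start_time)
  out <- lapply(split(ga, mol), function(sub) {
    d <- vapply(frames, function(f) {
      sqrt(min(cross_min_sqdist(frame_coords(traj, ra + 1L, f),
                                frame_coords(traj, sub + 1L, f),
                                traj$box[, , f])))
    }, numeric(1))
    structure(list(residue = residue, group = group, distance = d,
                   contact = d < cutoff, cutoff = cutoff, dt = traj$dt,
                   times = traj$times[frames]),
              class = "ContactSeries")
  })
  out
}

#' Proximity of a contact series
#'
#' Fraction of analyzed frames in contact: 1 means the residue always has
#' a group particle within the cutoff, 0 means it never does.
#'
#' @param series ContactSeries (or a logical contact vector)
#' @return proximity in [0, 1]
#' @export
proximity <- function(series) {
  ct <- if (inherits(series, "ContactSeries")) series$contact else series
  if (length(ct) == 0) stop("empty contact series")
  mean(ct)
}

#' Binding events of a contact series
#'
#' One event per out-of-contact to in-contact transition; a series that
#' starts in contact does not count its initial stretch as an event (no
#' preceding unbound frame is observed). Each event's duration is the
#' number of consecutive in-contact frames times the frame interval (the
#' triggering frame counts as one frame). An event still in contact at the
#' final frame is censored; it is counted in \code{n_events} but its true
#' duration is unknown.
#'
#' @param series ContactSeries, or a logical contact vector (then supply
#'   \code{dt})
#' @param dt frame interval, ps (taken from the series when given)
#' @return list: \code{n_events}, \code{durations} (ps, one per event,
#'   censored last included), \code{censored_last} (flag)
#' @export
binding_events <- function(series, dt = NULL) {
  if (inherits(series, "ContactSeries")) {
    ct <- series$contact
    if (is.null(dt)) dt <- series$dt
  } else {
    ct <- series
    if (is.null(dt)) stop("dt required for a bare contact vector")
  }
  if (length(ct) < 2) stop("contact series must have at least 2 frames")
  r <- rle(ct)
  runs <- which(r$values)
  # drop an initial in-contact run: no preceding unbound frame
  runs <- runs[runs > 1]
  durations <- r$lengths[runs] * dt
  censored <- length(runs) > 0 && runs[length(runs)] == length(r$values) &&
    r$values[length(r$values)]
  list(n_events = length(runs), durations = as.numeric(durations),
       censored_last = censored)
}

#' Mean residence time
#'
#' Arithmetic mean of event durations. Censored events (still bound at the
#' final frame) are excluded by default because their durations are lower
#' bounds only.
#'
#' @param durations numeric vector of event durations, ps
#' @param censored_last is the last duration censored?
#' @param include_censored keep censored events in the mean (default FALSE)
#' @return mean residence time, ps; NA when no (usable) events
#' @export
mean_residence_time <- function(durations, censored_last = FALSE,
                                include_censored = FALSE) {
  if (censored_last && !include_censored && length(durations) > 0) {
    durations <- durations[-length(durations)]
  }
  if (length(durations) == 0) return(NA_real_)
  mean(durations)
}

#' Contact statistics of one residue-group pair on one run
#'
#' @inheritParams contact_series
#' @return list of class \code{ContactStats}: \code{P}, \code{n_events},
#'   \code{t_mean} (ps), \code{durations}, \code{censored_last}
#' @export
contact_stats <- function(traj, residue, group, cutoff = 0.4,
                          start_time = 0, heavy_only = FALSE) {
  s <- contact_series(traj, residue, group, cutoff, start_time, heavy_only)
  ev <- binding_events(s)
  structure(list(residue = residue, group = group, P = proximity(s),
                 n_events = ev$n_events,
                 t_mean = mean_residence_time(ev$durations, ev$censored_last),
                 durations = ev$durations, censored_last = ev$censored_last),
            class = "ContactStats")
}

# per-frame minimum distance of every residue in `residues` to the atoms
# in `ga` (1-based), as a (n_residue x n_frames) matrix
residue_group_distance_matrix <- function(traj, residues, ga, frames,
                                          heavy_only = FALSE) {
  sys <- traj$system
  ra_list <- lapply(residues, residue_atoms, system = sys,
                    heavy_only = heavy_only)
  pa <- unlist(ra_list) + 1L
  rid <- rep(seq_along(residues), lengths(ra_list))
  out <- matrix(NA_real_, length(residues), length(frames))
  for (j in seq_along(frames)) {
    f <- frames[j]
    D2 <- cross_min_sqdist(frame_coords(traj, pa, f),
                           frame_coords(traj, ga, f),
                           traj$box[, , f])
    atom_min <- do.call(pmin, c(asplit(D2, 2), list(na.rm = TRUE)))
    out[, j] <- sqrt(tapply(atom_min, rid, min))
  }
  out
}

#' Contact statistics for all residues and groups over replica runs
#'
#' Aggregation over runs follows the replica-averaging convention:
#' proximity is the mean of per-run proximities, the event count is by
#' default the mean number of events per run, and the mean residence time
#' is pooled over all (non-censored) events of all runs.
#'
#' @param trajs list of Trajectory objects (replica runs) sharing one
#'   system definition
#' @param residues 0-based residue indices (default: all protein residues)
#' @param groups group role names (default water, lipid_tail, ion, ligand;
#'   groups with no atoms are skipped with a message)
#' @param cutoff contact cutoff, nm
#' @param start_time equilibration trim, ps
#' @param nb_mode \code{"mean"} (events per run, default) or \code{"sum"}
#' @param heavy_only heavy atoms only
#' @return data.frame with one row per residue x group: \code{residue_index},
#'   \code{residue_seq}, \code{residue_name}, \code{group}, \code{P},
#'   \code{n_events}, \code{t_mean_ps}, \code{n_events_total},
#'   \code{n_censored}
#' @export
contact_stats_all <- function(trajs, residues = NULL,
                              groups = c("water", "lipid_tail", "ion",
                                         "ligand"),
                              cutoff = 0.4, start_time = 0,
                              nb_mode = c("mean", "sum"),
                              heavy_only = FALSE) {
  nb_mode <- match.arg(nb_mode)
  if (inherits(trajs, "Trajectory")) trajs <- list(trajs)
  if (length(trajs) == 0) stop("need at least one trajectory")
  sys <- trajs[[1]]$system
  nat <- nrow(sys$atoms)
  for (tr in trajs) {
    if (nrow(tr$system$atoms) != nat) {
      stop("trajectories have inconsistent systems")
    }
  }
  if (is.null(residues)) residues <- protein_residues(sys)
  if (length(residues) == 0) stop("no protein residues to analyze")
  rows <- list()
  ri <- match(residues, sys$residues$residue_index)
  for (g in groups) {
    ga <- group_atoms(sys, g, heavy_only = heavy_only) + 1L
    if (length(ga) == 0) {
      message("group '", g, "' has no atoms; skipped")
      next
    }
    P <- matrix(0, length(residues), length(trajs))
    nev <- matrix(0, length(residues), length(trajs))
    cens <- matrix(0L, length(residues), length(trajs))
    pooled <- vector("list", length(residues))
    for (k in seq_along(trajs)) {
      tr <- trajs[[k]]
      frames <- analyzed_frames(tr, start_time)
      dm <- residue_group_distance_matrix(tr, residues, ga, frames,
                                          heavy_only = heavy_only)
      ct <- dm < cutoff
      P[, k] <- rowMeans(ct)
      for (i in seq_along(residues)) {
        ev <- binding_events(ct[i, ], dt = tr$dt)
        nev[i, k] <- ev$n_events
        cens[i, k] <- as.integer(ev$censored_last)
        d <- ev$durations
        if (ev$censored_last && length(d) > 0) d <- d[-length(d)]
        pooled[[i]] <- c(pooled[[i]], d)
      }
    }
    rows[[g]] <- data.frame(
      residue_index = residues,
      residue_seq = sys$residues$seq[ri],
      residue_name = sys$residues$name[ri],
      group = g,
      P = rowMeans(P),
      n_events = if (nb_mode == "mean") rowMeans(nev) else rowSums(nev),
      t_mean_ps = vapply(pooled, function(d) {
        if (length(d) == 0) NA_real_ else mean(d)
      }, numeric(1)),
      n_events_total = rowSums(nev),
      n_censored = rowSums(cens),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a contact-statistics table as TSV
#'
#' @param stats data.frame from \code{\link{contact_stats_all}}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_contacts_tsv <- function(stats, path) {
  st <- stats
  num <- vapply(st, is.numeric, logical(1))
  st[num] <- lapply(st[num], function(v) round(v, 6))
  utils::write.table(st, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
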