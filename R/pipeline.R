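#' @title Full per-model analysis pipeline
#' @description Orchestrates the standard replica analysis: load the
#'   structure and the replica trajectories, trim the equilibration
#'   segment, then compute RMSD series, the helicity profile and segments,
#'   contact statistics per particle group and the pore-radius summary,
#'   writing deterministic TSV tables plus a manifest of file hashes.
#' @name memtraj-pipeline
NULL

#' Build a run configuration
#'
#' @param trajectories list of Trajectory objects (replica runs), or
#'   character paths to trajectory files
#' @param structure MolecularSystem, or a structure file path (required
#'   when \code{trajectories} are paths)
#' @param selection SelectionSpec (default
#'   \code{\link{default_selection_spec}}); ignored when group roles are
#'   already assigned
#' @param cutoff contact cutoff, nm (default 0.4)
#' @param helicity_threshold nm (default 0.35)
#' @param trim equilibration trim, ps (default 50000: discard the first
#'   50 ns)
#' @param groups particle groups for contact statistics
#' @param channel list of channel settings: \code{enabled}, \code{dz},
#'   \code{r_max}, \code{stride} (ps), \code{r_open}, \code{membrane_z}
#' @param stages character vector of enabled stages, a subset of
#'   \code{c("rmsd", "helicity", "contacts", "channel")}
#' @param seed integer seed (channel-search restarts)
#' @param out_dir output directory (default: a fresh temporary directory)
#' @return list of class \code{RunConfig}
#' @export
run_config <- function(trajectories, structure = NULL,
                       selection = default_selection_spec(),
                       cutoff = 0.4, helicity_threshold = 0.35,
                       trim = 50000,
                       groups = c("water", "lipid_tail", "ion", "ligand"),
                       channel = list(), stages = c("rmsd", "helicity",
                                                    "contacts", "channel"),
                       seed = 1L, out_dir = NULL) {
  stopifnot(length(trajectories) >= 1, cutoff > 0, helicity_threshold > 0)
  ch <- utils::modifyList(
    list(enabled = TRUE, dz = 0.1, r_max = 1.0, stride = 200,
         r_open = 0.1, membrane_z = NULL, axis = c(0, 0, 1)),
    channel)
  structure(list(trajectories = trajectories, structure = structure,
                 selection = selection, cutoff = cutoff,
                 helicity_threshold = helicity_threshold, trim = trim,
                 groups = groups, channel = ch, stages = stages,
                 seed = as.integer(seed),
                 out_dir = if (is.null(out_dir)) {
                   tempfile("memtraj_out_")
                 } else out_dir),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Recognized keys: \code{structure}, \code{trajectories} (list of
#' paths), \code{cutoff}, \code{helicity_threshold}, \code{trim},
#' \code{groups}, \code{stages}, \code{seed}, \code{out_dir},
#' \code{channel} (mapping) and \code{selection} (rules list, as in
#' \code{\link{read_selection_spec}}).
#'
#' @param path YAML file
#' @return RunConfig
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$trajectories)) stop("config must list trajectories")
  miss <- y$trajectories[!file.exists(unlist(y$trajectories))]
  if (length(miss) > 0) {
    stop("trajectory path(s) not found: ", paste(unlist(miss), collapse = ", "))
  }
  sel <- if (!is.null(y$selection)) selection_spec(y$selection) else
    default_selection_spec()
  args <- list(trajectories = unlist(y$trajectories),
               structure = y$structure, selection = sel)
  for (k in c("cutoff", "helicity_threshold", "trim", "groups", "stages",
              "seed", "out_dir")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$channel)) args$channel <- y$channel
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' Stages run in order load, trim, rmsd, helicity, contacts, channel;
#' disabled stages are skipped without affecting the others. All tables
#' are written as TSV under \code{config$out_dir} and a
#' \code{manifest.tsv} records the MD5 hash of every artifact, so a rerun
#' with the same config and seed is byte-identical.
#'
#' @param config RunConfig
#' @return list of class \code{AnalysisReport}: \code{helicity},
#'   \code{segments}, \code{contacts}, \code{rmsd} (list per run),
#'   \code{channel} (summary data.frame), \code{files}, \code{manifest}
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  trajs <- load_runs(config)
  sys <- trajs[[1]]$system
  report <- list(files = character(0))

  refs <- lapply(trajs, get_frame, i = 1)
  trimmed <- lapply(trajs, function(tr) {
    if (config$trim > 0 && any(tr$times >= config$trim)) {
      trim_trajectory(tr, config$trim)
    } else tr
  })

  if ("rmsd" %in% config$stages) {
    report$rmsd <- vector("list", length(trajs))
    for (k in seq_along(trajs)) {
      rs <- rmsd_timeseries(trajs[[k]], refs[[k]],
                            selection = group_atoms(sys, "protein"))
      report$rmsd[[k]] <- rs
      p <- file.path(config$out_dir, sprintf("rmsd_run%d.tsv", k))
      utils::write.table(round(rs, 6), p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      report$files <- c(report$files, p)
    }
  }

  if ("helicity" %in% config$stages) {
    prof <- helicity_profile(trimmed)
    segs <- call_segments(classify_helical(prof, config$helicity_threshold))
    report$helicity <- prof
    report$segments <- segs
    p1 <- file.path(config$out_dir, "helicity.tsv")
    write_helicity_tsv(prof, p1, config$helicity_threshold)
    p2 <- file.path(config$out_dir, "segments.bed")
    write_segments_bed(segs, p2)
    report$files <- c(report$files, p1, p2)
  }

  if ("contacts" %in% config$stages) {
    stats <- contact_stats_all(trimmed, groups = config$groups,
                               cutoff = config$cutoff)
    report$contacts <- stats
    for (g in unique(stats$group)) {
      p <- file.path(config$out_dir, sprintf("contacts_%s.tsv", g))
      write_contacts_tsv(stats[stats$group == g, ], p)
      report$files <- c(report$files, p)
    }
  }

  if ("channel" %in% config$stages && isTRUE(config$channel$enabled)) {
    ch <- config$channel
    prot <- group_atoms(sys, "protein")
    summ <- list()
    for (k in seq_along(trimmed)) {
      profs <- profile_over_time(trimmed[[k]], prot, stride = ch$stride,
                                 dz = ch$dz, r_max = ch$r_max,
                                 system = sys, axis = ch$axis,
                                 seed = config$seed,
                                 origin = colMeans(get_frame(
                                   trimmed[[k]], 1)$coordinates[prot + 1L,
                                                                1:2,
                                                                drop = FALSE]))
      mz <- ch$membrane_z
      summ[[k]] <- do.call(rbind, lapply(profs, function(pr) {
        span <- if (is.null(mz)) {
          list(spans_membrane = NA)
        } else detect_span(pr, mz, ch$r_open)
        data.frame(run = k, time_ps = attr(pr, "time"),
                   min_radius_nm = min(pr$radius),
                   spans_membrane = span$spans_membrane)
      }))
    }
    report$channel <- do.call(rbind, summ)
    p <- file.path(config$out_dir, "channel_summary.tsv")
    df <- report$channel
    df$min_radius_nm <- round(df$min_radius_nm, 6)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    report$files <- c(report$files, p)
  }

  man <- data.frame(file = basename(report$files),
                    md5 = unname(tools::md5sum(report$files)))
  mp <- file.path(config$out_dir, "manifest.tsv")
  utils::write.table(man, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  report$manifest <- man
  class(report) <- "AnalysisReport"
  report
}

# resolve config$trajectories into Trajectory objects with roles assigned
load_runs <- function(config) {
  tl <- config$trajectories
  if (inherits(tl, "Trajectory")) tl <- list(tl)
  if (is.character(tl)) {
    sys <- if (inherits(config$structure, "MolecularSystem")) {
      config$structure
    } else {
      load_structure(config$structure)
    }
    if (all(sys$atoms$group_role == "other")) {
      sys <- assign_groups(sys, config$selection)
    }
    tl <- lapply(tl, load_trajectory, system = sys)
  } else {
    tl <- lapply(tl, function(tr) {
      if (all(tr$system$atoms$group_role == "other")) {
        tr$system <- assign_groups(tr$system, config$selection,
                                   frame = get_frame(tr, 1))
      }
      tr
    })
  }
  tl
}

#' @export
print.AnalysisReport <- function(x, ...) {
  cat("AnalysisReport with artifacts:\n")
  cat(paste(" -", x$manifest$file, collapse = "\n"), "\n")
  invisible(x)
}

#' Pairwise backbone RMSD between structural models
#'
#' Superposes every model pair on the backbone atoms (N, CA, C, O) of the
#' residues shared by all models (matched by author residue number) and
#' returns the RMSD matrix. Used to compare alternative homology models of
#' the same protein.
#'
#' @param models list of model entries; each either the result of
#'   \code{\link{load_structure}} (with its attached frame) or a list with
#'   \code{system} and \code{frame}
#' @return symmetric matrix of RMSD values, nm (diagonal 0)
#' @export
pairwise_model_rmsd <- function(models) {
  if (length(models) < 2) stop("need at least two models")
  models <- lapply(models, function(m) {
    if (inherits(m, "MolecularSystem")) {
      list(system = m, frame = attr(m, "frame"))
    } else m
  })
  bb <- c("N", "CA", "C", "O")
  keyed <- lapply(models, function(m) {
    at <- m$system$atoms
    prot <- if (any(at$group_role == "protein")) {
      at$group_role == "protein"
    } else rep(TRUE, nrow(at))
    idx <- which(prot & at$name %in% bb)
    list(idx = idx, key = paste(at$residue_seq[idx], at$name[idx]))
  })
  shared <- Reduce(intersect, lapply(keyed, `[[`, "key"))
  if (length(shared) == 0) stop("models share no backbone atoms")
  n <- length(models)
  M <- matrix(0, n, n)
  coords <- lapply(seq_len(n), function(i) {
    rows <- keyed[[i]]$idx[match(shared, keyed[[i]]$key)]
    models[[i]]$frame$coordinates[rows, , drop = FALSE]
  })
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    M[i, j] <- M[j, i] <- kabsch_superpose(coords[[i]], coords[[j]])$rmsd
  }
  M
}
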