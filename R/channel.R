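#' @title Pore-radius profile along the membrane normal
#' @description HOLE-style channel profiling: for successive positions z
#'   along the pore axis, the radius of the largest sphere centred in that
#'   plane that overlaps no protein atom (sphere clearance = min over atoms
#'   of centre-atom distance minus the atom's van der Waals radius), capped
#'   at a maximum radius. The in-plane centre is optimized by seeded
#'   multi-start local search continued from the previous slab's centre,
#'   a deterministic simplification of HOLE's simulated-annealing walk.
#' @name memtraj-channel
NULL

#' Bondi-style van der Waals radii (nm)
#'
#' @param elements character vector of element symbols
#' @param default radius for unknown elements, nm
#' @return numeric vector of radii, nm
#' @export
vdw_radii <- function(elements, default = 0.17) {
  tab <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
           P = 0.180, F = 0.147, CL = 0.175, K = 0.275, NA_ = 0.227,
           BR = 0.185, I = 0.198)
  key <- toupper(elements)
  key[key == "NA"] <- "NA_"
  r <- tab[key]
  r[is.na(r)] <- default
  unname(r)
}

#' Read a HOLE-format van der Waals radius file
#'
#' Parses the \code{VDWR} records of a HOLE radius file (radii in
#' Angstrom, converted to nm). Atom-name specific records are reduced to
#' one radius per element (the first listed).
#'
#' @param path file path
#' @return named numeric vector element -> radius (nm)
#' @export
read_hole_radii <- function(path) {
  lines <- readLines(path)
  lines <- lines[grepl("^\\s*VDWR", lines, ignore.case = TRUE)]
  out <- numeric(0)
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) < 4) next
    el <- toupper(gsub("[^A-Za-z]", "", tok[2]))
    if (!(el %in% names(out))) out[el] <- as.numeric(tok[4]) / 10
  }
  out
}

# clearance of a sphere centred at (x, y, z): min over atoms of distance
# minus vdW radius, capped at r_max (atoms pre-filtered by caller)
slab_clearance <- function(xy, z, A, radii, r_max) {
  dx <- A[, 1] - xy[1]; dy <- A[, 2] - xy[2]; dz <- A[, 3] - z
  min(r_max, min(sqrt(dx * dx + dy * dy + dz * dz) - radii))
}

#' Pore-radius profile of one frame
#'
#' @param frame Frame
#' @param protein_atoms 0-based atom indices bounding the pore
#' @param radii per-atom van der Waals radii, nm (default from element
#'   symbols via \code{\link{vdw_radii}}; requires a \code{system})
#' @param system MolecularSystem (only needed to derive default radii)
#' @param axis pore axis unit vector (default z, the membrane normal)
#' @param z_range numeric (lo, hi) along the axis, nm (default: protein
#'   extent)
#' @param dz slab spacing, nm (default 0.05)
#' @param r_max radius cap, nm (default 1.0)
#' @param seed integer seed for the multi-start search (default 1)
#' @param n_starts random restarts per slab in addition to the continued
#'   centre (default 4)
#' @param max_shift largest accepted in-plane displacement of a slab's
#'   centre from the previous slab's centre, nm (default 0.25); keeps the
#'   centre line connected so the search cannot jump out of the pore into
#'   open space
#' @param origin starting in-plane centre (x, y), nm (default c(0, 0))
#' @return data.frame of class \code{ChannelProfile} with columns \code{z},
#'   \code{radius} (0..r_max), \code{cx}, \code{cy}; attributes
#'   \code{r_max} and \code{time}
#' @export
channel_profile <- function(frame, protein_atoms, radii = NULL,
                            system = NULL, axis = c(0, 0, 1),
                            z_range = NULL, dz = 0.05, r_max = 1.0,
                            seed = 1L, n_starts = 4L, max_shift = 0.25,
                            origin = c(0, 0)) {
  if (length(protein_atoms) == 0) stop("empty protein atom set")
  X <- frame$coordinates[protein_atoms + 1L, , drop = FALSE]
  if (is.null(radii)) {
    if (is.null(system)) stop("supply per-atom radii or a system")
    radii <- vdw_radii(system$atoms$element[protein_atoms + 1L])
  }
  if (length(radii) == 1) radii <- rep(radii, nrow(X))
  axis <- axis / sqrt(sum(axis^2))
  R <- rotation_to_z(axis)
  X <- X %*% t(R)
  if (is.null(z_range)) z_range <- range(X[, 3])
  zg <- seq(z_range[1], z_range[2], by = dz)
  horizon <- r_max + max(radii)
  out <- matrix(NA_real_, length(zg), 3)
  with_seed(seed, {
    ctr <- as.numeric(origin)
    for (i in seq_along(zg)) {
      z <- zg[i]
      sel <- abs(X[, 3] - z) <= horizon
      if (!any(sel)) {
        out[i, ] <- c(r_max, ctr)
        next
      }
      A <- X[sel, , drop = FALSE]; rr <- radii[sel]
      f <- function(p) -slab_clearance(p, z, A, rr, r_max)
      starts <- rbind(ctr,
                      matrix(rep(ctr, each = n_starts) +
                             stats::rnorm(2 * n_starts, 0, 0.15),
                             ncol = 2))
      best <- NULL
      for (s in seq_len(nrow(starts))) {
        op <- stats::optim(starts[s, ], f, method = "Nelder-Mead",
                           control = list(reltol = 1e-10, maxit = 500))
        # keep the centre line connected: discard optima that jumped away
        if (sqrt(sum((op$par - ctr)^2)) > max_shift) next
        if (is.null(best) || op$value < best$value) best <- op
      }
      if (is.null(best)) best <- list(par = ctr, value = f(ctr))
      out[i, ] <- c(max(0, min(r_max, -best$value)), best$par)
      ctr <- best$par
    }
  })
  prof <- data.frame(z = zg, radius = out[, 1], cx = out[, 2], cy = out[, 3])
  attr(prof, "r_max") <- r_max
  attr(prof, "time") <- frame$time
  class(prof) <- c("ChannelProfile", "data.frame")
  if (all(prof$radius <= 0)) warning("pore fully occluded at every z")
  prof
}

# rotation matrix carrying `axis` onto +z
rotation_to_z <- function(axis) {
  z <- c(0, 0, 1)
  v <- cross3(axis, z)
  s <- sqrt(sum(v^2)); cth <- sum(axis * z)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    return(diag(c(1, -1, -1)))       # axis = -z: flip about x
  }
  K <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

#' Pore profiles at strided frames of a trajectory
#'
#' @param traj Trajectory
#' @param protein_atoms 0-based atom indices
#' @param stride time between profiled frames, ps (default 200); must be a
#'   multiple of the frame interval. The first analyzed frame is included.
#' @param start_time analyze frames with time >= this, ps
#' @param ... passed to \code{\link{channel_profile}}
#' @return list of ChannelProfile, one per strided frame
#' @export
profile_over_time <- function(traj, protein_atoms, stride = 200,
                              start_time = 0, ...) {
  if (traj$dt > 0) {
    k <- stride / traj$dt
    if (abs(k - round(k)) > 1e-9) {
      stop("stride (", stride, " ps) must be a multiple of dt (", traj$dt,
           " ps)")
    }
  }
  frames <- analyzed_frames(traj, start_time)
  t0 <- traj$times[frames[1]]
  keep <- frames[abs(((traj$times[frames] - t0) / stride) %%
                       1) < 1e-9]
  lapply(keep, function(f) {
    channel_profile(get_frame(traj, f), protein_atoms, ...)
  })
}

#' Detect whether an open channel spans the membrane
#'
#' TRUE when a contiguous run of z bins with radius >= \code{r_open}
#' covers the whole membrane slab.
#'
#' @param profile ChannelProfile
#' @param membrane_z numeric (lo, hi): membrane slab along the axis, nm
#' @param r_open opening radius threshold, nm (default 0.1, the lower edge
#'   of typical transient openings)
#' @return list of class \code{ChannelSpan}: \code{spans_membrane},
#'   \code{span_interval} (z lo/hi of the covering run, NA if none),
#'   \code{min_radius} on that run
#' @export
detect_span <- function(profile, membrane_z, r_open = 0.1) {
  open <- profile$radius >= r_open
  r <- rle(open)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  res <- list(spans_membrane = FALSE,
              span_interval = c(NA_real_, NA_real_),
              min_radius = NA_real_)
  for (k in which(r$values)) {
    zlo <- profile$z[starts[k]]; zhi <- profile$z[ends[k]]
    if (zlo <= membrane_z[1] + 1e-9 && zhi >= membrane_z[2] - 1e-9) {
      res$spans_membrane <- TRUE
      res$span_interval <- c(zlo, zhi)
      res$min_radius <- min(profile$radius[starts[k]:ends[k]])
      break
    }
  }
  class(res) <- "ChannelSpan"
  res
}

#' Write a channel profile as TSV
#' @param profile ChannelProfile
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_channel_tsv <- function(profile, path) {
  df <- data.frame(z_nm = round(profile$z, 6),
                   radius_nm = round(profile$radius, 6),
                   cx_nm = round(profile$cx, 6),
                   cy_nm = round(profile$cy, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
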