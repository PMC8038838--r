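#' @title Periodic-boundary distance machinery, superposition and RMSD
#' @name memtraj-geometry
NULL

# is a 3x3 box (row vectors) orthorhombic?
is_orthorhombic <- function(box) {
  all(abs(box[upper.tri(box) | lower.tri(box)]) < 1e-12)
}

check_box <- function(box) {
  if (!is.matrix(box) || any(dim(box) != c(3, 3))) stop("box must be 3x3")
  if (abs(det(box)) < 1e-12) stop("singular box matrix")
  if (any(diag(box) <= 0)) stop("box diagonal must be positive (reduced triclinic)")
  invisible(box)
}

#' Minimum-image distance between two points
#'
#' Distance between \code{a} and \code{b} under periodic boundary conditions
#' in a (reduced) triclinic box given as row vectors. The displacement is
#' wrapped to the central cell in fractional coordinates and the minimum is
#' taken over the 27 surrounding lattice images, which is exact for reduced
#' boxes.
#'
#' @param a,b numeric 3-vectors, nm
#' @param box 3x3 matrix of box row vectors, nm
#' @return distance in nm
#' @export
min_image_distance <- function(a, b, box) {
  check_box(box)
  d <- matrix(b - a, nrow = 1)
  sqrt(min_image_sqdist(d, box))
}

# squared min-image length of each row of displacement matrix D (n x 3)
min_image_sqdist <- function(D, box) {
  if (is_orthorhombic(box)) {
    L <- diag(box)
    for (k in 1:3) D[, k] <- D[, k] - L[k] * round(D[, k] / L[k])
    return(rowSums(D * D))
  }
  Fc <- D %*% solve(box)
  Fc <- Fc - round(Fc)
  best <- rep(Inf, nrow(D))
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    S <- sweep(Fc, 2, c(i, j, k), "+") %*% box
    best <- pmin(best, rowSums(S * S))
  }
  best
}

# full matrix of squared min-image distances between coordinate sets
# A (n x 3) and B (m x 3); returns n x m matrix
cross_min_sqdist <- function(A, B, box) {
  n <- nrow(A); m <- nrow(B)
  if (is_orthorhombic(box)) {
    L <- diag(box)
    tot <- matrix(0, n, m)
    for (k in 1:3) {
      dk <- outer(A[, k], B[, k], "-")
      dk <- dk - L[k] * round(dk / L[k])
      tot <- tot + dk * dk
    }
    return(tot)
  }
  D <- matrix(0, n * m, 3)
  for (k in 1:3) D[, k] <- as.vector(outer(A[, k], B[, k], "-"))
  matrix(min_image_sqdist(D, box), n, m)
}

#' Build a neighbor grid (cell list) over a coordinate set
#'
#' Bins atoms into cells in fractional coordinates. Used to accelerate
#' residue-to-group minimum-distance queries on large groups; results are
#' identical to the brute-force cross-product search.
#'
#' @param coords n x 3 coordinates, nm
#' @param box 3x3 box row vectors, nm
#' @param cell_size target cell edge, nm (must be >= the query cutoff for
#'   single-shell queries; queries here expand shells, so any size works)
#' @return object of class \code{NeighborGrid}
#' @export
neighbor_grid <- function(coords, box, cell_size = 0.5) {
  check_box(box)
  # perpendicular widths of the box along each fractional axis
  widths <- abs(det(box)) / c(
    sqrt(sum(cross3(box[2, ], box[3, ])^2)),
    sqrt(sum(cross3(box[1, ], box[3, ])^2)),
    sqrt(sum(cross3(box[1, ], box[2, ])^2))
  )
  nc <- pmax(1L, as.integer(floor(widths / cell_size)))
  Fc <- coords %*% solve(box)
  Fc <- Fc - floor(Fc)                       # wrap into [0,1)
  ci <- sapply(1:3, function(k) pmin(nc[k] - 1L, as.integer(floor(Fc[, k] * nc[k]))))
  if (nrow(coords) == 1) ci <- matrix(ci, nrow = 1)
  lin <- ci[, 1] + nc[1] * (ci[, 2] + nc[2] * ci[, 3])
  buckets <- split(seq_len(nrow(coords)), lin)
  structure(list(buckets = buckets, nc = nc, box = box,
                 cell_width = widths / nc, coords = coords),
            class = "NeighborGrid")
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# exact min distance from one point to the gridded set, by expanding cell
# shells until the best distance is certified
grid_min_dist_point <- function(grid, p) {
  nc <- grid$nc
  Fc <- as.numeric(matrix(p, 1) %*% solve(grid$box))
  Fc <- Fc - floor(Fc)
  c0 <- pmin(nc - 1L, as.integer(floor(Fc * nc)))
  wmin <- min(grid$cell_width)
  best <- Inf
  smax <- max(nc)
  for (s in 0:smax) {
    # cells at Chebyshev shell s around c0 (wrapped)
    offs <- shell_offsets(s, nc)
    if (nrow(offs) > 0) {
      cells <- sweep(offs, 2, c0, "+")
      for (k in 1:3) cells[, k] <- cells[, k] %% nc[k]
      cells <- unique(cells)
      lin <- cells[, 1] + nc[1] * (cells[, 2] + nc[2] * cells[, 3])
      idx <- unlist(grid$buckets[as.character(lin)], use.names = FALSE)
      if (length(idx) > 0) {
        d2 <- min_image_sqdist(sweep(grid$coords[idx, , drop = FALSE], 2, p, "-"),
                               grid$box)
        best <- min(best, sqrt(min(d2)))
      }
    }
    # unscanned atoms sit in shells > s, hence at distance >= s*wmin
    if (best <= s * wmin) break
  }
  best
}

shell_offsets <- function(s, nc) {
  rng <- -s:s
  g <- as.matrix(expand.grid(i = rng, j = rng, k = rng))
  keep <- apply(abs(g), 1, max) == s
  g <- g[keep, , drop = FALSE]
  # in dimensions with few cells a large shell just re-wraps; clamp span
  for (k in 1:3) g <- g[abs(g[, k]) <= nc[k], , drop = FALSE]
  g
}

#' Minimum distance between a residue's atoms and a particle group
#'
#' Minimum-image minimum distance over the atom-pair cross product. Large
#' problems use a cell-list search; both routes return identical values.
#'
#' @param frame Frame (or list with \code{coordinates} and \code{box})
#' @param residue_atoms,group_atoms 0-based atom index vectors
#' @param pbc apply the minimum-image convention (default TRUE)
#' @return minimum distance, nm
#' @export
min_residue_group_distance <- function(frame, residue_atoms, group_atoms,
                                       pbc = TRUE) {
  if (length(residue_atoms) == 0) stop("empty residue atom set")
  if (length(group_atoms) == 0) stop("empty group atom set")
  A <- frame$coordinates[residue_atoms + 1L, , drop = FALSE]
  B <- frame$coordinates[group_atoms + 1L, , drop = FALSE]
  if (!pbc) {
    box <- diag(3) * (2 * max(abs(rbind(A, B))) + 10)   # box too big to wrap
  } else {
    box <- frame$box
  }
  if (length(residue_atoms) * length(group_atoms) > 250000) {
    grid <- neighbor_grid(B, box)
    return(min(apply(A, 1, function(p) grid_min_dist_point(grid, p))))
  }
  sqrt(min(cross_min_sqdist(A, B, box)))
}

#' Kabsch least-squares superposition
#'
#' Optimal rigid-body superposition of \code{mobile} onto \code{reference}
#' (rotation + translation, reflections excluded) and the RMSD after the
#' fit. The transform maps a mobile point x to \code{rotation \%*\% x +
#' translation}.
#'
#' @param mobile,reference n x 3 coordinate matrices (n >= 3), nm
#' @param weights optional per-point weights
#' @return list with \code{rotation} (3x3, det +1), \code{translation}
#'   (3-vector, nm) and \code{rmsd} (nm), class \code{SuperpositionResult}
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) stop("point counts differ")
  if (nrow(mobile) < 3) stop("need at least 3 points")
  w <- if (is.null(weights)) rep(1, nrow(mobile)) else weights / sum(weights) * nrow(mobile)
  cm <- colSums(mobile * w) / sum(w)
  cr <- colSums(reference * w) / sum(w)
  M <- sweep(mobile, 2, cm); R0 <- sweep(reference, 2, cr)
  H <- t(M * w) %*% R0
  sv <- svd(H)
  if (sv$d[2] < 1e-12 * max(sv$d[1], 1e-300)) {
    stop("degenerate (collinear) point set: superposition undetermined")
  }
  s <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  fitted <- M %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - R0)^2)) / sum(w))
  structure(list(rotation = rot,
                 translation = as.numeric(cr - rot %*% cm),
                 rmsd = rmsd),
            class = "SuperpositionResult")
}

# apply a SuperpositionResult to an n x 3 coordinate matrix
apply_superposition <- function(sp, coords) {
  sweep(coords %*% t(sp$rotation), 2, sp$translation, "+")
}

#' RMSD time series against a reference frame
#'
#' Root-mean-square deviation of a selection in every frame from the same
#' selection in a reference frame, optionally after least-squares
#' superposition. Assumes molecules are whole (no minimum-image wrapping of
#' intramolecular displacements).
#'
#' @param traj Trajectory
#' @param reference Frame (typically the starting structure)
#' @param selection 0-based atom indices (default: all atoms)
#' @param fit superpose each frame onto the reference first (default TRUE)
#' @return data.frame with columns \code{time} (ps) and \code{rmsd} (nm)
#' @export
rmsd_timeseries <- function(traj, reference, selection = NULL, fit = TRUE) {
  if (is.null(selection)) selection <- seq_len(dim(traj$coords)[1]) - 1L
  if (length(selection) == 0) stop("empty selection")
  ref <- reference$coordinates[selection + 1L, , drop = FALSE]
  vals <- vapply(seq_len(n_frames(traj)), function(i) {
    X <- frame_coords(traj, selection + 1L, i)
    if (fit) {
      kabsch_superpose(X, ref)$rmsd
    } else {
      sqrt(mean(rowSums((X - ref)^2)))
    }
  }, numeric(1))
  data.frame(time = traj$times, rmsd = vals)
}

#' Detect the equilibration time from an RMSD series
#'
#' Earliest time after which the linear slope of every subsequent running
#' window stays below \code{slope_tol}. A production pipeline normally uses
#' a fixed trim instead (see \code{\link{trim_trajectory}}); this is a
#' diagnostic.
#'
#' @param rmsd_series data.frame with \code{time} (ps) and \code{rmsd} (nm)
#' @param window window length, ps (default 10 ns)
#' @param slope_tol slope tolerance, nm/ns (default 0.005)
#' @return equilibration time, ps; the final time (with a warning) if the
#'   series never settles
#' @export
detect_equilibration <- function(rmsd_series, window = 10000, slope_tol = 0.005) {
  t <- rmsd_series$time; y <- rmsd_series$rmsd
  span <- t[length(t)] - t[1]
  if (span < 2 * window) stop("series must span at least twice the window")
  dt <- t[2] - t[1]
  nw <- max(2L, as.integer(round(window / dt)))
  nstarts <- length(t) - nw + 1L
  slopes <- vapply(seq_len(nstarts), function(i) {
    idx <- i:(i + nw - 1L)
    tt <- t[idx] - mean(t[idx])
    sum(tt * (y[idx] - mean(y[idx]))) / sum(tt * tt) * 1000   # nm/ps -> nm/ns
  }, numeric(1))
  ok <- abs(slopes) < slope_tol
  # earliest start from which all later windows are flat
  flat_from <- rev(cumprod(rev(ok))) > 0
  if (!any(flat_from)) {
    warning("RMSD series never equilibrates under the given tolerance")
    return(t[length(t)])
  }
  t[which(flat_from)[1]]
}
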