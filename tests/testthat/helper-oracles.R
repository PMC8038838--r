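# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately share no code with the implementation.

# minimum distance between a and b over the 27 neighbouring periodic
# images, plain double loop over lattice shifts
brute_min_image <- function(a, b, box) {
  best <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    shift <- i * box[1, ] + j * box[2, ] + k * box[3, ]
    best <- min(best, sqrt(sum((b - a + shift)^2)))
  }
  best
}

# naive double-loop set-to-set minimum distance under the same convention
brute_min_set_dist <- function(A, B, box) {
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    best <- min(best, brute_min_image(A[i, ], B[j, ], box))
  }
  best
}

# random reduced triclinic box: dominant diagonal, small off-diagonals
random_triclinic <- function() {
  d <- runif(3, 2, 5)
  m <- diag(d)
  m[2, 1] <- runif(1, -0.3, 0.3) * d[1]
  m[3, 1] <- runif(1, -0.3, 0.3) * d[1]
  m[3, 2] <- runif(1, -0.3, 0.3) * d[2]
  m
}

# exhaustive in-plane grid search for the largest clearance sphere in a slab
grid_search_radius <- function(X, radii, z, r_max, span = 0.6, step = 0.01) {
  g <- seq(-span, span, by = step)
  best <- -Inf
  for (x in g) for (y in g) {
    d <- sqrt((X[, 1] - x)^2 + (X[, 2] - y)^2 + (X[, 3] - z)^2) - radii
    best <- max(best, min(r_max, min(d)))
  }
  max(0, best)
}

# single-frame trajectory from a generator result (system + frame)
one_frame_traj <- function(gen) {
  nat <- nrow(gen$system$atoms)
  suppressWarnings(trajectory(
    gen$system,
    array(gen$frame$coordinates, c(nat, 3, 1)),
    array(gen$frame$box, c(3, 3, 1)),
    0))
}

# trajectory from a list of coordinate matrices with a fixed box
traj_from_coords <- function(system, coord_list, box, dt = 10) {
  nat <- nrow(system$atoms)
  nf <- length(coord_list)
  co <- array(0, c(nat, 3, nf))
  for (i in seq_len(nf)) co[, , i] <- coord_list[[i]]
  suppressWarnings(trajectory(system, co, array(box, c(3, 3, nf)),
                              (seq_len(nf) - 1) * dt))
}

# a toy 5-residue, 30-atom PDB file (6 atoms per residue), orthogonal
# coordinates on a grid; returns the path
write_toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- character(0)
  ser <- 1
  nm <- c("N", "CA", "C", "O", "CB", "CG")
  el <- c("N", "C", "C", "O", "C", "C")
  for (r in 1:5) {
    for (a in 1:6) {
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        ser, nm[a], "ALA", "A", r, r * 3.0, a * 1.5, 1.0, 1.0, 0.0, el[a]))
      ser <- ser + 1
    }
  }
  writeLines(c(lines, "END"), path)
  path
}
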