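#' @title Synthetic systems and trajectories with known ground truth
#' @description Generators that stand in for MD output: ideal poly-alanine
#'   helices (backbone N, CA, C, O on an exact helical path), two-state
#'   Markov contact processes with closed-form proximity / event-count /
#'   residence-time expectations, and helix-bundle pores with compartmented
#'   water, lipid-tail, ion and ligand particles doing seeded random
#'   walks. Everything is deterministic given a seed.
#' @name memtraj-synthetic
NULL

# cylindrical-coordinate template of the ideal alpha-helix backbone
# (phi = -57, psi = -47, standard bond geometry): radius (nm), phase
# offset (deg) and axial offset (nm) of each backbone atom relative to CA;
# the natural geometry has twist 99.36 deg/residue and rise 0.1558 nm
HELIX_TEMPLATE <- data.frame(
  name = c("N", "CA", "C", "O"),
  element = c("N", "C", "C", "O"),
  r = c(0.155144, 0.227590, 0.166614, 0.192394),
  dtheta = c(-26.770952, 0, 26.742544, 20.177678),
  dz = c(-0.091869, 0, 0.106893, 0.225505),
  stringsAsFactors = FALSE
)

#' Generate an ideal helix (poly-alanine backbone)
#'
#' Backbone atoms are placed on cylindrical paths around the helix axis
#' using the ideal alpha-helix template, with the per-residue twist and
#' rise as free parameters. The defaults give an alpha-helix whose
#' O(n)...N(n+4) distances are about 0.29 nm; twist 180 deg with an
#' extended rise (about 0.35 nm/residue) gives an extended chain with
#' distances above 1 nm.
#'
#' @param n_residues number of residues (>= 5 for a defined i,i+4 metric)
#' @param rise rise per residue along the axis, nm (default 0.15)
#' @param twist twist per residue, degrees (default 100)
#' @param axis helix axis direction (default z)
#' @param center position of the helix midpoint, nm
#' @param chain chain identifier
#' @param first_seq author residue number of the first residue
#' @param phase rotation of the whole helix about its axis, degrees
#' @return list with \code{system} (MolecularSystem, roles assigned:
#'   protein) and \code{frame} (Frame; box = bounding box + 2 nm)
#' @export
make_ideal_helix <- function(n_residues, rise = 0.15, twist = 100,
                             axis = c(0, 0, 1), center = c(0, 0, 0),
                             chain = "A", first_seq = 1L, phase = 0) {
  stopifnot(n_residues >= 2)
  tpl <- HELIX_TEMPLATE
  n_at <- nrow(tpl)
  res <- rep(seq_len(n_residues) - 1L, each = n_at)
  th <- (res * twist + rep(tpl$dtheta, n_residues) + phase) * pi / 180
  r <- rep(tpl$r, n_residues)
  z <- res * rise + rep(tpl$dz, n_residues)
  z <- z - mean(range(z))
  X <- cbind(r * cos(th), r * sin(th), z)
  Rz <- t(rotation_to_z(axis / sqrt(sum(axis^2))))   # z -> axis
  X <- sweep(X %*% t(Rz), 2, center, "+")
  atoms <- data.frame(
    name = rep(tpl$name, n_residues),
    element = rep(tpl$element, n_residues),
    residue_name = "ALA",
    residue_seq = res + as.integer(first_seq),
    chain = chain,
    icode = "",
    group_role = "protein",
    stringsAsFactors = FALSE
  )
  sys <- molecular_system(atoms)
  ext <- apply(X, 2, function(v) diff(range(v)))
  frame <- structure(list(coordinates = X, box = diag(ext + 2), time = 0),
                     class = "Frame")
  attr(sys, "frame") <- frame
  list(system = sys, frame = frame)
}

#' Generate an extended (non-helical) chain
#'
#' Convenience wrapper around \code{\link{make_ideal_helix}} with a
#' 180-degree twist and an extended rise, giving O(n)...N(n+4) distances
#' above 1 nm.
#'
#' @param n_residues number of residues
#' @param ... passed on to \code{\link{make_ideal_helix}}
#' @return as \code{\link{make_ideal_helix}}
#' @export
make_extended_chain <- function(n_residues, ...) {
  make_ideal_helix(n_residues, rise = 0.347, twist = 180, ...)
}

#' Generate a two-state Markov contact trajectory
#'
#' A single-residue protein (one CA atom) and one group particle whose
#' separation alternates between a bound and an unbound distance following
#' a two-state Markov chain: per-frame probability \code{a} of entering
#' contact and \code{b} of leaving it. The initial state is drawn from the
#' stationary distribution a/(a+b). Closed-form expectations over N
#' analyzed frames: proximity a/(a+b), mean residence time dt/b, binding
#' events per run about N a b/(a+b).
#'
#' @param a per-frame entry probability (0..1)
#' @param b per-frame exit probability (0..1)
#' @param n_frames number of frames
#' @param dt frame interval, ps (default 10)
#' @param seed RNG seed
#' @param group group role of the particle (default \code{"water"})
#' @param bound,unbound separations in the two states, nm (defaults 0.25
#'   and 0.8, straddling the 0.4 nm cutoff)
#' @param box_len cubic box edge, nm
#' @return Trajectory; the simulated state path is attached as attribute
#'   \code{"states"} (logical, TRUE = bound)
#' @export
make_markov_contact_trajectory <- function(a, b, n_frames, dt = 10,
                                           seed = 1L, group = "water",
                                           bound = 0.25, unbound = 0.8,
                                           box_len = 4) {
  stopifnot(a >= 0, a <= 1, b >= 0, b <= 1, n_frames >= 1,
            bound < unbound)
  part <- switch(group,
    water = list(name = "OW", element = "O", resname = "SOL"),
    ion = list(name = "K", element = "K", resname = "K"),
    ligand = list(name = "CA", element = "C", resname = "ALA"),
    list(name = "X", element = "C", resname = "UNK"))
  atoms <- data.frame(
    name = c("CA", part$name), element = c("C", part$element),
    residue_name = c("ALA", part$resname), residue_seq = c(1L, 2L),
    chain = c("A", "B"), icode = "",
    group_role = c("protein", group), stringsAsFactors = FALSE)
  sys <- molecular_system(atoms)
  states <- logical(n_frames)
  with_seed(seed, {
    p_bound <- if (a + b > 0) a / (a + b) else 0
    states[1] <- stats::runif(1) < p_bound
    if (n_frames > 1) {
      u <- stats::runif(n_frames - 1)
      for (i in 2:n_frames) {
        states[i] <- if (states[i - 1]) u[i - 1] >= b else u[i - 1] < a
      }
    }
  })
  ctr <- rep(box_len / 2, 3)
  coords <- array(0, c(2, 3, n_frames))
  sep <- ifelse(states, bound, unbound)
  for (i in seq_len(n_frames)) {
    coords[1, , i] <- ctr
    coords[2, , i] <- ctr + c(sep[i], 0, 0)
  }
  box <- array(rep(diag(rep(box_len, 3)), n_frames), c(3, 3, n_frames))
  traj <- suppressWarnings(
    trajectory(sys, coords, box, (seq_len(n_frames) - 1) * dt))
  attr(traj, "states") <- states
  traj
}

#' Generate a helix-bundle pore trajectory
#'
#' \code{n_helices} ideal alpha-helices stand on a circle around the z
#' axis, leaving an axial pore whose minimum atom-centre distance from the
#' axis is calibrated to \code{pore_radius}. Lipid-tail particles live in
#' the membrane slab outside the bundle; water lives outside the slab and
#' inside the pore; ions and ligand particles live in the solvent outside
#' the slab. All mobile particles perform seeded Gaussian random walks
#' with rejection at their compartment boundaries; the protein is static.
#' Ligand particles can be biased to loiter near chosen residues through a
#' harmonic drift.
#'
#' @param n_helices number of helices (default 10, a transmembrane-bundle
#'   architecture)
#' @param n_res_per_helix residues per helix (default 30: 4.5 nm of helix,
#'   spanning the slab with solvent-exposed ends)
#' @param pore_radius minimum atom-centre distance from the pore axis, nm
#'   (default 0.45)
#' @param slab_half_z membrane slab half-thickness, nm (default 1.5, a
#'   typical hydrophobic-core half-thickness)
#' @param n_water,n_tail,n_ion,n_ligand particle counts (defaults 250,
#'   160, 10, 20; tails are confined to a 0.65 nm shell around the bundle
#'   so their local density is bilayer-like, and 20 ligand molecules
#'   mirrors a typical excess-ligand setup)
#' @param sigma random-walk step standard deviation, nm/frame (default
#'   0.05)
#' @param n_frames number of frames (default 100)
#' @param dt frame interval, ps (default 10)
#' @param seed RNG seed
#' @param ligand_bias_residues 0-based residue indices ligand particles
#'   are attracted to (default NULL: unbiased)
#' @param bias_k harmonic drift strength per frame (default 0.15)
#' @return Trajectory with group roles assigned; ground truth is attached
#'   as attribute \code{"ground_truth"} (achieved pore radius, slab
#'   bounds, compartment of every particle)
#' @export
make_pore_bundle <- function(n_helices = 10, n_res_per_helix = 30,
                             pore_radius = 0.45, slab_half_z = 1.5,
                             n_water = 250, n_tail = 160, n_ion = 10,
                             n_ligand = 20, sigma = 0.05, n_frames = 100,
                             dt = 10, seed = 1L,
                             ligand_bias_residues = NULL, bias_k = 0.15) {
  helix_rmax <- max(HELIX_TEMPLATE$r)
  ring_r <- pore_radius + helix_rmax
  # build helices, then calibrate the ring radius so the minimum
  # atom-centre distance from the z axis equals pore_radius exactly
  build <- function(rr) {
    pieces <- lapply(seq_len(n_helices) - 1L, function(k) {
      ang <- 2 * pi * k / n_helices
      make_ideal_helix(n_res_per_helix,
                       center = c(rr * cos(ang), rr * sin(ang), 0),
                       chain = LETTERS[(k %% 26) + 1L],
                       first_seq = 1L + k * n_res_per_helix,
                       phase = 360 * k / n_helices)
    })
    X <- do.call(rbind, lapply(pieces, function(p) p$frame$coordinates))
    at <- do.call(rbind, lapply(pieces, function(p) p$system$atoms[
      c("name", "element", "residue_name", "residue_seq", "chain", "icode",
        "group_role")]))
    list(X = X, atoms = at)
  }
  for (it in 1:3) {
    b <- build(ring_r)
    dmin <- min(sqrt(b$X[, 1]^2 + b$X[, 2]^2))
    ring_r <- ring_r + (pore_radius - dmin)
  }
  b <- build(ring_r)
  prot_X <- b$X
  prot_atoms <- b$atoms
  np <- nrow(prot_X)
  bundle_outer <- max(sqrt(prot_X[, 1]^2 + prot_X[, 2]^2))

  box_xy <- 2 * (bundle_outer + 1.2)
  box_z <- 2 * (slab_half_z + 2)
  L <- c(box_xy, box_xy, box_z)

  ntot_part <- n_water + n_tail + n_ion + n_ligand
  kind <- rep(c("water", "lipid_tail", "ion", "ligand"),
              c(n_water, n_tail, n_ion, n_ligand))

  # compartments (coordinates centred on the bundle, box later shifts):
  #   water: outside slab, or inside the pore core
  #   tail: inside slab, radially outside the bundle
  #   ion/ligand: outside slab
  pore_core <- max(0.05, pore_radius - 0.15)
  in_slab <- function(p) abs(p[3]) < slab_half_z
  rad <- function(p) sqrt(p[1]^2 + p[2]^2)
  allowed <- function(kind, p) {
    if (abs(p[1]) > L[1] / 2 - 0.2 || abs(p[2]) > L[2] / 2 - 0.2 ||
        abs(p[3]) > L[3] / 2 - 0.2) return(FALSE)
    switch(kind,
      water = !in_slab(p) || rad(p) < pore_core,
      lipid_tail = in_slab(p) && rad(p) > bundle_outer + 0.05 &&
        rad(p) < bundle_outer + 0.65,
      ion = !in_slab(p),
      ligand = !in_slab(p),
      TRUE)
  }
  coords <- array(0, c(np + ntot_part, 3, n_frames))
  with_seed(seed, {
    bias_targets <- NULL
    if (length(ligand_bias_residues) > 0) {
      sys_tmp <- molecular_system(prot_atoms)
      bias_targets <- t(vapply(ligand_bias_residues, function(ri) {
        colMeans(prot_X[residue_atoms(sys_tmp, ri) + 1L, , drop = FALSE])
      }, numeric(3)))
    }
    # initial placement by rejection sampling; biased ligands start on
    # their target residue's side of the membrane (a drift across the
    # impermeable slab would otherwise strand them at the far leaflet)
    P <- matrix(0, ntot_part, 3)
    for (i in seq_len(ntot_part)) {
      tgt_z <- if (kind[i] == "ligand" && !is.null(bias_targets)) {
        bias_targets[(i - 1) %% nrow(bias_targets) + 1L, 3]
      } else NA_real_
      repeat {
        p <- c(stats::runif(2, -L[1] / 2 + 0.3, L[1] / 2 - 0.3),
               stats::runif(1, -L[3] / 2 + 0.3, L[3] / 2 - 0.3))
        if (kind[i] == "water" && stats::runif(1) < 0.3) {
          p <- c(stats::runif(2, -pore_core, pore_core),
                 stats::runif(1, -slab_half_z, slab_half_z))
        }
        if (!is.na(tgt_z) && sign(p[3]) != sign(tgt_z)) next
        if (allowed(kind[i], p)) break
      }
      P[i, ] <- p
    }
    for (f in seq_len(n_frames)) {
      if (f > 1) {
        for (i in seq_len(ntot_part)) {
          step <- stats::rnorm(3, 0, sigma)
          if (kind[i] == "ligand" && !is.null(bias_targets)) {
            tgt <- bias_targets[
              (i - 1) %% nrow(bias_targets) + 1L, ]
            step <- step + bias_k * (tgt - P[i, ])
          }
          cand <- P[i, ] + step
          if (allowed(kind[i], cand)) P[i, ] <- cand
        }
      }
      coords[, , f] <- rbind(prot_X, P) + matrix(L / 2, np + ntot_part, 3,
                                                 byrow = TRUE)
    }
  })

  part_atoms <- data.frame(
    name = c("OW", "C22", "K", "CA")[match(kind, c("water", "lipid_tail",
                                                   "ion", "ligand"))],
    element = c("O", "C", "K", "C")[match(kind, c("water", "lipid_tail",
                                                  "ion", "ligand"))],
    residue_name = c("SOL", "POPE", "K", "ALA")[match(kind, c(
      "water", "lipid_tail", "ion", "ligand"))],
    residue_seq = seq_len(ntot_part) + max(prot_atoms$residue_seq),
    chain = "Z",
    icode = "",
    group_role = kind,
    stringsAsFactors = FALSE)
  sys <- molecular_system(rbind(prot_atoms, part_atoms))
  box <- array(rep(diag(L), n_frames), c(3, 3, n_frames))
  traj <- suppressWarnings(
    trajectory(sys, coords, box, (seq_len(n_frames) - 1) * dt))
  attr(traj, "ground_truth") <- list(
    pore_radius = pore_radius,
    achieved_min_axis_distance = min(sqrt(prot_X[, 1]^2 + prot_X[, 2]^2)),
    slab_z = c(-slab_half_z, slab_half_z) + L[3] / 2,
    axis_xy = c(L[1] / 2, L[2] / 2),
    ring_radius = ring_r,
    bundle_outer = bundle_outer,
    kind = kind)
  traj
}
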