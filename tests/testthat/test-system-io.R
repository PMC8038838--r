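test_that("a toy PDB loads with counts, residues and nm coordinates intact", {
  p <- write_toy_pdb()
  sys <- load_structure(p)
  expect_equal(nrow(sys$atoms), 30)
  expect_equal(nrow(sys$residues), 5)
  fr <- attr(sys, "frame")
  # PDB stores Angstrom; internal unit is nm
  expect_equal(fr$coordinates[1, 1], 0.3)
  expect_equal(sys$atoms$residue_index, rep(0:4, each = 6))
})

test_that("PDB insertion codes keep residues apart", {
  p <- tempfile(fileext = ".pdb")
  mk <- function(ser, seq, icode, y) sprintf(
    "ATOM  %5d  CA  ALA A%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    ser, seq, icode, 1.0, y, 1.0, 1.0, 0.0)
  writeLines(c(mk(1, 10, " ", 1), mk(2, 10, "A", 2), mk(3, 10, "B", 3),
               "END"), p)
  sys <- load_structure(p)
  expect_equal(nrow(sys$residues), 3)
})

test_that("GRO round trip preserves names, order and coordinates; PDB and GRO agree", {
  h <- make_ideal_helix(8)
  g <- tempfile(fileext = ".gro")
  write_structure(h$system, h$frame, g)
  sys2 <- load_structure(g)
  expect_equal(sys2$atoms$name, h$system$atoms$name)
  expect_equal(sys2$atoms$residue_seq, h$system$atoms$residue_seq)
  expect_lt(max(abs(attr(sys2, "frame")$coordinates - h$frame$coordinates)),
            1e-3)
  # same coordinates via PDB (Angstrom) agree within format precision
  pp <- tempfile(fileext = ".pdb")
  write_structure(h$system, h$frame, pp)
  sys3 <- load_structure(pp)
  expect_lt(max(abs(attr(sys3, "frame")$coordinates -
                      h$frame$coordinates)), 1e-3)
})

test_that("GRO files with velocity columns parse, velocities ignored", {
  p <- tempfile(fileext = ".gro")
  writeLines(c("toy t= 0.0", "2",
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f",
                       1L, "SOL", "OW", 1L, 1.5, 2.0, 2.5, 0.1, -0.2, 0.3),
               sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f",
                       1L, "SOL", "HW1", 2L, 1.6, 2.0, 2.5, 0, 0, 0),
               sprintf("%10.5f%10.5f%10.5f", 4, 4, 4)), p)
  sys <- load_structure(p)
  expect_equal(nrow(sys$atoms), 2)
  expect_equal(attr(sys, "frame")$coordinates[1, ], c(1.5, 2.0, 2.5))
})

test_that("multi-frame GRO trajectories infer dt from title timestamps", {
  m <- make_markov_contact_trajectory(0.3, 0.3, 11, dt = 10, seed = 4)
  p <- tempfile(fileext = ".gro")
  write_trajectory_gro(m, p)
  tr <- load_trajectory(p, m$system)
  expect_equal(n_frames(tr), 11)
  expect_equal(tr$dt, 10)
  expect_equal(tr$coords, m$coords, tolerance = 1e-3)
  # non-uniform timestamps are rejected
  tr_bad <- m; tr_bad$times[5] <- tr_bad$times[5] + 3
  attr(tr_bad, "class") <- "Trajectory"
  p2 <- tempfile(fileext = ".gro")
  write_trajectory_gro(tr_bad, p2)
  expect_error(load_trajectory(p2, m$system), "non-uniform")
})

test_that("single-frame input yields dt 0 with a warning", {
  h <- make_ideal_helix(6)
  g <- tempfile(fileext = ".gro")
  write_structure(h$system, h$frame, g)
  expect_warning(tr <- load_trajectory(g, h$system), "dt undefined")
  expect_equal(n_frames(tr), 1)
  expect_equal(tr$dt, 0)
})

test_that("atom-count mismatches raise an error naming the frame", {
  m <- make_markov_contact_trajectory(0.3, 0.3, 3, seed = 1)
  p <- tempfile(fileext = ".gro")
  write_trajectory_gro(m, p)
  h <- make_ideal_helix(6)
  expect_error(load_trajectory(p, h$system), "frame 1")
})

test_that("DCD coordinates are converted from Angstrom to nm", {
  pdb <- system.file("examples", "hivp.pdb", package = "bio3d")
  dcd <- system.file("examples", "hivp.dcd", package = "bio3d")
  skip_if(pdb == "" || dcd == "")
  sys <- load_structure(pdb)
  tr <- load_trajectory(dcd, sys, format = "dcd", dt = 10)
  raw <- bio3d::read.dcd(dcd, verbose = FALSE)
  expect_equal(tr$coords[1, , 1], unname(raw[1, 1:3]) / 10, tolerance = 1e-6)
  expect_equal(n_frames(tr), nrow(raw))
})

test_that("xtc/trr formats are refused with guidance", {
  h <- make_ideal_helix(6)
  expect_error(load_trajectory("x.xtc", h$system), "not supported")
})

test_that("group roles partition the atom set", {
  b <- make_pore_bundle(n_frames = 1, n_water = 20, n_tail = 20, n_ion = 3,
                        n_ligand = 4, seed = 9)
  tab <- table(b$system$atoms$group_role)
  expect_equal(sum(tab), nrow(b$system$atoms))
  expect_true(all(names(tab) %in% c("protein", "water", "lipid_tail",
                                    "lipid_other", "ion", "ligand",
                                    "other")))
})

test_that("assign_groups splits lipid tails from head groups and finds ions", {
  atoms <- data.frame(
    name = c("N", "CA", "C", "O", "N", "CA", "C", "O",   # 2-residue peptide
             "P", "O11", "N1", "C21", "C22", "C23", "C31", "C32",  # POPE
             "OW", "HW1", "HW2",             # water
             "K"),                           # ion
    element = c("N", "C", "C", "O", "N", "C", "C", "O",
                "P", "O", "N", "C", "C", "C", "C", "C", "O", "H", "H", "K"),
    residue_name = c(rep("ALA", 8), rep("POPE", 8), rep("SOL", 3), "K"),
    residue_seq = c(rep(1, 4), rep(2, 4), rep(3, 8), rep(4, 3), 5),
    chain = "",
    stringsAsFactors = FALSE)
  sys <- assign_groups(molecular_system(atoms))
  roles <- sys$atoms$group_role
  expect_equal(roles[1:8], rep("protein", 8))
  # only acyl-chain carbons C2x/C3x are tails; P/O11/N1 are head atoms
  expect_equal(roles[atoms$name %in% c("C21", "C22", "C23", "C31", "C32")],
               rep("lipid_tail", 5))
  expect_equal(roles[atoms$name %in% c("P", "O11", "N1")],
               rep("lipid_other", 3))
  expect_equal(roles[17:19], rep("water", 3))
  expect_equal(roles[20], "ion")
})

test_that("free amino acids become ligand; in-chain ones stay protein", {
  h <- make_ideal_helix(6)          # a real peptide chain
  free <- data.frame(name = "CA", element = "C", residue_name = "ALA",
                     residue_seq = 100:119, chain = "",
                     stringsAsFactors = FALSE)
  free <- free[rep(1, 20), ]; free$residue_seq <- 100:119
  atoms <- rbind(h$system$atoms[c("name", "element", "residue_name",
                                  "residue_seq", "chain")],
                 free)
  atoms$chain <- ""                 # as in a GRO file: no chain ids
  sys <- molecular_system(atoms)
  # coordinates: helix as built, free alanines far apart
  X <- rbind(h$frame$coordinates,
             cbind(5 + (1:20), 0, 0))
  fr <- structure(list(coordinates = X, box = diag(c(50, 10, 10)),
                       time = 0), class = "Frame")
  sys <- suppressWarnings(assign_groups(sys, frame = fr))  # no lipids here
  res_roles <- sys$atoms$group_role[sys$residues$first + 1L]
  expect_equal(sum(res_roles == "ligand"), 20)
  expect_equal(sum(res_roles == "protein"), 6)
})

test_that("a spec without a water rule leaves water atoms as other", {
  atoms <- data.frame(name = c("OW", "HW1"), element = c("O", "H"),
                      residue_name = "SOL", residue_seq = 1,
                      stringsAsFactors = FALSE)
  spec <- selection_spec(list(list(residue_name = "^ALA$",
                                   role = "protein")))
  sys <- suppressWarnings(assign_groups(molecular_system(atoms), spec))
  expect_equal(sys$atoms$group_role, c("other", "other"))
  expect_warning(assign_groups(molecular_system(atoms), spec),
                 "matches no atoms")
})

test_that("selection specs load from YAML", {
  p <- tempfile(fileext = ".yaml")
  writeLines(c("rules:",
               "  - residue_name: '^SOL$'",
               "    role: water",
               "  - residue_name: '^ALA$'",
               "    role: protein"), p)
  spec <- read_selection_spec(p)
  expect_length(spec$rules, 2)
  expect_equal(spec$rules[[1]]$role, "water")
})
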