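# hand-enumerated event oracle: distance series [0.5,0.3,0.3,0.5,0.35,0.5]
# at cutoff 0.4 and dt 10 ps -> 2 events of 20 and 10 ps, mean 15 ps
test_that("binding events match the hand-enumerated oracle exactly", {
  d <- c(0.5, 0.3, 0.3, 0.5, 0.35, 0.5)
  ct <- d < 0.4
  ev <- binding_events(ct, dt = 10)
  expect_identical(ev$n_events, 2L)
  expect_equal(ev$durations, c(20, 10))
  expect_false(ev$censored_last)
  expect_equal(mean_residence_time(ev$durations, ev$censored_last), 15)
})

test_that("event counting needs a preceding unbound frame and flags censoring", {
  # all out of contact
  ev0 <- binding_events(rep(FALSE, 10), dt = 10)
  expect_equal(ev0$n_events, 0)
  expect_length(ev0$durations, 0)
  expect_true(is.na(mean_residence_time(ev0$durations)))
  # starts and ends in contact: the initial stretch is not an event
  ev1 <- binding_events(c(TRUE, TRUE, TRUE), dt = 10)
  expect_equal(ev1$n_events, 0)
  # an event running into the final frame is censored
  ev2 <- binding_events(c(FALSE, TRUE, TRUE), dt = 10)
  expect_equal(ev2$n_events, 1)
  expect_true(ev2$censored_last)
  expect_equal(ev2$durations, 20)
  # censored events are excluded from the mean unless requested
  expect_true(is.na(mean_residence_time(ev2$durations, ev2$censored_last)))
  expect_equal(mean_residence_time(ev2$durations, ev2$censored_last,
                                   include_censored = TRUE), 20)
  expect_equal(mean_residence_time(207), 207)
})

test_that("contact series reflect fixed geometries and the strict cutoff", {
  m <- make_markov_contact_trajectory(1, 0, 5, seed = 1, bound = 0.2,
                                      unbound = 1.0)
  # a = 1, b = 0: bound from the stationary distribution, stays bound
  s <- contact_series(m, 0, "water")
  expect_true(all(s$contact))
  expect_equal(proximity(s), 1.0)
  m2 <- make_markov_contact_trajectory(0, 1, 5, seed = 1, bound = 0.2,
                                       unbound = 1.0)
  s2 <- contact_series(m2, 0, "water")
  expect_false(any(s2$contact))
  expect_equal(proximity(s2), 0.0)
  expect_error(contact_series(m, 0, "ion"), "ion")
})

test_that("per-frame minima agree with hand-placed particles", {
  # one-atom residue at the box centre; three water particles, two parked
  # 2 nm away, the third moved by hand every frame (incl. one wrap case)
  atoms <- data.frame(
    name = c("CA", "OW", "OW", "OW"), element = c("C", "O", "O", "O"),
    residue_name = c("ALA", "SOL", "SOL", "SOL"), residue_seq = 1:4,
    group_role = c("protein", "water", "water", "water"),
    stringsAsFactors = FALSE)
  sys <- molecular_system(atoms)
  box <- diag(c(5, 5, 5))
  ctr <- c(2.5, 2.5, 2.5)
  moving <- list(ctr + c(0.30, 0, 0),        # 0.30
                 ctr + c(0, 0.50, 0),        # 0.50
                 ctr + c(0, 0, -0.35),       # 0.35
                 ctr + c(0.20, 0, 0),        # 0.20
                 c(0.2, 2.5, 2.5),           # direct 2.3, image 2.7 -> 2.3
                 ctr + c(0.45, 0, 0))        # 0.45
  d_expected <- c(0.30, 0.50, 0.35, 0.20, 2.0, 0.45)  # frame 5: parked pair
  coord_list <- lapply(moving, function(p) {
    rbind(ctr, p, ctr + c(2, 0, 0), ctr + c(0, 2, 0))
  })
  tr <- traj_from_coords(sys, coord_list, box)
  s <- contact_series(tr, 0, "water")
  expect_equal(s$distance, d_expected, tolerance = 1e-10)
  expect_equal(s$contact, s$distance < 0.4)
  # contacts are T F T T F F: the initial bound frame is no event, the
  # frame-3 entry is one event of two frames
  ev <- binding_events(s)
  expect_equal(ev$n_events, 1L)
  expect_equal(ev$durations, 20)
})

test_that("two-state Markov statistics match closed-form expectations within 3 SE", {
  a <- 0.02; b <- 0.2; dt <- 10; nf <- 5000; nruns <- 5
  runs <- lapply(1:nruns, function(k) {
    make_markov_contact_trajectory(a, b, nf, dt = dt, seed = k)
  })
  P <- numeric(nruns); nb <- numeric(nruns); durs <- list()
  for (k in seq_len(nruns)) {
    s <- contact_series(runs[[k]], 0, "water")
    P[k] <- proximity(s)
    ev <- binding_events(s)
    nb[k] <- ev$n_events
    d <- ev$durations
    if (ev$censored_last && length(d) > 0) d <- d[-length(d)]
    durs[[k]] <- d
  }
  p_exp <- a / (a + b)                  # 0.0909
  nb_exp <- nf * a * b / (a + b)        # ~90.9
  t_exp <- dt / b                       # 50 ps
  # SEs: events are roughly independent; P is autocorrelated, use the
  # spread of the 5 per-run estimates
  se_p <- sd(P) / sqrt(nruns)
  expect_lt(abs(mean(P) - p_exp), 3 * se_p + 1e-12)
  se_nb <- sd(nb) / sqrt(nruns)
  expect_lt(abs(mean(nb) - nb_exp), 3 * se_nb + 1e-12)
  alld <- unlist(durs)
  se_t <- sd(alld) / sqrt(length(alld))
  expect_lt(abs(mean(alld) - t_exp), 3 * se_t)
})

test_that("event durations conserve in-contact time", {
  set.seed(77)
  for (i in 1:20) {
    ct <- runif(60) < 0.4
    ev <- binding_events(ct, dt = 10)
    expect_lte(sum(ev$durations), sum(ct) * 10)
    r <- rle(ct)
    initial_bound <- r$values[1]
    if (!initial_bound) expect_equal(sum(ev$durations), sum(ct) * 10)
  }
})

test_that("group-level contact is the per-frame minimum over per-molecule series", {
  b <- make_pore_bundle(n_helices = 3, n_res_per_helix = 8, n_frames = 15,
                        n_water = 12, n_tail = 8, n_ion = 2, n_ligand = 2,
                        seed = 33)
  ri <- protein_residues(b$system)[3]
  s_group <- contact_series(b, ri, "water")
  s_mol <- contact_series_by_molecule(b, ri, "water")
  expect_length(s_mol, 12)
  dmin <- do.call(pmin, lapply(s_mol, `[[`, "distance"))
  expect_equal(s_group$distance, dmin, tolerance = 1e-12)
  expect_equal(s_group$contact, dmin < 0.4)
})

test_that("proximity is non-decreasing in the cutoff", {
  b <- make_pore_bundle(n_helices = 3, n_res_per_helix = 8, n_frames = 20,
                        n_water = 30, n_tail = 20, n_ion = 2, n_ligand = 2,
                        seed = 12)
  res <- protein_residues(b$system)[c(1, 5, 10)]
  for (ri in res) {
    Ps <- sapply(c(0.3, 0.4, 0.5, 0.7), function(co) {
      proximity(contact_series(b, ri, "water", cutoff = co))
    })
    expect_true(all(diff(Ps) >= 0))
  }
})

test_that("replica aggregation averages P and events, pools residence times", {
  m1 <- make_markov_contact_trajectory(0.1, 0.2, 300, seed = 21)
  m2 <- make_markov_contact_trajectory(0.1, 0.2, 300, seed = 22)
  st <- contact_stats_all(list(m1, m2), groups = "water")
  s1 <- contact_stats(m1, 0, "water")
  s2 <- contact_stats(m2, 0, "water")
  expect_equal(st$P, (s1$P + s2$P) / 2)
  expect_equal(st$n_events, (s1$n_events + s2$n_events) / 2)
  d1 <- s1$durations; if (s1$censored_last && length(d1)) d1 <- d1[-length(d1)]
  d2 <- s2$durations; if (s2$censored_last && length(d2)) d2 <- d2[-length(d2)]
  expect_equal(st$t_mean_ps, mean(c(d1, d2)))
  expect_equal(st$n_events_total, s1$n_events + s2$n_events)
  # identical replicas leave the statistics unchanged
  st5 <- contact_stats_all(rep(list(m1), 5), groups = "water")
  expect_equal(st5$P, s1$P)
  expect_equal(st5$n_events, s1$n_events * 1.0)
  # events summed when requested
  st_sum <- contact_stats_all(list(m1, m2), groups = "water",
                              nb_mode = "sum")
  expect_equal(st_sum$n_events, s1$n_events + s2$n_events)
})

test_that("membrane-embedded residues prefer lipid tails, solvent-exposed ones water", {
  b <- make_pore_bundle(n_frames = 40, seed = 5)
  gt <- attr(b, "ground_truth")
  st <- contact_stats_all(b, groups = c("water", "lipid_tail"))
  f1 <- get_frame(b, 1)
  sys <- b$system
  res <- protein_residues(sys)
  pos <- t(sapply(res, function(ri) {
    colMeans(f1$coordinates[residue_atoms(sys, ri) + 1L, , drop = FALSE])
  }))
  z <- pos[, 3]
  r <- sqrt((pos[, 1] - gt$axis_xy[1])^2 + (pos[, 2] - gt$axis_xy[2])^2)
  # membrane-embedded = mid-slab AND facing outwards; pore-facing slab
  # residues legitimately see the water channel instead
  slab <- z > gt$slab_z[1] + 0.4 & z < gt$slab_z[2] - 0.4 &
    r > gt$ring_radius
  outside <- z < gt$slab_z[1] - 0.2 | z > gt$slab_z[2] + 0.2
  w <- st[st$group == "water", ]; l <- st[st$group == "lipid_tail", ]
  expect_gt(mean(l$P[slab]), mean(w$P[slab]))
  expect_gt(mean(w$P[outside]), mean(l$P[outside]))
  expect_gt(mean(l$P[slab] > w$P[slab]), 0.7)
  expect_gt(mean(w$P[outside] > l$P[outside]), 0.9)
})

test_that("ligand bias concentrates ligand proximity on the chosen residues", {
  target_res <- c(29, 59)   # top residues of helices 1 and 2 (0-based)
  b <- make_pore_bundle(n_helices = 6, n_res_per_helix = 30, n_frames = 60,
                        n_water = 40, n_tail = 30, n_ion = 2, n_ligand = 12,
                        seed = 8, ligand_bias_residues = target_res,
                        bias_k = 0.2)
  st <- contact_stats_all(b, groups = "ligand")
  ranked <- st$residue_index[order(-st$P)]
  expect_true(all(target_res %in% ranked[1:6]))
})
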