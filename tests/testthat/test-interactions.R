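test_that("hydrogen-bond detection honours distance and angle thresholds", {
  # collinear D-H...A at 2.8 A -> detected
  f <- generate_interaction_fixture("hbond", distance = 2.8, angle = 180)
  ev <- detect_interactions(f$trajectory, types = "hbond")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$distance, 2.8, tolerance = 1e-9)
  expect_equal(ev$angle, 180, tolerance = 1e-6)

  # 3.2 A -> beyond the 3 A criterion
  f2 <- generate_interaction_fixture("hbond", distance = 3.2, angle = 180)
  expect_equal(nrow(detect_interactions(f2$trajectory, types = "hbond")), 0)

  # bent geometry (120 deg) at 2.8 A -> below the 150 degree criterion
  f3 <- generate_interaction_fixture("hbond", distance = 2.8, angle = 120)
  expect_equal(nrow(detect_interactions(f3$trajectory, types = "hbond")), 0)

  # just inside / outside both thresholds
  expect_equal(nrow(detect_interactions(
    generate_interaction_fixture("hbond", 2.9, 170)$trajectory, types = "hbond")), 1)
  expect_equal(nrow(detect_interactions(
    generate_interaction_fixture("hbond", 3.1, 170)$trajectory, types = "hbond")), 0)
  expect_equal(nrow(detect_interactions(
    generate_interaction_fixture("hbond", 2.9, 149)$trajectory, types = "hbond")), 0)

  # donor without an attached hydrogen is skipped with a warning
  f4 <- generate_interaction_fixture("hbond", 2.8, 180)
  donors <- data.frame(donor = 1L, hydrogen = NA_integer_, residue = 1L)
  acceptors <- data.frame(atom = 3L, residue = 2L)
  expect_warning(
    out <- detect_hbonds(f4$trajectory$coords[1, , ], donors, acceptors),
    "without attached hydrogen")
  expect_equal(nrow(out), 0)
})

test_that("hydrophobic contacts respect the distance cutoff and neighbour exclusion", {
  f <- generate_interaction_fixture("hydrophobic", distance = 3.8)
  ev <- detect_interactions(f$trajectory, types = "hydrophobic")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$res_a, 1)
  expect_equal(ev$res_b, 3)

  f2 <- generate_interaction_fixture("hydrophobic", distance = 4.2)
  expect_equal(nrow(detect_interactions(f2$trajectory, types = "hydrophobic")), 0)

  # sequence neighbours excluded even at contact distance: make residues 1,2
  # both hydrophobic and 3.8 A apart
  st <- f$structure
  st$atoms$resname <- c("LEU", "LEU", "GLY")
  st$atoms$x <- c(0, 3.8, 50)
  tr <- f$trajectory; tr$structure <- st
  tr$coords[1, , 1] <- st$atoms$x
  expect_equal(nrow(detect_hydrophobic(tr$coords[1, , ], st)), 0)
})

test_that("cation-pi and pi-pi detection follow their geometric criteria", {
  expect_equal(nrow(detect_interactions(
    generate_interaction_fixture("cation_pi", 5.5)$trajectory, types = "cation_pi")), 1)
  expect_equal(nrow(detect_interactions(
    generate_interaction_fixture("cation_pi", 6.3)$trajectory, types = "cation_pi")), 0)

  expect_equal(nrow(detect_interactions(
    generate_interaction_fixture("pi_pi", 4.5)$trajectory, types = "pi_pi")), 1)
  expect_equal(nrow(detect_interactions(
    generate_interaction_fixture("pi_pi", 5.4)$trajectory, types = "pi_pi")), 0)
  expect_equal(nrow(detect_interactions(
    generate_interaction_fixture("pi_pi", 4.9)$trajectory, types = "pi_pi")), 1)
  expect_equal(nrow(detect_interactions(
    generate_interaction_fixture("pi_pi", 5.1)$trajectory, types = "pi_pi")), 0)

  # a residue's own rings never pair with themselves (Trp carries two rings)
  f <- generate_interaction_fixture("pi_pi", 4.5)
  st <- f$structure
  groups <- interaction_groups(st)
  same_res <- list(groups$rings[[1]], groups$rings[[1]])
  expect_equal(nrow(detect_pi_pi(f$trajectory$coords[1, , ], same_res)), 0)

  # ligand cation partner is labelled like any other residue
  fc <- generate_interaction_fixture("cation_pi", 5.0)
  ev <- detect_interactions(fc$trajectory, types = "cation_pi")
  expect_equal(ev$atom_b, "NZ")
})

test_that("all detectors match a brute-force all-pairs scan on random frames", {
  crit <- interaction_criteria()
  for (seed in 1:20) {
    fr <- random_interaction_frame(seed)
    ev_pkg <- detect_interactions(fr$trajectory, crit)
    ev_bf <- oracle_events(fr$structure, fr$coords, crit)
    expect_identical(event_keys(ev_pkg), event_keys(ev_bf))
  }
})

test_that("detection is invariant under global rigid transforms", {
  crit <- interaction_criteria()
  fr <- random_interaction_frame(101)
  base <- event_keys(detect_interactions(fr$trajectory, crit))
  base_geom <- detect_interactions(fr$trajectory, crit)
  for (s in 1:3) {
    moved <- apply_rigid_traj(fr$trajectory, random_rigid(s))
    ev <- detect_interactions(moved, crit)
    expect_identical(event_keys(ev), base)
    expect_equal(ev$distance, base_geom$distance, tolerance = 1e-9)
  }
})

test_that("occupancy counts frames with events and is monotone in thresholds", {
  # synthetic events table over 4 frames
  ev <- data.frame(frame = c(1L, 2L, 2L, 3L), type = "hbond",
                   res_a = c(5L, 5L, 7L, 5L), atom_a = "OG",
                   res_b = c(9L, 9L, 9L, 9L), atom_b = "OG",
                   distance = 2.5, angle = 170)
  occ <- occupancy_table(ev, n_frames = 4, site = c(5L, 9L))
  expect_equal(occ$occupancy_pct, 75)           # events in 3 of 4 frames
  expect_equal(occ$min, 0)
  expect_equal(occ$max, 2)
  expect_equal(occ$mean, 1)
  expect_true(occ$min <= occ$mean && occ$mean <= occ$max)

  # every frame -> 100 %, none -> 0 %
  all_f <- ev[1:3, ]; all_f$frame <- 1:3
  expect_equal(occupancy_table(all_f, 3, 9L)$occupancy_pct, 100)
  expect_equal(occupancy_table(ev, 4, 99L, type = "hbond")$occupancy_pct, 0)
  expect_error(occupancy_table(ev, 4, integer(0)), class = "allopath_validation_error")

  # widening any distance threshold never loses events
  fr <- random_interaction_frame(55)
  tight <- interaction_criteria(hbond_max_dist = 2.5, hydrophobic_max_dist = 3.5,
                                cation_pi_max_dist = 5, pi_pi_max_centroid_dist = 4)
  wide <- interaction_criteria(hbond_max_dist = 3.5, hydrophobic_max_dist = 4.5,
                               cation_pi_max_dist = 7, pi_pi_max_centroid_dist = 6)
  ev_t <- detect_interactions(fr$trajectory, tight)
  ev_w <- detect_interactions(fr$trajectory, wide)
  expect_true(all(event_keys(ev_t) %in% event_keys(ev_w)))
  site <- sort(unique(fr$structure$atoms$residue_index))
  for (tp in c("hbond", "hydrophobic", "cation_pi", "pi_pi")) {
    o_t <- occupancy_table(ev_t, 1, site, type = tp)$occupancy_pct
    o_w <- occupancy_table(ev_w, 1, site, type = tp)$occupancy_pct
    expect_lte(o_t, o_w)
  }
})
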