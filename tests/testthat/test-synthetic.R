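test_that("ideal helix is deterministic and annotates as helix without hairpin bonds", {
  topo <- topo_phys
  expect_identical(make_ideal_helix(topo), make_ideal_helix(topo))
  h <- make_ideal_helix(topo)
  ss <- assign_secondary_structure(trajectory(topo, h))
  expect_equal(as.vector(unclass(ss)[1, 2:11]), rep("H", 10))
  # helical CA(i)-CA(i+3) distances sit in the 0.50-0.55 nm band
  ca <- h[ca_indices(topo), ]
  d3 <- sqrt(rowSums((ca[1:9, ] - ca[4:12, ])^2))
  expect_true(all(d3 > 0.50 & d3 < 0.55))
  for (def in condition_defaults("physiological")$hbonds) {
    expect_false(detect_hbond(h, topo, def))
  }
})

test_that("ideal hairpins satisfy their registries and differ from the helix", {
  topo <- topo_phys
  hp <- make_ideal_hairpin(topo, turn_definition(6),
                           condition_defaults("physiological")$hbonds)
  for (def in condition_defaults("physiological")$hbonds) {
    expect_true(detect_hbond(hp, topo, def))
  }
  hpa <- make_ideal_hairpin(topo_acid, turn_definition(5),
                            condition_defaults("acidic")$hbonds)
  for (def in condition_defaults("acidic")$hbonds) {
    expect_true(detect_hbond(hpa, topo_acid, def))
  }
  expect_gt(superpose(hp, make_ideal_helix(topo), ca_indices(topo))$rmsd, 0.3)
  # a geometrically impossible registry fails loudly
  expect_error(make_ideal_hairpin(topo, turn_definition(6),
                                  list(hbond_definition(2, 3))),
               "template")
})

test_that("template backbones keep ideal bond lengths within 5%", {
  topo <- topo_phys
  check_bonds <- function(frame) {
    at <- topo$atoms
    for (r in 1:12) {
      nI <- atom_index(topo, r, "N"); caI <- atom_index(topo, r, "CA")
      cI <- atom_index(topo, r, "C"); oI <- atom_index(topo, r, "O")
      expect_equal(sqrt(sum((frame[nI, ] - frame[caI, ])^2)), 0.1458, tolerance = 0.05)
      expect_equal(sqrt(sum((frame[caI, ] - frame[cI, ])^2)), 0.1525, tolerance = 0.05)
      expect_equal(sqrt(sum((frame[cI, ] - frame[oI, ])^2)), 0.1231, tolerance = 0.05)
      if (r < 12) {
        n2 <- atom_index(topo, r + 1, "N")
        expect_equal(sqrt(sum((frame[cI, ] - frame[n2, ])^2)), 0.1329, tolerance = 0.05)
      }
    }
  }
  ts <- turnpath:::template_set("physiological", topo)
  for (tpl in ts$templates) check_bonds(tpl$frame)
})

test_that("generation is bit-identical under a fixed seed", {
  sc <- mechanism_script("turn_first", n_frames = 300, seed = 99)
  g1 <- generate_trajectory(sc, topo_phys)
  g2 <- generate_trajectory(sc, topo_phys)
  expect_identical(g1$trajectory$coords, g2$trajectory$coords)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_trajectory(mechanism_script("turn_first", n_frames = 300, seed = 100),
                            topo_phys)
  expect_false(identical(g1$trajectory$coords, g3$trajectory$coords))
})

test_that("zero-noise scripts reproduce programmed onsets exactly", {
  topo <- topo_phys
  sc <- mechanism_script("turn_first", n_frames = 400, turn_onset_frame = 123,
                         noise_sigma = 0, seed = 1)
  g <- generate_trajectory(sc, topo)
  tt <- turn_track(g$trajectory, condition_defaults("physiological")$turn)
  expect_equal(min(which(tt[["Turn_9-6"]])), 123)
  expect_identical(tt[["Turn_9-6"]], g$truth$tracks[["Turn_9-6"]])
})

test_that("detected tracks match ground truth on at least 99% of frames across seeds", {
  topo <- topo_phys
  defs <- condition_defaults("physiological")
  for (seed in 1:10) {
    g <- generate_trajectory(mechanism_script("turn_first", n_frames = 400,
                                              noise_sigma = 0.01, seed = seed), topo)
    hb <- hbond_tracks(g$trajectory, defs$hbonds)
    tt <- turn_track(g$trajectory, defs$turn)
    agree <- c(mean(tt[[2]] == g$truth$tracks[[2]]),
               vapply(seq_along(defs$hbonds), function(j) {
                 lab <- defs$hbonds[[j]]$label
                 mean(hb[[lab]] == g$truth$tracks[[lab]])
               }, numeric(1)))
    expect_true(all(agree >= 0.99))
  }
})

test_that("turn-first scripts have no designated bond geometry before the turn onset", {
  topo <- topo_phys
  defs <- condition_defaults("physiological")
  g <- generate_trajectory(mechanism_script("turn_first", n_frames = 600,
                                            turn_onset_frame = 201, seed = 13), topo)
  hb <- hbond_tracks(g$trajectory, defs$hbonds)
  pre <- hb[hb$frame < 201, -1]
  expect_false(any(as.matrix(pre)))
})

test_that("dihedral-space interpolation yields valid geometry at switches", {
  topo <- topo_phys
  sc <- mechanism_script("turn_first", n_frames = 200, turn_onset_frame = 101,
                         noise_sigma = 0, switch_frames = 5, seed = 1)
  g <- generate_trajectory(sc, topo)
  # interpolated frames are flagged unassigned and keep ideal bond lengths
  expect_true(all(g$truth$basins[101:105] == "unassigned"))
  f <- get_frame(g$trajectory, 103)
  nI <- atom_index(topo, 6, "N"); caI <- atom_index(topo, 6, "CA")
  expect_equal(sqrt(sum((f[nI, ] - f[caI, ])^2)), 0.1458, tolerance = 0.01)
})

test_that("script validation rejects inconsistent programs", {
  expect_error(mechanism_script("turn_first", n_frames = 100, turn_onset_frame = 200),
               "outside trajectory")
  expect_error(mechanism_script("two_path", path_mixture = c(0.7, 0.2)), "sum to 1")
  expect_error(mechanism_script("turn_first", noise_sigma = -1), ">= 0")
  expect_error(mechanism_script("two_path", condition = "acidic"), "physiological")
  sched <- tibble::tibble(state = "helix", start = 1L, end = 500L)
  expect_error(mechanism_script("turn_first", n_frames = 100, basin_schedule = sched),
               "exceeds n_frames")
})

test_that("acidic-condition scripts annotate with the acidic registry", {
  defs <- condition_defaults("acidic")
  g <- generate_trajectory(mechanism_script("turn_first", n_frames = 400,
                                            condition = "acidic", seed = 31))
  hb <- hbond_tracks(g$trajectory, defs$hbonds)
  tt <- turn_track(g$trajectory, defs$turn)
  cc <- conditional_hbond_given_no_turn(tt, hb)
  expect_equal(cc$probability, rep(0, 5))
  st <- encode_states(tt, hb, rmsd_series(g$trajectory, make_ideal_hairpin(topo_acid)))
  expect_true(all(st$ycode %in% -1:5))
  expect_equal(max(st$ycode), 5)  # folded acidic hairpin carries all five bonds
})
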