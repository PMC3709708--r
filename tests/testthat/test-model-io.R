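test_that("topology construction records backbone atoms and invariants", {
  topo <- peptide_topology("MDVFMKGLSKAK")
  expect_equal(n_residues(topo), 12)
  expect_equal(topo$sequence, "MDVFMKGLSKAK")
  # residue 1 has no amide H; all others do (no proline in alpha-syn12)
  expect_true(is.na(atom_index(topo, 1, "H")))
  expect_true(all(!is.na(vapply(2:12, atom_index, 1L, topology = topo, name = "H"))))
  expect_equal(nrow(topo$atoms), 4 + 11 * 5)
  expect_equal(topo$atoms$atom, seq_len(nrow(topo$atoms)))  # unique and dense
  expect_error(peptide_topology("MDV"), "at least 4")
  expect_error(peptide_topology("MDXF"), "unknown residue")
})

test_that("trajectory constructor validates shapes, times and NA", {
  topo <- topo_phys
  h <- helix_frame()
  trj <- trajectory(topo, h)
  expect_equal(n_frames(trj), 1)
  expect_equal(trj$times, 0.05)  # default 50 ps spacing
  expect_error(trajectory(topo, h[-1, ]), "atoms")
  bad <- h; bad[3, 2] <- NA
  expect_error(trajectory(topo, bad), "NA")
  co <- array(rep(h, each = 3), c(3, nrow(h), 3))
  expect_error(trajectory(topo, co, times = c(1, 1, 2)), "strictly increasing")
  expect_error(get_frame(trj, 2), "out of range")
})

test_that("structure PDB round-trips through write/read at PDB precision", {
  topo <- topo_phys
  h <- helix_frame()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(trajectory(topo, h), path, dialect = "pdb")
  got <- read_structure(path)
  expect_equal(got$topology$sequence, "MDVFMKGLSKAK")
  expect_equal(n_residues(got$topology), 12)
  expect_lt(max(abs(get_frame(got$frame, 1) - h)), 1e-3)  # 0.001 A PDB grid / 10
})

test_that("read_structure rejects CA-only and missing-backbone files", {
  # hand-written CA-only PDB
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- vapply(1:5, function(i) {
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, i, i * 3.8, 0, 0)
  }, character(1))
  writeLines(c(lines, "END"), path)
  expect_error(read_structure(path), "missing backbone atom")
  expect_error(read_structure("no/such/file.pdb"), "not found")
})

test_that("missing amide hydrogens are rebuilt in the peptide plane", {
  topo <- topo_phys
  h <- helix_frame()
  # write a PDB without H atoms, re-read, compare rebuilt H to ideal H
  path <- withr::local_tempfile(fileext = ".pdb")
  keep <- topo$atoms$name != "H"
  sub <- topo$atoms[keep, ]
  xyz <- matrix(as.vector(t(h[keep, ])) * 10, nrow = 1)
  bio3d::write.pdb(file = path, xyz = xyz, resno = sub$resno, resid = sub$resid,
                   eleno = seq_len(nrow(sub)), elety = sub$name,
                   chain = rep("A", nrow(sub)))
  got <- read_structure(path)
  hIdx <- which(topo$atoms$name == "H")
  expect_lt(max(abs(get_frame(got$frame, 1)[hIdx, ] - h[hIdx, ])), 2e-3)
})

test_that("multi-model PDB trajectories keep frame order and count", {
  topo <- topo_phys
  frames <- lapply(1:5, function(i) helix_frame() + i * 0.01)
  trj <- stack_frames(topo, frames)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(trj, path, dialect = "pdb")
  txt <- readLines(path)
  expect_equal(sum(grepl("^MODEL", txt)), 5)
  expect_equal(sum(grepl("^ENDMDL", txt)), 5)
  back <- read_trajectory(path, topo, dialect = "pdb")
  expect_equal(n_frames(back), 5)
  for (i in 1:5) expect_lt(max(abs(get_frame(back, i) - frames[[i]])), 1e-3)
})

test_that("frame-array dialect round-trips bit-exactly", {
  topo <- topo_phys
  set.seed(42)
  frames <- lapply(1:50, function(i) helix_frame() + rnorm(59 * 3, 0, 0.02))
  trj <- stack_frames(topo, frames)
  path <- withr::local_tempfile(fileext = ".dat")
  write_trajectory(trj, path, dialect = "frame_array")
  back <- read_trajectory(path, topo)
  expect_identical(back$coords, trj$coords)
  expect_identical(back$times, trj$times)
  # atom-count mismatch is reported
  small <- peptide_topology("MKGL")
  expect_error(read_trajectory(path, small), "atom-count mismatch")
  # empty file is a parse error, not an empty trajectory
  empty <- withr::local_tempfile(fileext = ".dat")
  file.create(empty)
  expect_error(read_trajectory(empty, topo), "empty")
})

test_that("csv-track secondary-structure files round-trip and validate", {
  ss <- matrix("C", 4, 12)
  ss[, 6:9] <- "T"
  ss[2, 1] <- "H"
  class(ss) <- c("ss_assignment", "matrix", "array")
  path <- withr::local_tempfile(fileext = ".csv")
  write_ss_assignment(ss, path)
  back <- read_ss_assignment(path, "csv")
  expect_equal(unclass(back)[, ], unclass(ss)[, ], ignore_attr = TRUE)
  # all-T window means the turn is derivable as always-true
  tt <- turn_track(NULL, turn_definition(6), method = "all_T", ss = back)
  expect_true(all(tt[["Turn_9-6"]]))
  # unknown code errors
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,residue,code", "1,1,Q"), bad)
  expect_error(read_ss_assignment(bad, "csv"), "unknown code.*Q")
})

test_that("STRIDE and DSSP snapshot dialects parse with code mapping", {
  stride <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "REM  -------------------- Secondary structure summary -------------------",
    sprintf("ASG  %s A %4d %4d    %s    %-12s   %7.2f   %7.2f   %7.1f      ~~~~",
            c("MET", "ASP", "VAL", "PHE"), 1:4, 1:4, c("H", "H", "G", "C"),
            c("AlphaHelix", "AlphaHelix", "310Helix", "Coil"),
            -57, -47, 100)), stride)
  ss <- read_ss_assignment(stride, "stride")
  expect_equal(as.vector(unclass(ss)), c("H", "H", "H", "C"))

  # hand-built 3-line DSSP with a bend (S) and a bridge (B)
  dssp <- withr::local_tempfile(fileext = ".dssp")
  writeLines(c(
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    "    1    1 A M  S              0   0  200",
    "    2    2 A D  B              0   0  150",
    "    3    3 A V  T              0   0  120"), dssp)
  ss2 <- read_ss_assignment(dssp, "dssp")
  expect_equal(as.vector(unclass(ss2)), c("C", "E", "T"))
  expect_equal(attr(ss2, "bend_count"), 1L)
})

test_that("boolean track csv export round-trips exactly", {
  set.seed(9)
  tr <- tibble::tibble(frame = 1:40,
                       `Turn_9-6` = runif(40) > 0.5,
                       `HB_4-11` = runif(40) > 0.7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tr, path)
  expect_identical(read_tracks(path), tr)
})
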