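#' Hydrogen-bond definition
#'
#' A backbone hydrogen bond from the amide N-H of the donor residue to the
#' carbonyl O of the acceptor residue, labelled `HB_d-a` (donor first), e.g.
#' `HB_4-11` is the bond from the amide NH of residue 4 to the carbonyl O of
#' residue 11.
#'
#' @param donor,acceptor 1-based residue indices; must differ.
#' @return A list of class `hbond_definition` with `donor`, `acceptor`,
#'   `label`.
#' @export
hbond_definition <- function(donor, acceptor) {
  donor <- as.integer(donor)
  acceptor <- as.integer(acceptor)
  if (donor == acceptor) abort("donor and acceptor must differ")
  structure(list(donor = donor, acceptor = acceptor,
                 label = sprintf("HB_%d-%d", donor, acceptor)),
            class = "hbond_definition")
}

#' Geometric hydrogen-bond criteria
#'
#' A bond is present when the hydrogen-acceptor distance is *less than*
#' `max_distance` and the donor-hydrogen-acceptor (N-H...O) interior angle is
#' *more than* `min_angle`; both inequalities strict. The defaults (2.5 A,
#' 135 deg) are the GROMOS++ analysis criteria.
#'
#' @param max_distance Maximum H...O distance in nm (default 0.25).
#' @param min_angle Minimum N-H...O angle in degrees (default 135).
#' @return A list of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_distance = 0.25, min_angle = 135) {
  if (max_distance <= 0) abort("max_distance must be positive")
  if (min_angle <= 0 || min_angle >= 180) abort("min_angle must be in (0, 180)")
  structure(list(max_distance = max_distance, min_angle = min_angle),
            class = "hbond_criteria")
}

#' Beta-turn definition
#'
#' A four-residue turn window from `start` to `start + 3`, labelled with the
#' later residue first as in `Turn_9-6` (the turn over residues 6-9).
#'
#' @param start 1-based index of the first residue of the window.
#' @return A list of class `turn_definition` with `start`, `end`, `label`.
#' @export
turn_definition <- function(start) {
  start <- as.integer(start)
  structure(list(start = start, end = start + 3L,
                 label = sprintf("Turn_%d-%d", start + 3L, start)),
            class = "turn_definition")
}

# resolve the H/O/N atom indices of a bond; errors on undefined donors
hbond_atom_indices <- function(topology, def) {
  nres <- n_residues(topology)
  if (def$donor < 1 || def$donor > nres || def$acceptor < 1 || def$acceptor > nres) {
    abort(sprintf("%s outside peptide (1..%d)", def$label, nres))
  }
  h <- atom_index(topology, def$donor, "H")
  if (is.na(h)) {
    abort(sprintf("undefined donor: residue %d has no amide H (%s)",
                  def$donor, def$label))
  }
  list(h = h, o = atom_index(topology, def$acceptor, "O"),
       n = atom_index(topology, def$donor, "N"))
}

#' Detect a hydrogen bond in a single frame
#'
#' @param frame `atoms x 3` coordinate matrix (nm).
#' @param topology The matching [peptide_topology()].
#' @param def An [hbond_definition()].
#' @param criteria An [hbond_criteria()] object.
#' @return Logical scalar.
#' @export
detect_hbond <- function(frame, topology, def, criteria = hbond_criteria()) {
  ai <- hbond_atom_indices(topology, def)
  d <- dist_rows(frame[ai$h, ], frame[ai$o, ])
  ang <- angle_rows(frame[ai$n, ], frame[ai$h, ], frame[ai$o, ])
  unname(d < criteria$max_distance & ang > criteria$min_angle)
}

#' Per-frame hydrogen-bond tracks
#'
#' Evaluates each hydrogen-bond definition over every frame of a trajectory.
#'
#' @param trj A [trajectory()] object.
#' @param definitions List of [hbond_definition()] objects.
#' @param criteria An [hbond_criteria()] object.
#' @return A tibble with a `frame` column and one logical column per bond
#'   label. Per-track occurrence probabilities are available via
#'   [occurrence_table()].
#' @export
hbond_tracks <- function(trj, definitions, criteria = hbond_criteria()) {
  out <- tibble(frame = seq_len(n_frames(trj)))
  for (def in definitions) {
    ai <- hbond_atom_indices(trj$topology, def)
    H <- matrix(trj$coords[, ai$h, ], ncol = 3)
    O <- matrix(trj$coords[, ai$o, ], ncol = 3)
    N <- matrix(trj$coords[, ai$n, ], ncol = 3)
    d <- dist_rows(H, O)
    ang <- angle_rows(N, H, O)
    out[[def$label]] <- d < criteria$max_distance & ang > criteria$min_angle
  }
  out
}

#' Geometric secondary-structure assignment
#'
#' A transparent geometry-based assigner producing per-residue codes H
#' (helix), E (strand), T (turn) and C (coil/other) with precedence
#' H > E > T > C. Helix: a residue and its existing neighbours have phi/psi
#' within -57+/-30, -47+/-30 degrees. Strand: phi/psi in the beta region
#' (phi in \[-180,-45\], psi in \[90,180\] or \[-180,-150\]) with an
#' inter-strand backbone hydrogen bond (|donor-acceptor| >= 3) within two
#' residues. Turn: a window i..i+3 with d(CAi, CAi+3) < `turn_ca_cutoff` and
#' interior residues not helical. Terminal residues with undefined dihedrals
#' default to C. This is not a STRIDE re-implementation; externally computed
#' STRIDE/DSSP assignments can be supplied via [read_ss_assignment()].
#'
#' @param trj A [trajectory()] object.
#' @param criteria [hbond_criteria()] used for the strand H-bond test.
#' @param turn_ca_cutoff CA(i)-CA(i+3) distance cutoff in nm (default 0.7).
#' @return A `frames x residues` character matrix of codes, class
#'   `ss_assignment`.
#' @export
assign_secondary_structure <- function(trj, criteria = hbond_criteria(),
                                       turn_ca_cutoff = 0.7) {
  topo <- trj$topology
  nres <- n_residues(topo)
  nf <- n_frames(trj)
  dih <- backbone_dihedrals(trj)
  in_helix <- function(phi, psi) {
    !is.na(phi) & !is.na(psi) & abs(phi + 57) <= 30 & abs(psi + 47) <= 30
  }
  in_beta <- function(phi, psi) {
    !is.na(phi) & !is.na(psi) & phi >= -180 & phi <= -45 &
      ((psi >= 90 & psi <= 180) | (psi >= -180 & psi <= -150))
  }
  helix_compat <- in_helix(dih$phi, dih$psi)            # frames x res
  # H: residue and both existing neighbours helix-compatible; termini stay C
  H <- matrix(FALSE, nf, nres)
  for (r in 2:(nres - 1)) {
    ok <- helix_compat[, r]
    if (r > 2) ok <- ok & helix_compat[, r - 1]
    if (r < nres - 1) ok <- ok & helix_compat[, r + 1]
    H[, r] <- ok
  }
  # generic inter-strand backbone H-bond per residue (frames x res)
  hb_res <- matrix(FALSE, nf, nres)
  crit <- criteria
  for (d in seq_len(nres)) {
    hI <- atom_index(topo, d, "H")
    if (is.na(hI)) next
    for (a in seq_len(nres)) {
      if (abs(d - a) < 3) next
      oI <- atom_index(topo, a, "O")
      Hm <- matrix(trj$coords[, hI, ], ncol = 3)
      Om <- matrix(trj$coords[, oI, ], ncol = 3)
      Nm <- matrix(trj$coords[, atom_index(topo, d, "N"), ], ncol = 3)
      hit <- dist_rows(Hm, Om) < crit$max_distance &
        angle_rows(Nm, Hm, Om) > crit$min_angle
      if (any(hit)) {
        hb_res[hit, d] <- TRUE
        hb_res[hit, a] <- TRUE
      }
    }
  }
  near_hb <- hb_res
  for (off in 1:2) {
    near_hb[, seq_len(nres - off)] <- near_hb[, seq_len(nres - off)] |
      hb_res[, (1 + off):nres]
    near_hb[, (1 + off):nres] <- near_hb[, (1 + off):nres] |
      hb_res[, seq_len(nres - off)]
  }
  E <- in_beta(dih$phi, dih$psi) & near_hb & !H
  # turn windows on CA distances
  caI <- ca_indices(topo)
  Tm <- matrix(FALSE, nf, nres)
  for (i in seq_len(nres - 3)) {
    ca_i <- matrix(trj$coords[, caI[i], ], ncol = 3)
    ca_j <- matrix(trj$coords[, caI[i + 3], ], ncol = 3)
    win <- dist_rows(ca_i, ca_j) < turn_ca_cutoff & !H[, i + 1] & !H[, i + 2]
    for (r in i:(i + 3)) Tm[win, r] <- TRUE
  }
  codes <- matrix("C", nf, nres)
  codes[Tm & !E & !H] <- "T"
  codes[E] <- "E"
  codes[H] <- "H"
  structure(codes, class = c("ss_assignment", "matrix", "array"))
}

#' Per-frame beta-turn track
#'
#' Whether a given turn is formed in each frame. The default `"native"`
#' method applies the window criterion directly (CA(i)-CA(i+3) distance below
#' the cutoff with non-helical interior residues); `"all_T"` requires all
#' four window residues to carry code T in a supplied secondary-structure
#' assignment (useful with imported STRIDE/DSSP tracks, where E takes
#' precedence on the hydrogen-bonded flanking pair).
#'
#' @param trj A [trajectory()] object (native method), or `NULL` when `ss`
#'   is supplied.
#' @param turn A [turn_definition()].
#' @param method `"native"` or `"all_T"`.
#' @param ss An `ss_assignment` matrix (required for `"all_T"`).
#' @param turn_ca_cutoff CA distance cutoff in nm for the native criterion.
#' @return A tibble with columns `frame` and one logical column named by the
#'   turn label.
#' @export
turn_track <- function(trj, turn, method = c("native", "all_T"), ss = NULL,
                       turn_ca_cutoff = 0.7) {
  method <- match.arg(method)
  nres_needed <- turn$end
  if (method == "native") {
    topo <- trj$topology
    if (turn$start < 1 || nres_needed > n_residues(topo)) {
      abort(sprintf("%s outside peptide", turn$label))
    }
    caI <- ca_indices(topo)
    ca_i <- matrix(trj$coords[, caI[turn$start], ], ncol = 3)
    ca_j <- matrix(trj$coords[, caI[turn$end], ], ncol = 3)
    dih <- backbone_dihedrals(trj)
    hc <- function(r) {
      !is.na(dih$phi[, r]) & !is.na(dih$psi[, r]) &
        abs(dih$phi[, r] + 57) <= 30 & abs(dih$psi[, r] + 47) <= 30
    }
    val <- dist_rows(ca_i, ca_j) < turn_ca_cutoff &
      !hc(turn$start + 1) & !hc(turn$start + 2)
    out <- tibble(frame = seq_len(n_frames(trj)))
  } else {
    if (is.null(ss)) abort("method 'all_T' needs an ss assignment")
    if (nres_needed > ncol(ss)) abort(sprintf("%s outside peptide", turn$label))
    val <- rowSums(ss[, turn$start:turn$end, drop = FALSE] == "T") == 4
    out <- tibble(frame = seq_len(nrow(ss)))
  }
  out[[turn$label]] <- as.logical(val)
  out
}

#' Per-residue turn and strand occurrence propensities
#'
#' Fraction of frames in which each residue carries code T and code E,
#' the per-residue secondary-structure propensity profile.
#'
#' @param ss An `ss_assignment` matrix (frames x residues), e.g. from
#'   [assign_secondary_structure()] or [read_ss_assignment()].
#' @return A tibble with columns `residue`, `p_turn`, `p_strand`, `p_helix`.
#' @export
residue_propensities <- function(ss) {
  if (nrow(ss) < 1) abort("no frames in assignment")
  tibble(residue = seq_len(ncol(ss)),
         p_turn = colMeans(unclass(ss) == "T"),
         p_strand = colMeans(unclass(ss) == "E"),
         p_helix = colMeans(unclass(ss) == "H"))
}

#' Default turn and hydrogen-bond registry for a pH condition
#'
#' The most-clustered hairpin registries: at physiological pH Turn_9-6 with
#' the four bonds HB_9-6, HB_6-9, HB_11-4, HB_4-11; at acidic pH Turn_8-5
#' with the five bonds HB_8-5, HB_5-8, HB_10-3, HB_3-10, HB_12-1.
#'
#' @param condition `"physiological"` or `"acidic"`.
#' @return A list with `turn` (a [turn_definition()]) and `hbonds` (list of
#'   [hbond_definition()] objects, the designated ordered set).
#' @export
condition_defaults <- function(condition = c("physiological", "acidic")) {
  condition <- match.arg(condition)
  if (condition == "physiological") {
    list(turn = turn_definition(6),
         hbonds = list(hbond_definition(9, 6), hbond_definition(6, 9),
                       hbond_definition(11, 4), hbond_definition(4, 11)))
  } else {
    list(turn = turn_definition(5),
         hbonds = list(hbond_definition(8, 5), hbond_definition(5, 8),
                       hbond_definition(10, 3), hbond_definition(3, 10),
                       hbond_definition(12, 1)))
  }
}
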