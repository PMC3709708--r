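# Synthetic backbone-trajectory generator. Templates are ideal-geometry
# backbones (NeRF-built from ideal bond lengths/angles) whose phi/psi
# dihedrals are refined by a deterministic penalized least-squares fit so
# that each template reproduces a programmed structural state: which
# designated hydrogen bonds are formed, whether the turn is closed, and the
# Calpha RMSD from the folded reference. Construction is verified against
# the package's own annotators and fails loudly if a programmed state is not
# realized.

#' Ideal alpha-helical frame
#'
#' Backbone built from ideal bond lengths and angles with phi = -57,
#' psi = -47, omega = 180 degrees; amide hydrogens in the peptide plane.
#' Deterministic: repeated calls return identical coordinates.
#'
#' @param topology A [peptide_topology()] object.
#' @return An `atoms x 3` coordinate matrix (nm).
#' @export
make_ideal_helix <- function(topology) {
  nres <- n_residues(topology)
  frame_from_dihedrals(topology, rep(-57, nres), rep(-47, nres))
}

# base dihedral template: extended strands with a two-residue type-I' turn
base_hairpin_dihedrals <- function(nres, turn_center) {
  phi <- rep(-135, nres)
  psi <- rep(135, nres)
  phi[turn_center[1]] <- 55; psi[turn_center[1]] <- 40
  phi[turn_center[2]] <- 78; psi[turn_center[2]] <- 6
  list(phi = phi, psi = psi)
}

hb_geometry <- function(at, donor, acceptor) {
  H <- at[[donor]]$H
  O <- at[[acceptor]]$O
  N <- at[[donor]]$N
  c(dist = sqrt(sum((H - O)^2)),
    ang = angle_rows(matrix(N, 1), matrix(H, 1), matrix(O, 1)))
}

# penalized dihedral refinement toward a programmed structural state
refine_template <- function(nres, turn_center, bonds_on, bonds_off = list(),
                            rmsd_target = NULL, ref_ca = NULL,
                            rmsd_target2 = NULL, ref_ca2 = NULL,
                            turn_open = NULL, turn_closed = NULL,
                            start = NULL, maxit = 250) {
  tpl <- start %||% base_hairpin_dihedrals(nres, turn_center)
  # when the turn must stay closed the central phi values are pinned at the
  # (positive) type-I' values, keeping the window out of the helical region
  free_phi <- if (is.null(turn_open)) {
    setdiff(2:(nres - 1), turn_center)
  } else {
    2:(nres - 1)
  }
  free_psi <- 2:(nres - 1)
  nphi <- length(free_phi)
  npsi <- length(free_psi)
  x0 <- c(tpl$phi[free_phi], tpl$psi[free_psi])
  pair_i <- pair_j <- integer(0)
  for (i in seq_len(nres - 2)) {
    pair_i <- c(pair_i, rep(i, nres - i - 1))
    pair_j <- c(pair_j, (i + 2):nres)
  }
  yc <- yc2 <- NULL
  if (!is.null(rmsd_target)) {
    yc <- sweep(ref_ca, 2, colMeans(ref_ca))
  }
  if (!is.null(rmsd_target2)) {
    yc2 <- sweep(ref_ca2, 2, colMeans(ref_ca2))
  }
  objective <- function(x) {
    phi <- tpl$phi; psi <- tpl$psi
    phi[free_phi] <- x[1:nphi]; psi[free_psi] <- x[nphi + 1:npsi]
    at <- build_backbone_atoms(nres, phi, psi)
    pen <- 0
    # formed bonds aim well inside the detection criteria (d in 0.17-0.19 nm,
    # angle >= 168 deg): coordinate noise of 0.01 nm works out to ~8-10 deg of
    # angular jitter over the short N-H lever, so the angular margin carries
    # most of the robustness of the ground-truth tracks
    for (b in bonds_on) {
      g <- hb_geometry(at, b[1], b[2])
      pen <- pen + 400 * (max(0, g[1] - 0.19)^2 + max(0, 0.17 - g[1])^2) +
        2e-4 * max(0, 168 - g[2])^2
    }
    # absent bonds are pushed past d >= 0.32 nm or angle <= 104 deg
    for (b in bonds_off) {
      g <- hb_geometry(at, b[1], b[2])
      pen <- pen + 100 * max(0, 0.32 - g[1])^2 * max(0, (g[2] - 104) / 76)^2
    }
    ca <- t(vapply(at, function(a) a$CA, numeric(3)))
    clash <- dist_rows(ca[pair_i, , drop = FALSE], ca[pair_j, , drop = FALSE])
    pen <- pen + 50 * sum(pmax(0, 0.40 - clash)^2)
    if (!is.null(rmsd_target)) {
      xc <- sweep(ca, 2, colMeans(ca))
      r <- kabsch_rmsd_centred(xc, yc, sum(xc^2) + sum(yc^2), nres)
      pen <- pen + 30 * (r - rmsd_target)^2
    }
    if (!is.null(rmsd_target2)) {
      xc <- sweep(ca, 2, colMeans(ca))
      r2 <- kabsch_rmsd_centred(xc, yc2, sum(xc^2) + sum(yc2^2), nres)
      pen <- pen + 30 * (r2 - rmsd_target2)^2
    }
    if (!is.null(turn_open)) {
      d <- sqrt(sum((at[[turn_open[1]]]$CA - at[[turn_open[2]]]$CA)^2))
      pen <- pen + 100 * max(0, 0.78 - d)^2
    }
    if (!is.null(turn_closed)) {
      d <- sqrt(sum((at[[turn_closed[1]]]$CA - at[[turn_closed[2]]]$CA)^2))
      pen <- pen + 100 * max(0, d - 0.62)^2
    }
    pen + 1e-6 * sum((x - x0)^2)
  }
  fit <- optim(x0, objective, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-10))
  phi <- tpl$phi; psi <- tpl$psi
  phi[free_phi] <- fit$par[1:nphi]; psi[free_psi] <- fit$par[nphi + 1:npsi]
  list(phi = phi, psi = psi, objective = fit$value)
}

# verify a built frame realizes the programmed bond/turn states
verify_template <- function(frame, topology, turn, registry, formed,
                            turn_formed, what) {
  trj1 <- trajectory(topology, frame)
  for (i in seq_along(registry)) {
    got <- detect_hbond(frame, topology, registry[[i]])
    if (got != formed[i]) {
      abort(sprintf("template '%s': bond %s is %s but should be %s",
                    what, registry[[i]]$label,
                    if (got) "formed" else "absent",
                    if (formed[i]) "formed" else "absent"))
    }
  }
  tt <- turn_track(trj1, turn)[[turn$label]]
  if (tt != turn_formed) {
    abort(sprintf("template '%s': turn %s state mismatch", what, turn$label))
  }
  invisible(TRUE)
}

#' Ideal beta-hairpin frame satisfying a hydrogen-bond registry
#'
#' Two antiparallel strands joined by a type-I'-like turn at the given
#' window; the dihedrals are refined so every registry bond satisfies the
#' default hydrogen-bond criteria. Construction is verified with
#' [detect_hbond()] and fails with an error if the registry cannot be
#' realized (e.g. geometrically inconsistent with the turn placement).
#' Deterministic; results are cached per registry.
#'
#' @param topology A [peptide_topology()] object.
#' @param turn A [turn_definition()]; defaults to the topology's
#'   protonation-state registry.
#' @param registry List of [hbond_definition()] objects that must all be
#'   satisfied; defaults likewise.
#' @return An `atoms x 3` coordinate matrix (nm).
#' @examples
#' topo <- syn12_topology()
#' hp <- make_ideal_hairpin(topo)
#' detect_hbond(hp, topo, hbond_definition(4, 11))
#' @export
make_ideal_hairpin <- function(topology, turn = NULL, registry = NULL) {
  if (is.null(turn) || is.null(registry)) {
    cond <- if (topology$protonation == "acidic") "acidic" else "physiological"
    defs <- condition_defaults(cond)
    turn <- turn %||% defs$turn
    registry <- registry %||% defs$hbonds
  }
  key <- paste0("hairpin|", n_residues(topology), "|", turn$label, "|",
                paste(vapply(registry, `[[`, "", "label"), collapse = ","))
  if (!is.null(the[[key]])) return(the[[key]])
  nres <- n_residues(topology)
  if (turn$end > nres) abort("turn window outside peptide")
  bonds_on <- lapply(registry, function(d) c(d$donor, d$acceptor))
  fit <- refine_template(nres, c(turn$start + 1, turn$start + 2), bonds_on)
  frame <- frame_from_dihedrals(topology, fit$phi, fit$psi)
  verify_template(frame, topology, turn, registry,
                  rep(TRUE, length(registry)), TRUE, "hairpin")
  the[[key]] <- frame
  frame
}

# the named template set for one condition: helix, U1, (U2), F, folded,
# collapse -- each with ground-truth turn/bond states
template_set <- function(condition, topology) {
  key <- paste0("set|", condition, "|", n_residues(topology))
  if (!is.null(the[[key]])) return(the[[key]])
  defs <- condition_defaults(condition)
  turn <- defs$turn
  registry <- defs$hbonds
  nb <- length(registry)
  nres <- n_residues(topology)
  tc <- c(turn$start + 1, turn$start + 2)
  tw <- c(turn$start, turn$end)
  bonds <- lapply(registry, function(d) c(d$donor, d$acceptor))
  folded_frame <- make_ideal_hairpin(topology, turn, registry)
  ref_ca <- folded_frame[ca_indices(topology), ]

  build <- function(name, on_idx, rmsd_target = NULL, turn_state = TRUE,
                    helix = FALSE, away_from = NULL, away_rmsd = 0.14) {
    if (helix) {
      frame <- make_ideal_helix(topology)
    } else {
      fit <- refine_template(
        nres, tc, bonds[on_idx], bonds_off = bonds[setdiff(seq_len(nb), on_idx)],
        rmsd_target = rmsd_target, ref_ca = ref_ca,
        rmsd_target2 = if (!is.null(away_from)) away_rmsd,
        ref_ca2 = if (!is.null(away_from)) away_from[ca_indices(topology), ],
        turn_open = if (!turn_state) tw, turn_closed = if (turn_state) tw)
      frame <- frame_from_dihedrals(topology, fit$phi, fit$psi)
    }
    formed <- seq_len(nb) %in% on_idx
    verify_template(frame, topology, turn, registry, formed, turn_state, name)
    list(name = name, frame = frame, turn = turn_state,
         bonds = setNames(formed, vapply(registry, `[[`, "", "label")))
  }

  tpl <- list(helix = build("helix", integer(0), turn_state = FALSE, helix = TRUE),
              folded = list(name = "folded", frame = folded_frame, turn = TRUE,
                            bonds = setNames(rep(TRUE, nb),
                                             vapply(registry, `[[`, "", "label"))))
  # the F basin is a two-conformer mixture: both members sit at the basin's
  # RMSD from the folded structure but apart from each other, emulating the
  # conformational heterogeneity of a real basin (and keeping the folded
  # structure the unambiguous most-clustered centre at the 0.1 nm cutoff)
  if (condition == "physiological") {
    tpl$U1 <- build("U1", integer(0), rmsd_target = 0.23)
    tpl$U2 <- build("U2", 1:2, rmsd_target = 0.38)
    tpl$F <- build("F", 2:4, rmsd_target = 0.08)
    tpl$F2 <- build("F2", 2:4, rmsd_target = 0.08, away_from = tpl$F$frame)
    tpl$collapse <- build("collapse", 3:4, turn_state = FALSE)
  } else {
    tpl$U1 <- build("U1", integer(0), rmsd_target = 0.27)
    tpl$F <- build("F", 2:nb, rmsd_target = 0.08)
    tpl$F2 <- build("F2", 2:nb, rmsd_target = 0.08, away_from = tpl$F$frame)
    tpl$collapse <- build("collapse", 3:4, turn_state = FALSE)
  }
  sep <- superpose(tpl$F2$frame, tpl$F$frame, ca_indices(topology))$rmsd
  if (sep < 0.11) {
    abort(sprintf("F-basin conformers insufficiently separated (%.3f nm)", sep))
  }
  out <- list(templates = tpl, turn = turn, registry = registry,
              folded_ca = ref_ca)
  the[[key]] <- out
  out
}

#' Programmed folding-mechanism script
#'
#' Describes a synthetic trajectory: which mechanism generates it, where the
#' programmed onsets lie, how basins are visited and how much Gaussian
#' coordinate noise is added. Three mechanism modes are available:
#' `"turn_first"` (zipper: helix, then turn-formed basin U1, then hydrogen
#' bonds zip through F to the folded hairpin; no designated bond geometry
#' exists before the turn onset), `"hbond_first"` (collapse: the outer
#' bonds form while the turn window is still open, then the turn closes) and
#' `"two_path"` (repeated folding events routed U1->F or U2->F with the
#' given mixture). A custom `basin_schedule` (tibble with columns `state`,
#' `start`, `end` over the states helix/U1/U2/F/folded/collapse) overrides
#' the mode-derived schedule.
#'
#' @param mode `"turn_first"`, `"hbond_first"` or `"two_path"`.
#' @param n_frames Number of frames (default 5000).
#' @param condition `"physiological"` or `"acidic"` (two-path folding is a
#'   physiological-pH phenomenon and requires U2).
#' @param turn_onset_frame First frame with the turn formed (turn-first
#'   default: 19% into the trajectory, giving turn occupancy 0.81).
#' @param hbond_onset_frames Frames at which successive bond-gaining states
#'   begin (turn-first mode; one per remaining state on the route).
#' @param path_mixture Probabilities of the U1->F and U2->F routes
#'   (two-path mode); must sum to 1.
#' @param n_events Number of folding events (two-path mode, default 20).
#' @param noise_sigma Isotropic Gaussian coordinate noise, nm (default
#'   0.005), truncated at three sigma.
#' @param switch_frames Frames of dihedral-space interpolation at each state
#'   switch (default 0: instantaneous, programmed onsets exact).
#' @param basin_schedule Optional explicit schedule tibble.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `mechanism_script`.
#' @export
mechanism_script <- function(mode = c("turn_first", "hbond_first", "two_path"),
                             n_frames = 5000,
                             condition = c("physiological", "acidic"),
                             turn_onset_frame = NULL,
                             hbond_onset_frames = NULL,
                             path_mixture = c(0.7, 0.3),
                             n_events = 20,
                             noise_sigma = 0.005,
                             switch_frames = 0,
                             basin_schedule = NULL,
                             seed = 1) {
  mode <- match.arg(mode)
  condition <- match.arg(condition)
  if (noise_sigma < 0) abort("noise_sigma must be >= 0")
  if (mode == "two_path") {
    if (condition != "physiological") abort("two_path mode requires the physiological condition (basin U2)")
    if (abs(sum(path_mixture) - 1) > 1e-9) abort("path_mixture must sum to 1")
  }
  if (!is.null(turn_onset_frame) &&
      (turn_onset_frame < 1 || turn_onset_frame > n_frames)) {
    abort("turn_onset_frame outside trajectory")
  }
  if (!is.null(hbond_onset_frames) && any(hbond_onset_frames > n_frames)) {
    abort("hbond_onset_frames outside trajectory")
  }
  if (!is.null(basin_schedule) && max(basin_schedule$end) > n_frames) {
    abort("basin_schedule exceeds n_frames")
  }
  structure(list(mode = mode, n_frames = as.integer(n_frames),
                 condition = condition, turn_onset_frame = turn_onset_frame,
                 hbond_onset_frames = hbond_onset_frames,
                 path_mixture = path_mixture, n_events = n_events,
                 noise_sigma = noise_sigma, switch_frames = switch_frames,
                 basin_schedule = basin_schedule, seed = as.integer(seed)),
            class = "mechanism_script")
}

# mode-specific default schedule; fractions for turn_first chosen to emulate
# the reported turn occupancy (0.81) and the Boltzmann weights of the basin
# depths (0.3 / 1.7 / 0 kJ/mol at 300 K)
script_schedule <- function(script) {
  n <- script$n_frames
  if (!is.null(script$basin_schedule)) return(script$basin_schedule)
  mk <- function(states, bounds) {
    tibble(state = states,
           start = c(1L, head(bounds, -1) + 1L),
           end = bounds)
  }
  if (script$mode == "turn_first") {
    t_on <- script$turn_onset_frame %||% (round(0.19 * n) + 1L)
    if (script$condition == "physiological") {
      hb <- script$hbond_onset_frames %||%
        (t_on - 1L + round(c(0.2483, 0.2483 + 0.1416, 0.2483 + 0.1416 + 0.28) /
                             0.81 * (n - t_on + 1L)))
      fmid <- as.integer(hb[2] + round((hb[3] - hb[2]) / 2))
      states <- c("helix", "U1", "U2", "F", "F2", "folded")
      bounds <- as.integer(c(t_on - 1L, hb[1] - 1L, hb[2] - 1L, fmid - 1L,
                             hb[3] - 1L, n))
    } else {
      # dwell fractions from the Boltzmann weight of the basin depths at
      # acidic pH (U1 1.8 kJ/mol above F at 300 K)
      hb <- script$hbond_onset_frames %||%
        (t_on - 1L + round(c(0.2464, 0.7531) * (n - t_on + 1L)))
      fmid <- as.integer(hb[1] + round((hb[2] - hb[1]) / 2))
      states <- c("helix", "U1", "F", "F2", "folded")
      bounds <- as.integer(c(t_on - 1L, hb[1] - 1L, fmid - 1L, hb[2] - 1L, n))
    }
    keep <- c(bounds[1] >= 1, diff(bounds) >= 1)
    mk(states[keep], bounds[keep])
  } else if (script$mode == "hbond_first") {
    hb_on <- script$hbond_onset_frames %||% round(0.30 * n)
    t_on <- script$turn_onset_frame %||% (round(0.60 * n) + 1L)
    mk(c("helix", "collapse", "folded"),
       as.integer(c(hb_on[1] - 1L, t_on - 1L, n)))
  } else {
    # each folding event starts from the folded hairpin (so the folded
    # structure dominates the ensemble and stays its most-clustered centre),
    # unfolds into the drawn basin and refolds through the F basin
    per <- n %/% script$n_events
    fold_len <- max(1L, round(0.35 * per))
    u_len <- max(1L, round(0.4 * per))
    rows <- list()
    pos <- 1L
    for (e in seq_len(script$n_events)) {
      last <- e == script$n_events
      endf <- if (last) script$n_frames else pos + per - 1L
      u_state <- script$path_states[e]
      rows[[3 * e - 2]] <- tibble(state = "folded", start = pos,
                                  end = pos + fold_len - 1L)
      rows[[3 * e - 1]] <- tibble(state = u_state, start = pos + fold_len,
                                  end = pos + fold_len + u_len - 1L)
      rows[[3 * e]] <- tibble(state = if (e %% 2) "F" else "F2",
                              start = pos + fold_len + u_len, end = endf)
      pos <- endf + 1L
    }
    bind_rows(rows)
  }
}

#' Generate a synthetic transition trajectory with ground truth
#'
#' Realizes a [mechanism_script()]: every frame is its scheduled state
#' template (with optional dihedral-space interpolation at switches) plus
#' truncated isotropic Gaussian coordinate noise. Ground-truth annotation
#' tracks (turn, each designated bond) and basin labels are returned
#' alongside; reproducible from the script seed.
#'
#' @param script A [mechanism_script()].
#' @param topology A [peptide_topology()]; defaults to alpha-syn12 at the
#'   script's pH condition.
#' @return A list with elements `trajectory` (a [trajectory()]), `truth`
#'   (list with `tracks` tibble of frame + turn + bond logicals, `basins`
#'   character vector, `states` character vector), `schedule` (tibble) and
#'   `script`.
#' @export
generate_trajectory <- function(script, topology = NULL) {
  stopifnot(inherits(script, "mechanism_script"))
  if (is.null(topology)) {
    topology <- peptide_topology("MDVFMKGLSKAK",
                                 protonation = script$condition)
  }
  set.seed(script$seed)
  if (script$mode == "two_path") {
    script$path_states <- ifelse(runif(script$n_events) < script$path_mixture[1],
                                 "U1", "U2")
  }
  ts <- template_set(script$condition, topology)
  sched <- script_schedule(script)
  if (max(sched$end) > script$n_frames) abort("schedule exceeds n_frames")
  bad <- setdiff(sched$state, names(ts$templates))
  if (length(bad)) abort(paste("unknown schedule state(s):", paste(bad, collapse = ", ")))
  n <- script$n_frames
  states <- character(n)
  for (i in seq_len(nrow(sched))) states[sched$start[i]:sched$end[i]] <- sched$state[i]
  natoms <- nrow(topology$atoms)
  coords <- array(0, c(n, natoms, 3))
  turn_truth <- logical(n)
  bond_truth <- matrix(FALSE, n, length(ts$registry),
                       dimnames = list(NULL, vapply(ts$registry, `[[`, "", "label")))
  for (st in unique(states)) {
    idx <- which(states == st)
    tpl <- ts$templates[[st]]
    coords[idx, , ] <- rep(tpl$frame, each = length(idx))
    turn_truth[idx] <- tpl$turn
    bond_truth[idx, ] <- rep(tpl$bonds, each = length(idx))
  }
  interp_frames <- integer(0)
  if (script$switch_frames > 0 && nrow(sched) > 1) {
    w <- script$switch_frames
    dih <- lapply(ts$templates, function(t) {
      d <- backbone_dihedrals(trajectory(topology, t$frame))
      list(phi = d$phi[1, ], psi = d$psi[1, ])
    })
    for (i in 2:nrow(sched)) {
      b <- sched$start[i]
      from <- sched$state[i - 1]; to <- sched$state[i]
      span <- b:min(b + w - 1L, n)
      for (k in seq_along(span)) {
        f <- k / (length(span) + 1)
        mix <- function(a, bb) {
          a <- ifelse(is.na(a), bb, a); bb <- ifelse(is.na(bb), a, bb)
          out <- a + f * (((bb - a + 180) %% 360) - 180)
          # terminal dihedrals (phi_1, psi_R) are not derivable from
          # coordinates; any value gives valid geometry there
          ifelse(is.na(out), 180, out)
        }
        fr <- frame_from_dihedrals(topology, mix(dih[[from]]$phi, dih[[to]]$phi),
                                   mix(dih[[from]]$psi, dih[[to]]$psi))
        coords[span[k], , ] <- fr
        trj1 <- trajectory(topology, fr)
        turn_truth[span[k]] <- turn_track(trj1, ts$turn)[[ts$turn$label]]
        bond_truth[span[k], ] <- vapply(ts$registry, function(d) {
          detect_hbond(fr, topology, d)
        }, logical(1))
      }
      interp_frames <- c(interp_frames, span)
    }
  }
  if (script$noise_sigma > 0) {
    s <- script$noise_sigma
    noise <- array(pmin(3 * s, pmax(-3 * s, rnorm(n * natoms * 3, 0, s))),
                   c(n, natoms, 3))
    coords <- coords + noise
  }
  basins <- ifelse(states %in% c("U1", "U2", "F", "F2"), states, "unassigned")
  basins[basins == "F2"] <- "F"   # both conformers belong to the F basin
  basins[interp_frames] <- "unassigned"
  tracks <- tibble(frame = seq_len(n))
  tracks[[ts$turn$label]] <- turn_truth
  for (j in seq_len(ncol(bond_truth))) tracks[[colnames(bond_truth)[j]]] <- bond_truth[, j]
  list(trajectory = trajectory(topology, coords,
                               source_label = paste0(script$mode, "/seed", script$seed)),
       truth = list(tracks = tracks, basins = basins, states = states),
       schedule = sched, script = script)
}
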