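# Internal vector geometry on nm-scale Cartesian coordinates.
# Frames are natoms x 3 matrices; many helpers also accept n x 3 matrices of
# per-frame points so distances/angles/dihedrals vectorize over frames.

cross3 <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, 1)
  if (is.null(dim(b))) b <- matrix(b, 1)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norm <- function(m) sqrt(rowSums(m^2))

unit_rows <- function(m) m / row_norm(m)

# Euclidean distance between paired rows
dist_rows <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, 1)
  if (is.null(dim(b))) b <- matrix(b, 1)
  sqrt(rowSums((a - b)^2))
}

# interior angle a-b-c in degrees, rowwise
angle_rows <- function(a, b, c) {
  if (is.null(dim(a))) { a <- matrix(a, 1); b <- matrix(b, 1); c <- matrix(c, 1) }
  v1 <- unit_rows(a - b)
  v2 <- unit_rows(c - b)
  acos(pmin(1, pmax(-1, rowSums(v1 * v2)))) * 180 / pi
}

# signed torsion p1-p2-p3-p4 in degrees (IUPAC convention), rowwise
dihedral_rows <- function(p1, p2, p3, p4) {
  if (is.null(dim(p1))) {
    p1 <- matrix(p1, 1); p2 <- matrix(p2, 1); p3 <- matrix(p3, 1); p4 <- matrix(p4, 1)
  }
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m <- cross3(n1, unit_rows(b2))
  atan2(rowSums(m * n2), rowSums(n1 * n2)) * 180 / pi
}

# Natural-extension reference frame: place atom D given A, B, C with bond
# length |C-D| = r, angle(B,C,D) = theta (deg) and torsion(A,B,C,D) = tau (deg).
nerf_place <- function(A, B, C, r, theta, tau) {
  th <- theta * pi / 180
  ta <- tau * pi / 180
  bc <- (C - B) / sqrt(sum((C - B)^2))
  n <- cross3(B - A, bc)[1, ]
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)[1, ]
  C + r * (-cos(th) * bc + sin(th) * cos(ta) * m - sin(th) * sin(ta) * n)
}

# Ideal backbone internal coordinates (nm / degrees)
backbone_ideal <- list(
  b_NCA = 0.1458, b_CAC = 0.1525, b_CN = 0.1329, b_CO = 0.1231, b_NH = 0.100,
  a_NCAC = 111.2, a_CACN = 116.2, a_CNCA = 121.7, a_CACO = 120.8, a_CNH = 119.5
)

# Build an R-residue backbone (N, H, CA, C, O; residue 1 without amide H) from
# phi/psi/omega dihedrals. Returns a list of per-residue coordinate lists.
build_backbone_atoms <- function(n_res, phi, psi, omega = rep(180, n_res)) {
  p <- backbone_ideal
  at <- vector("list", n_res)
  N <- c(0, 0, 0)
  CA <- c(p$b_NCA, 0, 0)
  C <- nerf_place(c(0, 1, 0), N, CA, p$b_CAC, p$a_NCAC, phi[1])
  H <- NULL
  for (i in seq_len(n_res)) {
    if (i > 1) {
      prev <- at[[i - 1]]
      N <- nerf_place(prev$N, prev$CA, prev$C, p$b_CN, p$a_CACN, psi[i - 1])
      CA <- nerf_place(prev$CA, prev$C, N, p$b_NCA, p$a_CNCA, omega[i])
      C <- nerf_place(prev$C, N, CA, p$b_CAC, p$a_NCAC, phi[i])
      # amide H in the peptide plane, anti to the preceding carbonyl O
      H <- nerf_place(prev$O, prev$C, N, p$b_NH, p$a_CNH, 180)
    }
    O <- nerf_place(N, CA, C, p$b_CO, p$a_CACO, psi[i] + 180)
    at[[i]] <- list(N = N, H = H, CA = CA, C = C, O = O)
  }
  at
}

# Flatten per-residue atom list into a frame matrix ordered as the topology
# atom table (N, [H], CA, C, O per residue).
backbone_to_frame <- function(at) {
  rows <- list()
  for (i in seq_along(at)) {
    a <- at[[i]]
    rows[[i]] <- do.call(rbind, a[!vapply(a, is.null, logical(1))])
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- NULL
  m
}

# Build a frame matrix for a topology directly from dihedrals.
frame_from_dihedrals <- function(topology, phi, psi, omega = rep(180, n_residues(topology))) {
  backbone_to_frame(build_backbone_atoms(n_residues(topology), phi, psi, omega))
}

# Reconstruct a missing amide H for residue i from the preceding peptide plane.
reconstruct_amide_h <- function(O_prev, C_prev, N) {
  p <- backbone_ideal
  nerf_place(O_prev, C_prev, N, p$b_NH, p$a_CNH, 180)
}

# phi/psi torsions for every residue of every frame.
# Returns list(phi = frames x R matrix, psi = frames x R matrix), NA at termini.
backbone_dihedrals <- function(trj) {
  topo <- trj$topology
  nres <- n_residues(topo)
  nf <- n_frames(trj)
  co <- trj$coords
  idx <- function(res, name) atom_index(topo, res, name)
  pick <- function(i) co[, i, , drop = FALSE][, 1, ]
  phi <- psi <- matrix(NA_real_, nf, nres)
  for (r in seq_len(nres)) {
    Nr <- pick(idx(r, "N")); CAr <- pick(idx(r, "CA")); Cr <- pick(idx(r, "C"))
    if (nf == 1) { Nr <- matrix(Nr, 1); CAr <- matrix(CAr, 1); Cr <- matrix(Cr, 1) }
    if (r > 1) {
      Cp <- pick(idx(r - 1, "C"))
      if (nf == 1) Cp <- matrix(Cp, 1)
      phi[, r] <- dihedral_rows(Cp, Nr, CAr, Cr)
    }
    if (r < nres) {
      Nn <- pick(idx(r + 1, "N"))
      if (nf == 1) Nn <- matrix(Nn, 1)
      psi[, r] <- dihedral_rows(Nr, CAr, Cr, Nn)
    }
  }
  list(phi = phi, psi = psi)
}
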