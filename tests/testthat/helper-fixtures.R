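# Shared fixtures. Template construction is cached package-side, so the first
# test file that touches a hairpin pays the optimization once per session.

topo_phys <- syn12_topology("physiological")
topo_acid <- syn12_topology("acidic")

helix_frame <- function(topo = topo_phys) make_ideal_helix(topo)

# random rigid transform of a frame
random_rigid <- function(frame, seed = 1) {
  set.seed(seed)
  th <- runif(3, -pi, pi)
  rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]), 0, sin(th[1]), cos(th[1])), 3, byrow = TRUE)
  ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0, -sin(th[2]), 0, cos(th[2])), 3, byrow = TRUE)
  rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0, 0, 0, 1), 3, byrow = TRUE)
  sweep(frame %*% (rx %*% ry %*% rz), 2, runif(3, -2, 2), `+`)
}

# a frame-stack trajectory from a list of frames
stack_frames <- function(topo, frames) {
  coords <- array(0, c(length(frames), nrow(frames[[1]]), 3))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  trajectory(topo, coords)
}

# independent naive hydrogen-bond evaluation used as an oracle
naive_hbond <- function(H, O, N, max_d = 0.25, min_ang = 135) {
  d <- sqrt(sum((H - O)^2))
  v1 <- (N - H) / sqrt(sum((N - H)^2))
  v2 <- (O - H) / sqrt(sum((O - H)^2))
  ang <- acos(min(1, max(-1, sum(v1 * v2)))) * 180 / pi
  d < max_d && ang > min_ang
}

# independent O(n^3)-style reference for the neighbour-count clustering:
# recomputes every neighbour count from the full matrix at every round
reference_daura <- function(mat, cutoff) {
  nf <- nrow(mat)
  remaining <- seq_len(nf)
  assignments <- integer(nf)
  centers <- integer(0)
  k <- 0L
  while (length(remaining) > 0) {
    best <- -1L
    center <- NA_integer_
    for (i in remaining) {
      cnt <- 0L
      for (j in remaining) if (mat[i, j] < cutoff) cnt <- cnt + 1L
      if (cnt > best) { best <- cnt; center <- i }   # first max = lowest index
    }
    members <- remaining[vapply(remaining, function(j) mat[center, j] < cutoff, logical(1))]
    k <- k + 1L
    assignments[members] <- k
    centers[k] <- center
    remaining <- setdiff(remaining, members)
  }
  sizes <- tabulate(assignments, k)
  ord <- order(-sizes, seq_len(k))
  relab <- integer(k)
  relab[ord] <- seq_len(k)
  list(assignments = relab[assignments], centers = centers[ord])
}
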