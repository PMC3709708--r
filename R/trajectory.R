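#' Construct a peptide trajectory
#'
#' Bundles a topology with an ordered set of Cartesian snapshots. Coordinates
#' are always in nanometres; times in nanoseconds, strictly increasing. When
#' no times are supplied frames are spaced uniformly at 0.05 ns (the 50 ps
#' sampling interval implied by 50,000 conformations over 2,500 ns).
#'
#' @param topology A [peptide_topology()] object.
#' @param coords Either a `frames x atoms x 3` array or a single `atoms x 3`
#'   matrix (one frame), in nm.
#' @param times Optional numeric vector of frame times (ns), strictly
#'   increasing.
#' @param source_label Free-text trajectory identifier.
#' @return An object of class `peptide_trajectory`.
#' @examples
#' topo <- syn12_topology()
#' trj <- trajectory(topo, make_ideal_helix(topo))
#' n_frames(trj)
#' @export
trajectory <- function(topology, coords, times = NULL, source_label = "") {
  stopifnot(inherits(topology, "peptide_topology"))
  if (is.matrix(coords)) coords <- array(coords, c(1, nrow(coords), 3))
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    abort("coords must be a frames x atoms x 3 array")
  }
  if (dim(coords)[2] != nrow(topology$atoms)) {
    abort(sprintf("coords have %d atoms but topology has %d",
                  dim(coords)[2], nrow(topology$atoms)))
  }
  if (anyNA(coords)) abort("coords contain NA values")
  nf <- dim(coords)[1]
  if (is.null(times)) times <- seq_len(nf) * 0.05
  if (length(times) != nf) abort("times length must equal frame count")
  if (nf > 1 && any(diff(times) <= 0)) abort("times must be strictly increasing")
  structure(list(topology = topology, coords = coords, times = as.numeric(times),
                 source_label = source_label),
            class = "peptide_trajectory")
}

#' Number of frames in a trajectory
#' @param trj A [trajectory()] object.
#' @return Integer frame count.
#' @export
n_frames <- function(trj) dim(trj$coords)[1]

#' Extract one frame as an atoms x 3 matrix
#' @param trj A [trajectory()] object.
#' @param i Frame index (1-based).
#' @return An `atoms x 3` coordinate matrix (nm).
#' @export
get_frame <- function(trj, i) {
  if (i < 1 || i > n_frames(trj)) abort(sprintf("frame %d out of range", i))
  matrix(trj$coords[i, , ], ncol = 3)
}

#' @export
print.peptide_trajectory <- function(x, ...) {
  cat("<peptide_trajectory> ", n_frames(x), " frames x ", dim(x$coords)[2],
      " atoms (", x$topology$sequence, ")",
      if (nzchar(x$source_label)) paste0(" [", x$source_label, "]"), "\n",
      sep = "")
  invisible(x)
}

#' @export
as_tibble.peptide_trajectory <- function(x, ...) {
  nf <- n_frames(x)
  na <- dim(x$coords)[2]
  tibble(frame = rep(seq_len(nf), each = na),
         time = rep(x$times, each = na),
         atom = rep(seq_len(na), nf),
         resno = rep(x$topology$atoms$resno, nf),
         name = rep(x$topology$atoms$name, nf),
         x = as.vector(t(x$coords[, , 1, drop = FALSE][, , 1])),
         y = as.vector(t(x$coords[, , 2, drop = FALSE][, , 1])),
         z = as.vector(t(x$coords[, , 3, drop = FALSE][, , 1])))
}

# subset frames, keeping times
subset_frames <- function(trj, idx) {
  trajectory(trj$topology, trj$coords[idx, , , drop = FALSE], trj$times[idx],
             trj$source_label)
}
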