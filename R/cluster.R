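#' RMSD-cutoff conformational clustering (Daura / GROMOS algorithm)
#'
#' Neighbour-count clustering of conformations on a mutual RMSD matrix: the
#' frame with the most neighbours within the cutoff (strictly below) becomes
#' a cluster centre, it and its neighbours are removed, and the procedure
#' repeats until no frames remain. Ties on neighbour count are broken by the
#' lowest frame index. Cluster 1 is the largest ("most clustered") cluster;
#' its centre is the most-clustered structure of the ensemble.
#'
#' @param mat Symmetric pairwise RMSD matrix (nm) with zero diagonal, e.g.
#'   from [pairwise_rmsd()].
#' @param cutoff RMSD cutoff in nm (default 0.1).
#' @return An object of class `daura_clusters`: list with `assignments`
#'   (per-frame cluster id, 1 = largest), `centers` (frame index per
#'   cluster), `populations` (fractions summing to 1), `sizes`, `cutoff`.
#' @export
cluster_daura <- function(mat, cutoff = 0.1) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat)) abort("mat must be square")
  if (max(abs(mat - t(mat))) > 1e-9) abort("mat must be symmetric")
  nf <- nrow(mat)
  adj <- mat < cutoff      # strict; includes the diagonal (self)
  remaining <- rep(TRUE, nf)
  assignments <- integer(nf)
  centers <- integer(0)
  k <- 0L
  while (any(remaining)) {
    idx <- which(remaining)
    counts <- rowSums(adj[idx, idx, drop = FALSE])
    center <- idx[which.max(counts)]      # which.max takes lowest index on ties
    members <- idx[adj[center, idx]]
    k <- k + 1L
    assignments[members] <- k
    centers[k] <- center
    remaining[members] <- FALSE
  }
  # relabel so cluster 1 is the largest (ties: earlier-found first)
  sizes <- tabulate(assignments, k)
  ord <- order(-sizes, seq_len(k))
  relab <- integer(k)
  relab[ord] <- seq_len(k)
  assignments <- relab[assignments]
  centers <- centers[ord]
  sizes <- sizes[ord]
  structure(list(assignments = assignments, centers = centers,
                 sizes = sizes, populations = sizes / nf, cutoff = cutoff),
            class = "daura_clusters")
}

#' @export
print.daura_clusters <- function(x, ...) {
  cat(sprintf("<daura_clusters> %d frames, %d clusters at cutoff %.3g nm; top population %.3f\n",
              length(x$assignments), length(x$centers), x$cutoff, x$populations[1]))
  invisible(x)
}

#' @rdname cluster_daura
#' @param x A `daura_clusters` object.
#' @param ... Unused.
#' @export
tidy.daura_clusters <- function(x, ...) {
  tibble(cluster = seq_along(x$centers), size = x$sizes,
         population = x$populations, center_frame = x$centers)
}

#' @rdname cluster_daura
#' @export
glance.daura_clusters <- function(x, ...) {
  tibble(n_frames = length(x$assignments), n_clusters = length(x$centers),
         top_population = x$populations[1], cutoff = x$cutoff)
}

#' Representative (centre) structure of a cluster
#'
#' @param trj The [trajectory()] the clustering was computed on (same frame
#'   order as the RMSD matrix).
#' @param clusters A [cluster_daura()] result.
#' @param cluster_id Cluster number (1 = most clustered).
#' @return The `atoms x 3` coordinate matrix of the cluster centre frame.
#' @export
representative_structure <- function(trj, clusters, cluster_id = 1) {
  if (cluster_id < 1 || cluster_id > length(clusters$centers)) {
    abort(sprintf("unknown cluster id %s", cluster_id))
  }
  get_frame(trj, clusters$centers[cluster_id])
}
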