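#' Optimal rigid-body superposition of two frames
#'
#' Least-squares superposition of a mobile frame onto a reference over a
#' common atom selection, with the RMSD of the selected atoms after fitting.
#' Two independent algorithms are provided: the Kabsch solution via singular
#' value decomposition (default) and the Horn quaternion eigenvector method.
#' Both enforce a proper rotation (no reflection; the SVD route corrects the
#' determinant sign, the quaternion route is proper by construction).
#'
#' @param mobile,reference `atoms x 3` coordinate matrices (nm).
#' @param selection Integer atom indices used for the fit and the RMSD;
#'   identical interpretation in both frames. At least 3 non-collinear atoms.
#' @param method `"svd"` (Kabsch) or `"quaternion"` (Horn).
#' @return A list of class `superposition`: `rmsd` (nm), `rotation` (3x3,
#'   applied on the right of centred mobile coordinates), `translation`
#'   (3-vector; centre of the reference selection), `selection`, `method`.
#'   `fitted(x)`-style transformed coordinates can be obtained with
#'   [apply_superposition()].
#' @examples
#' topo <- syn12_topology()
#' f <- make_ideal_helix(topo)
#' superpose(f, f)$rmsd
#' @export
superpose <- function(mobile, reference, selection = NULL,
                      method = c("svd", "quaternion")) {
  method <- match.arg(method)
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  if (length(selection) < 3) abort("selection needs at least 3 atoms")
  x <- mobile[selection, , drop = FALSE]
  y <- reference[selection, , drop = FALSE]
  if (nrow(x) != nrow(y)) abort("selection length differs between frames")
  cx <- colMeans(x)
  cy <- colMeans(y)
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  # collinearity check on either point set
  if (qr(xc)$rank < 2 || qr(yc)$rank < 2) {
    abort("degenerate geometry: selection is collinear")
  }
  n <- nrow(x)
  if (method == "svd") {
    cm <- crossprod(xc, yc)           # 3x3 covariance
    s <- svd(cm)
    d <- sign(det(s$u %*% t(s$v)))
    rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  } else {
    cm <- crossprod(xc, yc)
    k <- horn_key_matrix(cm)
    eig <- eigen(k, symmetric = TRUE)
    q <- eig$vectors[, 1]
    # Horn's quaternion acts on column vectors; transpose for row convention
    rot <- t(quaternion_to_rotation(q))
  }
  # explicit residual: no catastrophic cancellation for near-identical frames
  rmsd <- sqrt(sum((xc %*% rot - yc)^2) / n)
  structure(list(rmsd = rmsd, rotation = rot, translation = cy,
                 center_mobile = cx, selection = selection, method = method),
            class = "superposition")
}

# Horn's 4x4 key matrix from the 3x3 covariance of centred coordinate sets
horn_key_matrix <- function(s) {
  matrix(c(
    s[1,1]+s[2,2]+s[3,3], s[2,3]-s[3,2],        s[3,1]-s[1,3],        s[1,2]-s[2,1],
    s[2,3]-s[3,2],        s[1,1]-s[2,2]-s[3,3], s[1,2]+s[2,1],        s[3,1]+s[1,3],
    s[3,1]-s[1,3],        s[1,2]+s[2,1],        -s[1,1]+s[2,2]-s[3,3], s[2,3]+s[3,2],
    s[1,2]-s[2,1],        s[3,1]+s[1,3],        s[2,3]+s[3,2],        -s[1,1]-s[2,2]+s[3,3]
  ), 4, 4, byrow = TRUE)
}

quaternion_to_rotation <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w*w+x*x-y*y-z*z, 2*(x*y-w*z),     2*(x*z+w*y),
    2*(x*y+w*z),     w*w-x*x+y*y-z*z, 2*(y*z-w*x),
    2*(x*z-w*y),     2*(y*z+w*x),     w*w-x*x-y*y+z*z
  ), 3, 3, byrow = TRUE)
}

#' Apply a fitted superposition to a full frame
#'
#' @param frame `atoms x 3` matrix to transform (typically the mobile frame
#'   the fit was computed from).
#' @param fit A [superpose()] result.
#' @return The transformed `atoms x 3` matrix.
#' @export
apply_superposition <- function(frame, fit) {
  sweep(sweep(frame, 2, fit$center_mobile) %*% fit$rotation, 2, fit$translation, `+`)
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.6f nm over %d atoms (%s)\n",
              x$rmsd, length(x$selection), x$method))
  invisible(x)
}

# fast scalar Kabsch RMSD on pre-centred matrices with precomputed E0
kabsch_rmsd_centred <- function(xc, yc, e0, n) {
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$u %*% t(s$v)))
  sv <- s$d
  sv[3] <- sv[3] * d
  sqrt(max(0, (e0 - 2 * sum(sv)) / n))
}

# centre the selected atoms of every frame once; returns list(mats, ssq)
centred_selection <- function(trj, selection) {
  nf <- n_frames(trj)
  mats <- vector("list", nf)
  ssq <- numeric(nf)
  for (i in seq_len(nf)) {
    m <- matrix(trj$coords[i, selection, ], ncol = 3)
    m <- sweep(m, 2, colMeans(m))
    mats[[i]] <- m
    ssq[i] <- sum(m^2)
  }
  list(mats = mats, ssq = ssq)
}

#' Per-frame RMSD against a reference structure
#'
#' The standard RMSDCa time series: every frame of a trajectory is
#' optimally superposed onto a fixed reference and the Calpha RMSD recorded.
#'
#' @param trj A [trajectory()] object.
#' @param reference An `atoms x 3` reference frame (same topology).
#' @param selection Atom indices; defaults to all Calpha atoms.
#' @return A tibble with columns `frame`, `time` (ns) and `rmsd` (nm).
#' @export
rmsd_series <- function(trj, reference, selection = NULL) {
  if (is.null(selection)) selection <- ca_indices(trj$topology)
  cs <- centred_selection(trj, selection)
  yr <- reference[selection, , drop = FALSE]
  yc <- sweep(yr, 2, colMeans(yr))
  ey <- sum(yc^2)
  nsel <- length(selection)
  r <- vapply(seq_along(cs$mats), function(i) {
    kabsch_rmsd_centred(cs$mats[[i]], yc, cs$ssq[i] + ey, nsel)
  }, numeric(1))
  tibble(frame = seq_len(n_frames(trj)), time = trj$times, rmsd = r)
}

#' Mutual RMSD matrix over all frame pairs
#'
#' Symmetric matrix of pairwise Calpha RMSD values after optimal
#' superposition, the input to RMSD-cutoff clustering.
#'
#' @inheritParams rmsd_series
#' @return A symmetric `frames x frames` matrix (nm) with zero diagonal.
#' @export
pairwise_rmsd <- function(trj, selection = NULL) {
  if (is.null(selection)) selection <- ca_indices(trj$topology)
  cs <- centred_selection(trj, selection)
  nf <- n_frames(trj)
  nsel <- length(selection)
  m <- matrix(0, nf, nf)
  if (nf > 1) {
    for (i in seq_len(nf - 1)) {
      xi <- cs$mats[[i]]
      for (j in (i + 1):nf) {
        r <- kabsch_rmsd_centred(xi, cs$mats[[j]], cs$ssq[i] + cs$ssq[j], nsel)
        m[i, j] <- r
        m[j, i] <- r
      }
    }
  }
  m
}
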