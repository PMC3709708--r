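GAS_CONSTANT_KJ <- 0.0083145  # kJ mol^-1 K^-1

#' Encode the discrete turn/hydrogen-bond reaction coordinate
#'
#' The Y-axis coding of the free-energy surface: code -1 when the designated
#' turn is absent; code k in 0..n when the turn is present and exactly k of
#' the n designated hydrogen bonds are formed. Only the designated bond set
#' enters the count; other hydrogen bonds are ignored.
#'
#' @param turn_track A tibble from [turn_track()] (frame + one logical
#'   column).
#' @param hbond_tracks A tibble from [hbond_tracks()] over the designated
#'   ordered bond set.
#' @param rmsd A numeric vector of per-frame RMSD values (nm) against the
#'   most-clustered structure, or a tibble from [rmsd_series()].
#' @return A tibble (`state_series`) with columns `frame`, `rmsd`, `ycode`.
#' @export
encode_states <- function(turn_track, hbond_tracks, rmsd) {
  if (is.data.frame(rmsd)) rmsd <- rmsd$rmsd
  tv <- turn_track[[setdiff(names(turn_track), "frame")[1]]]
  hb <- as.matrix(hbond_tracks[setdiff(names(hbond_tracks), "frame")])
  if (length(tv) != nrow(hb) || length(tv) != length(rmsd)) {
    abort("turn, hbond and rmsd tracks must cover the same frames")
  }
  ycode <- ifelse(tv, rowSums(hb), -1L)
  tibble(frame = seq_along(tv), rmsd = rmsd, ycode = as.integer(ycode))
}

#' Two-dimensional free-energy surface over (RMSD, y-code)
#'
#' Normalized 2D histogram of the state series converted to free energies
#' F = -kT ln P, shifted so the global sampled minimum is zero. The X axis is
#' binned RMSD; the Y axis is the discrete code, one level per integer
#' (no binning). Unsampled bins are reported as `NA`, not infinity.
#'
#' @param states A tibble from [encode_states()].
#' @param x_bin_width RMSD bin width in nm (default 0.01).
#' @param temperature Temperature in K (default 300).
#' @param y_levels Integer codes to include; defaults to the full observed
#'   range `-1..max(ycode)`.
#' @return An object of class `fes`: list with `grid` (tibble `x_center`,
#'   `y_level`, `count`, `F`), `x_edges`, `y_levels`, `kT`, `temperature`,
#'   `n_frames`.
#' @export
build_fes <- function(states, x_bin_width = 0.01, temperature = 300,
                      y_levels = NULL) {
  if (nrow(states) == 0) abort("state series has zero frames")
  if (x_bin_width <= 0) abort("x_bin_width must be positive")
  kT <- GAS_CONSTANT_KJ * temperature
  x_max <- max(states$rmsd)
  edges <- seq(0, x_max + x_bin_width, by = x_bin_width)
  if (is.null(y_levels)) y_levels <- seq(min(-1L, min(states$ycode)), max(states$ycode))
  xb <- findInterval(states$rmsd, edges, rightmost.closed = FALSE)
  xb[xb > length(edges) - 1] <- length(edges) - 1
  yb <- match(states$ycode, y_levels)
  if (anyNA(yb)) abort("ycode outside supplied y_levels")
  counts <- matrix(0, length(edges) - 1, length(y_levels))
  for (i in seq_along(xb)) counts[xb[i], yb[i]] <- counts[xb[i], yb[i]] + 1
  P <- counts / sum(counts)
  Fm <- ifelse(counts > 0, -kT * log(P), NA_real_)
  Fm <- Fm - min(Fm, na.rm = TRUE)
  grid <- tibble(
    x_center = rep(edges[-length(edges)] + x_bin_width / 2, times = length(y_levels)),
    y_level = rep(y_levels, each = nrow(counts)),
    count = as.vector(counts),
    F = as.vector(Fm))
  structure(list(grid = grid, x_edges = edges, y_levels = y_levels, kT = kT,
                 temperature = temperature, n_frames = nrow(states)),
            class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  cat(sprintf("<fes> %d x-bins x %d y-levels, %d frames, kT = %.4f kJ/mol\n",
              length(x$x_edges) - 1, length(x$y_levels), x$n_frames, x$kT))
  invisible(x)
}

#' @rdname build_fes
#' @param x An `fes` object.
#' @param ... Unused.
#' @export
tidy.fes <- function(x, ...) x$grid

#' @rdname build_fes
#' @export
glance.fes <- function(x, ...) {
  sampled <- !is.na(x$grid$F)
  tibble(n_frames = x$n_frames, n_sampled_bins = sum(sampled),
         kT = x$kT, temperature = x$temperature,
         f_max = max(x$grid$F, na.rm = TRUE))
}

#' Local minima of a free-energy surface
#'
#' A sampled bin is a local minimum when its free energy is strictly lower
#' than that of every sampled 8-neighbour on the (x-bin, y-level) lattice.
#' Bins on a plateau (equal neighbours) are not minima under the strict
#' inequality. Depths are relative to the global minimum (which has depth 0).
#'
#' @param fes An [build_fes()] result.
#' @return A tibble with columns `x_center`, `y_level`, `depth`
#'   (kJ mol^-1), sorted by depth.
#' @export
find_minima <- function(fes) {
  nx <- length(fes$x_edges) - 1
  ny <- length(fes$y_levels)
  Fm <- matrix(fes$grid$F, nx, ny)
  mins <- list()
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      f0 <- Fm[i, j]
      if (is.na(f0)) next
      is_min <- TRUE
      for (di in -1:1) {
        for (dj in -1:1) {
          if (di == 0 && dj == 0) next
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > nx || jj < 1 || jj > ny) next
          fn <- Fm[ii, jj]
          if (!is.na(fn) && fn <= f0) { is_min <- FALSE; break }
        }
        if (!is_min) break
      }
      if (is_min) {
        mins[[length(mins) + 1]] <- tibble(
          x_center = fes$x_edges[i] + diff(fes$x_edges[1:2]) / 2,
          y_level = fes$y_levels[j], depth = f0)
      }
    }
  }
  if (length(mins) == 0) {
    return(tibble(x_center = numeric(), y_level = integer(), depth = numeric()))
  }
  arrange(bind_rows(mins), .data$depth)
}

#' Basin regions in (RMSD, y-code) space
#'
#' Rectangular regions at an exact y level used to label frames with basin
#' names. Regions must be pairwise disjoint.
#'
#' @param basin Character vector of basin names.
#' @param x_min,x_max Numeric RMSD bounds (nm), inclusive.
#' @param y Integer y-code of each region.
#' @return A tibble of class `basin_regions`.
#' @export
basin_regions <- function(basin, x_min, x_max, y) {
  reg <- tibble(basin = basin, x_min = x_min, x_max = x_max, y = as.integer(y))
  if (any(reg$x_min >= reg$x_max)) abort("x_min must be below x_max")
  if (nrow(reg) > 1) {
    for (i in seq_len(nrow(reg) - 1)) {
      for (j in (i + 1):nrow(reg)) {
        if (reg$y[i] == reg$y[j] &&
            reg$x_min[i] < reg$x_max[j] && reg$x_min[j] < reg$x_max[i]) {
          abort(sprintf("overlapping basin regions: %s and %s",
                        reg$basin[i], reg$basin[j]))
        }
      }
    }
  }
  class(reg) <- c("basin_regions", class(reg))
  reg
}

#' Default basin regions for a pH condition
#'
#' Rectangles of +/- `half_width` nm around the free-energy minima at their
#' exact y level: at physiological pH U1 (0.23 nm, 0), U2 (0.38 nm, 2) and
#' F (0.08 nm, 3); at acidic pH U1 (0.27 nm, 0) and F (0.08 nm, 4).
#'
#' @param condition `"physiological"` or `"acidic"`.
#' @param half_width Half-width of the rectangles in nm (default 0.05).
#' @return A [basin_regions()] tibble.
#' @export
default_basin_regions <- function(condition = c("physiological", "acidic"),
                                  half_width = 0.05) {
  condition <- match.arg(condition)
  if (condition == "physiological") {
    centers <- tibble(basin = c("U1", "U2", "F"), x = c(0.23, 0.38, 0.08),
                      y = c(0L, 2L, 3L))
  } else {
    centers <- tibble(basin = c("U1", "F"), x = c(0.27, 0.08), y = c(0L, 4L))
  }
  basin_regions(centers$basin, centers$x - half_width, centers$x + half_width,
                centers$y)
}

#' Regions centred on detected free-energy minima
#'
#' @param minima A [find_minima()] tibble.
#' @param half_width Half-width in nm.
#' @param names Optional basin names; defaults to `B1`, `B2`, ...
#' @return A [basin_regions()] tibble.
#' @export
regions_from_minima <- function(minima, half_width = 0.05, names = NULL) {
  if (is.null(names)) names <- paste0("B", seq_len(nrow(minima)))
  basin_regions(names, minima$x_center - half_width,
                minima$x_center + half_width, minima$y_level)
}

#' Label frames with basin membership
#'
#' @param states A tibble from [encode_states()].
#' @param regions A [basin_regions()] tibble.
#' @return The `states` tibble with an added character column `basin`
#'   (`"unassigned"` outside every region).
#' @export
label_basins <- function(states, regions) {
  if (!inherits(regions, "basin_regions")) {
    regions <- basin_regions(regions$basin, regions$x_min, regions$x_max, regions$y)
  }
  lab <- rep("unassigned", nrow(states))
  for (i in seq_len(nrow(regions))) {
    hit <- states$ycode == regions$y[i] &
      states$rmsd >= regions$x_min[i] & states$rmsd <= regions$x_max[i]
    lab[hit] <- regions$basin[i]
  }
  mutate(states, basin = lab)
}
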