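mk_turn_track <- function(v) tibble::tibble(frame = seq_along(v), `Turn_9-6` = v)
mk_hb_tracks <- function(m) {
  out <- tibble::tibble(frame = seq_len(nrow(m)))
  for (j in seq_len(ncol(m))) out[[paste0("HB_", j)]] <- m[, j]
  out
}

test_that("state encoding matches the exhaustive 2^5 truth table", {
  combos <- expand.grid(turn = c(FALSE, TRUE), b1 = c(FALSE, TRUE),
                        b2 = c(FALSE, TRUE), b3 = c(FALSE, TRUE),
                        b4 = c(FALSE, TRUE))
  st <- encode_states(mk_turn_track(combos$turn),
                      mk_hb_tracks(as.matrix(combos[, 2:5])),
                      rep(0.1, nrow(combos)))
  want <- ifelse(!combos$turn, -1L,
                 combos$b1 + combos$b2 + combos$b3 + combos$b4)
  expect_identical(st$ycode, as.integer(want))
  # no turn -> -1 regardless of bonds; turn with no bonds -> 0; all four -> 4
  expect_equal(unique(st$ycode[!combos$turn]), -1L)
  expect_equal(st$ycode[combos$turn & !combos$b1 & !combos$b2 & !combos$b3 & !combos$b4], 0L)
  expect_equal(st$ycode[combos$turn & combos$b1 & combos$b2 & combos$b3 & combos$b4], 4L)
  expect_error(encode_states(mk_turn_track(c(TRUE, FALSE)),
                             mk_hb_tracks(matrix(TRUE, 3, 2)), rep(0, 3)),
               "same frames")
})

test_that("encoding counts only the designated bond set", {
  set.seed(1)
  turn <- rep(TRUE, 20)
  des <- matrix(runif(40) > 0.5, 20, 2)
  extra <- matrix(TRUE, 20, 3)  # other bonds, must be ignored
  st <- encode_states(mk_turn_track(turn), mk_hb_tracks(des), rep(0, 20))
  expect_equal(st$ycode, as.integer(rowSums(des)))
  expect_true(all(st$ycode <= 2))
})

test_that("free-energy surface closed forms hold", {
  kT <- 0.0083145 * 300
  # two bins with counts in ratio e:1 -> dF = kT = 2.494 kJ/mol
  n2 <- 1000
  n1 <- round(exp(1) * n2)
  st <- tibble::tibble(frame = 1, rmsd = c(rep(0.105, n1), rep(0.205, n2)),
                       ycode = 0L)
  st$frame <- seq_len(nrow(st))
  fes <- build_fes(st, x_bin_width = 0.01, temperature = 300)
  f <- fes$grid$F[!is.na(fes$grid$F)]
  expect_equal(sort(f), c(0, -kT * log(n2 / n1)), tolerance = 1e-3)
  expect_equal(max(f), 2.494, tolerance = 1e-3)
  expect_equal(fes$kT, kT)
  # uniform occupancy over 4 bins -> flat F = 0
  stu <- tibble::tibble(frame = 1:400,
                        rmsd = rep(c(0.005, 0.015, 0.025, 0.035), 100),
                        ycode = 0L)
  fu <- build_fes(stu)
  expect_equal(fu$grid$F[!is.na(fu$grid$F)], rep(0, 4))
  # single sampled bin: F = 0 there, all others unsampled
  s1 <- tibble::tibble(frame = 1:10, rmsd = 0.055, ycode = 2L)
  f1 <- build_fes(s1)
  expect_equal(sum(!is.na(f1$grid$F)), 1)
  expect_equal(f1$grid$F[!is.na(f1$grid$F)], 0)
  expect_error(build_fes(s1[0, ]), "zero frames")
  expect_error(build_fes(s1, x_bin_width = 0), "positive")
})

test_that("adding a constant count to every bin only shifts F uniformly", {
  set.seed(6)
  counts <- matrix(rpois(12, 40) + 1, 4, 3)
  mk_states <- function(cnt) {
    rows <- list()
    for (i in 1:4) for (j in 1:3) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        rmsd = rep(0.005 + (i - 1) * 0.01, cnt[i, j]), ycode = j - 2L)
    }
    st <- dplyr::bind_rows(rows)
    st$frame <- seq_len(nrow(st))
    st
  }
  f0 <- build_fes(mk_states(counts))
  f1 <- build_fes(mk_states(counts + 25))
  # after the min-shift both surfaces differ by bin, but re-shifting to a
  # common reference bin makes the pattern comparable: differences of F are
  # reproduced up to the monotone count transform, and sampled-bin sets match
  expect_equal(is.na(f0$grid$F), is.na(f1$grid$F))
  expect_equal(order(f0$grid$F), order(f1$grid$F))
})

test_that("minima finder matches a vectorized shift-based oracle on random grids", {
  oracle_minima <- function(Fm) {
    nx <- nrow(Fm); ny <- ncol(Fm)
    pad <- matrix(Inf, nx + 2, ny + 2)
    pad[2:(nx + 1), 2:(ny + 1)] <- ifelse(is.na(Fm), Inf, Fm)
    hits <- matrix(TRUE, nx, ny)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb <- pad[2:(nx + 1) + di, 2:(ny + 1) + dj]
      hits <- hits & (ifelse(is.na(Fm), Inf, Fm) < nb)
    }
    hits & !is.na(Fm)
  }
  set.seed(33)
  for (rep in 1:10) {
    nx <- sample(5:15, 1); ny <- sample(3:6, 1)
    cnt <- matrix(rpois(nx * ny, 3), nx, ny)
    rows <- list()
    for (i in seq_len(nx)) for (j in seq_len(ny)) {
      if (cnt[i, j] > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          rmsd = rep(0.005 + (i - 1) * 0.01, cnt[i, j]), ycode = as.integer(j - 2))
      }
    }
    st <- dplyr::bind_rows(rows)
    st$frame <- seq_len(nrow(st))
    fes <- build_fes(st, y_levels = seq(-1, ny - 2))
    mins <- find_minima(fes)
    nx_eff <- length(fes$x_edges) - 1
    Fm <- matrix(fes$grid$F, nx_eff, length(fes$y_levels))
    want <- which(oracle_minima(Fm), arr.ind = TRUE)
    got <- cbind(round((mins$x_center - 0.005) / 0.01) + 1,
                 match(mins$y_level, fes$y_levels))
    expect_equal(nrow(mins), nrow(want))
    expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))
    expect_true(all(diff(mins$depth) >= 0))
  }
})

test_that("a constructed two-well surface yields both wells and no plateau minima", {
  mk <- function(cnt_by_bin) {
    rows <- list()
    for (i in seq_along(cnt_by_bin)) {
      if (cnt_by_bin[i] > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          rmsd = rep(0.005 + (i - 1) * 0.01, cnt_by_bin[i]), ycode = 0L)
      }
    }
    st <- dplyr::bind_rows(rows)
    st$frame <- seq_len(nrow(st))
    st
  }
  # counts: well, barrier, well (1D row at a single y level)
  fes <- build_fes(mk(c(100, 20, 5, 30, 80)))
  mins <- find_minima(fes)
  expect_equal(nrow(mins), 2)
  expect_equal(mins$depth[1], 0)
  # plateau: two equal adjacent bins are not minima
  fplat <- build_fes(mk(c(50, 50, 10)))
  expect_equal(nrow(find_minima(fplat)), 0)
})

test_that("basin labelling assigns rectangles and validates overlap", {
  st <- tibble::tibble(frame = 1:4,
                       rmsd = c(0.08, 0.23, 0.38, 0.60),
                       ycode = c(3L, 0L, 2L, -1L))
  lb <- label_basins(st, default_basin_regions("physiological"))
  expect_equal(lb$basin, c("F", "U1", "U2", "unassigned"))
  expect_error(basin_regions(c("A", "B"), c(0, 0.05), c(0.1, 0.15), c(0L, 0L)),
               "overlapping")
  # same x range at different y levels is fine
  ok <- basin_regions(c("A", "B"), c(0, 0), c(0.1, 0.1), c(0L, 1L))
  expect_equal(nrow(ok), 2)
})

test_that("labels recover the generator's programmed basin schedule", {
  topo <- topo_phys
  g <- generate_trajectory(mechanism_script("two_path", n_frames = 2000,
                                            n_events = 10, seed = 17), topo)
  defs <- condition_defaults("physiological")
  hb <- hbond_tracks(g$trajectory, defs$hbonds)
  tt <- turn_track(g$trajectory, defs$turn)
  rs <- rmsd_series(g$trajectory, make_ideal_hairpin(topo))
  st <- encode_states(tt, hb, rs)
  lb <- label_basins(st, default_basin_regions("physiological"))
  expect_gt(mean(lb$basin == g$truth$basins), 0.95)
})
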