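#' Occurrence probabilities of boolean annotation tracks
#'
#' Mean of each boolean track over frames, per trajectory when a
#' `trajectory` column is present (with a pooled row) and pooled otherwise.
#' This is the headline summary of turn and hydrogen-bond formation
#' probabilities per simulation.
#'
#' @param tracks A tibble with a `frame` column, logical track columns and
#'   optionally a `trajectory` column.
#' @return A tibble with columns `trajectory` (`"pooled"` when absent),
#'   `label`, `probability`, `n_frames`.
#' @export
occurrence_table <- function(tracks) {
  if (nrow(tracks) == 0) abort("empty frame set")
  labs <- setdiff(names(tracks), c("frame", "trajectory"))
  one <- function(df, id) {
    tibble(trajectory = id, label = labs,
           probability = unname(vapply(labs, function(l) mean(df[[l]]), numeric(1))),
           n_frames = nrow(df))
  }
  if ("trajectory" %in% names(tracks)) {
    per <- bind_rows(lapply(split(tracks, tracks$trajectory),
                            function(df) one(df, as.character(df$trajectory[1]))))
    bind_rows(per, one(tracks, "pooled"))
  } else {
    one(tracks, "pooled")
  }
}

#' Conditional hydrogen-bond probability given the turn is absent
#'
#' For every (turn, bond) pair, the fraction of turn-absent frames in which
#' the bond is formed: P(HB | no turn). A vanishing conditional for the
#' driving turn is the signature of turn-first (zipper) folding — the bonds
#' are never observed without the turn. Pairs with no conditioning frames
#' (turn always present) are flagged undefined rather than reported as 0.
#'
#' @param turn_tracks Tibble with `frame` plus one or more logical turn
#'   columns.
#' @param hbond_tracks Tibble with `frame` plus logical bond columns,
#'   aligned to the same frames.
#' @return A tibble with columns `turn`, `hbond`, `probability` (`NA` when
#'   undefined), `n_conditioning_frames`, `defined`.
#' @export
conditional_hbond_given_no_turn <- function(turn_tracks, hbond_tracks) {
  tlabs <- setdiff(names(turn_tracks), c("frame", "trajectory"))
  hlabs <- setdiff(names(hbond_tracks), c("frame", "trajectory"))
  if (nrow(turn_tracks) != nrow(hbond_tracks)) {
    abort("turn and hbond tracks must cover the same frames")
  }
  rows <- list()
  for (tl in tlabs) {
    off <- !turn_tracks[[tl]]
    n0 <- sum(off)
    for (hl in hlabs) {
      p <- if (n0 > 0) mean(hbond_tracks[[hl]][off]) else NA_real_
      rows[[length(rows) + 1]] <- tibble(
        turn = tl, hbond = hl, probability = p,
        n_conditioning_frames = n0, defined = n0 > 0)
    }
  }
  bind_rows(rows)
}

#' Default transition-path catalog
#'
#' The six candidate routes between the unfolded basins U1/U2 and the folded
#' basin F considered at physiological pH: direct folding from either basin,
#' folding via the other basin, and basin interconversion without folding.
#'
#' @return A character vector of path strings (basins separated by `">"`).
#' @export
default_path_catalog <- function() {
  c("U1>F", "U2>F", "U1>U2>F", "U2>U1>F", "U1>U2", "U2>U1")
}

#' Enumerate transition-path events from basin labels
#'
#' The per-frame basin label series is compressed to its sequence of visited
#' basins (unassigned frames and consecutive repeats dropped). Each maximal
#' segment that starts at an unfolded basin and ends at the folded label is
#' one folding event; a trailing segment that visits more than one unfolded
#' basin without reaching the folded label is a non-folding interconversion
#' event. Events are matched against the catalog; unmatched sequences are
#' counted under `"other"`. Probabilities are counts normalized over all
#' observed events. With `first_passage_only = TRUE` only the first folding
#' event is counted.
#'
#' @param labels Character vector of per-frame basin labels (from
#'   [label_basins()]), or the labelled tibble itself.
#' @param unfolded Character vector of unfolded basin names.
#' @param folded Name of the folded basin.
#' @param catalog Character vector of path strings; see
#'   [default_path_catalog()].
#' @param first_passage_only Count only the first folding event.
#' @return A tibble of class `path_report` with columns `path`, `count`,
#'   `probability` (0-count catalog paths retained).
#' @export
enumerate_transition_paths <- function(labels, unfolded = c("U1", "U2"),
                                       folded = "F",
                                       catalog = default_path_catalog(),
                                       first_passage_only = FALSE) {
  if (is.data.frame(labels)) labels <- labels$basin
  if (length(catalog) == 0) abort("path catalog is empty")
  seqv <- labels[labels != "unassigned"]
  seqv <- seqv[c(TRUE, seqv[-1] != seqv[-length(seqv)])]  # collapse repeats
  events <- character(0)
  cur <- character(0)
  for (b in seqv) {
    if (length(cur) == 0) {
      if (b %in% unfolded) cur <- b
      next
    }
    cur <- c(cur, b)
    if (b == folded) {
      events <- c(events, paste(cur, collapse = ">"))
      cur <- character(0)
      if (first_passage_only) break
    }
  }
  if (!first_passage_only && length(cur) >= 2) {
    events <- c(events, paste(cur, collapse = ">"))  # trailing non-folding event
  }
  if (length(events) == 0) {
    warn("no transition events observed")
    out <- tibble(path = catalog, count = 0L, probability = NA_real_)
  } else {
    matched <- ifelse(events %in% catalog, events, "other")
    lev <- c(catalog, if (any(matched == "other")) "other")
    cnt <- table(factor(matched, levels = lev))
    out <- tibble(path = names(cnt), count = as.integer(cnt),
                  probability = as.integer(cnt) / length(events))
  }
  class(out) <- c("path_report", class(out))
  out
}

#' Combined mechanism report
#'
#' Bundles the result surface of the analysis: cluster summary, occurrence
#' probabilities, conditionals given the turn is absent, free-energy minima
#' and transition-path statistics, with the turn-first verdict. The verdict
#' is `"turn precedes H-bonds"` when every conditional of the driving turn
#' is below `zero_tol`.
#'
#' @param occurrence Result of [occurrence_table()].
#' @param conditionals Result of [conditional_hbond_given_no_turn()].
#' @param paths Result of [enumerate_transition_paths()] (or `NULL`).
#' @param minima Result of [find_minima()] (or `NULL`).
#' @param clusters Result of [cluster_daura()] (or `NULL`).
#' @param driving_turn Label of the designated turn.
#' @param condition pH condition label.
#' @param zero_tol Threshold below which a conditional counts as zero.
#' @return An object of class `mechanism_report`.
#' @export
mechanism_report <- function(occurrence, conditionals, paths = NULL,
                             minima = NULL, clusters = NULL,
                             driving_turn = NULL, condition = NULL,
                             zero_tol = 0.01) {
  verdict <- NA_character_
  if (!is.null(driving_turn)) {
    cc <- filter(conditionals, .data$turn == driving_turn, .data$defined)
    if (nrow(cc) > 0) {
      verdict <- if (all(cc$probability < zero_tol)) {
        "turn precedes H-bonds"
      } else {
        "H-bonds occur without the turn"
      }
    }
  }
  structure(list(occurrence = occurrence, conditionals = conditionals,
                 paths = paths, minima = minima,
                 clusters = if (!is.null(clusters)) glance(clusters),
                 driving_turn = driving_turn, condition = condition,
                 verdict = verdict),
            class = "mechanism_report")
}

#' @export
print.mechanism_report <- function(x, ...) {
  cat("<mechanism_report>", if (!is.null(x$condition)) paste0(" (", x$condition, " pH)"), "\n", sep = "")
  if (!is.null(x$clusters)) {
    cat(sprintf("  top cluster population: %.3f\n", x$clusters$top_population))
  }
  if (!is.na(x$verdict)) cat("  verdict:", x$verdict, "\n")
  if (!is.null(x$paths) && nrow(x$paths)) {
    on <- x$paths[x$paths$count > 0, ]
    if (nrow(on)) {
      cat("  paths:", paste(sprintf("%s %.2f", on$path, on$probability),
                            collapse = ", "), "\n")
    }
  }
  invisible(x)
}

#' @rdname mechanism_report
#' @param x A `mechanism_report`.
#' @param what Which table to return: `"occurrence"`, `"conditionals"`,
#'   `"paths"` or `"minima"`.
#' @param ... Unused.
#' @export
tidy.mechanism_report <- function(x, what = c("occurrence", "conditionals",
                                              "paths", "minima"), ...) {
  what <- match.arg(what)
  x[[what]]
}

#' @rdname mechanism_report
#' @export
glance.mechanism_report <- function(x, ...) {
  tibble(condition = x$condition %||% NA_character_,
         driving_turn = x$driving_turn %||% NA_character_,
         verdict = x$verdict,
         n_events = if (!is.null(x$paths)) sum(x$paths$count) else NA_integer_,
         top_population = if (!is.null(x$clusters)) x$clusters$top_population else NA_real_)
}
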