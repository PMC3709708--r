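#' Plot a free-energy surface
#'
#' Filled tile map of F over (RMSD, y-code) with contour lines at 1 kJ/mol
#' spacing; unsampled bins are blank.
#'
#' @param object An `fes` object from [build_fes()].
#' @param contour_spacing Contour interval in kJ/mol.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fes <- function(object, contour_spacing = 1, ...) {
  g <- filter(object$grid, !is.na(.data$F))
  ggplot2::ggplot(g, ggplot2::aes(.data$x_center, .data$y_level)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$F)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$F),
                          binwidth = contour_spacing, colour = "grey20",
                          na.rm = TRUE) +
    ggplot2::scale_fill_viridis_c(name = "F (kJ/mol)", direction = -1) +
    ggplot2::scale_y_continuous(breaks = object$y_levels) +
    ggplot2::labs(x = "RMSD to most-clustered structure (nm)",
                  y = "turn / hydrogen-bond code") +
    ggplot2::theme_minimal()
}

#' Plot an RMSD time series
#'
#' @param rmsd A tibble from [rmsd_series()] (optionally with a
#'   `trajectory` column).
#' @return A ggplot object.
#' @export
plot_rmsd_series <- function(rmsd) {
  aes <- if ("trajectory" %in% names(rmsd)) {
    ggplot2::aes(.data$time, .data$rmsd, colour = .data$trajectory)
  } else {
    ggplot2::aes(.data$time, .data$rmsd)
  }
  ggplot2::ggplot(rmsd, aes) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ns)", y = "RMSD (nm)") +
    ggplot2::theme_minimal()
}

#' Plot per-residue turn/strand propensities
#'
#' @param prop A tibble from [residue_propensities()].
#' @return A ggplot object.
#' @export
plot_propensities <- function(prop) {
  long <- tidyr::pivot_longer(prop, c("p_turn", "p_strand"),
                              names_to = "kind", values_to = "probability")
  long$kind <- c(p_turn = "turn", p_strand = "strand")[long$kind]
  ggplot2::ggplot(long, ggplot2::aes(.data$residue, .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~kind, ncol = 1) +
    ggplot2::scale_x_continuous(breaks = prop$residue) +
    ggplot2::labs(x = "residue", y = "occurrence probability") +
    ggplot2::theme_minimal()
}

#' Plot transition-path probabilities
#'
#' @param object A `path_report` from [enumerate_transition_paths()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.path_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$path, .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "transition path", y = "probability") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
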