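#' Plot a PMF profile
#'
#' Free energy vs. separation with the per-point uncertainty as a ribbon.
#' @param object an `fl_pmf`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fl_pmf <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$w)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$w - .data$w_err,
                                      ymax = .data$w + .data$w_err),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "separation (nm)", y = "W(r) (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Plot an orientation distribution
#'
#' Histogram of body-axis angles to the interface normal.
#' @param data a tibble from [orientation_series()].
#' @param binwidth degrees (default 2).
#' @return A ggplot.
#' @export
plot_orientation <- function(data, binwidth = 2) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$angle)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "angle to interface normal (deg)", y = "frames") +
    ggplot2::theme_minimal()
}

#' Plot a separation trace
#'
#' Inter-monomer distance vs. time, with an optional detected dissociation
#' frame marked.
#' @param data a tibble from [separation_series()].
#' @param event optional frame index from [detect_dissociation()].
#' @return A ggplot.
#' @export
plot_separation <- function(data, event = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$time, y = .data$distance)) +
    ggplot2::geom_line(colour = "darkgreen") +
    ggplot2::labs(x = "time (ns)", y = "separation (nm)") +
    ggplot2::theme_minimal()
  if (!is.null(event) && !is.na(event))
    p <- p + ggplot2::geom_vline(xintercept = data$time[event],
                                 linetype = "dashed", colour = "red")
  p
}

#' Plot per-residue interface burial
#'
#' Buried area per residue for the two chains of an interface report.
#' @param object an `fl_interface`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.fl_interface <- function(object, ...) {
  df <- object$per_residue
  ggplot2::ggplot(df, ggplot2::aes(x = .data$res_seq, y = .data$delta_sasa,
                                   fill = .data$buried)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~chain, ncol = 1) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "residue", y = expression(Delta * SASA ~ (ring(A)^2))) +
    ggplot2::theme_minimal()
}
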