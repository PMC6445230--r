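#' Plot spectra as stick plots
#'
#' One panel per spectrum, peaks drawn as vertical segments, the way
#' instrument software renders unit-resolution scans.
#'
#' @param spectra A spectrum tibble.
#' @param label_top Number of most intense peaks to label with their m/z per
#'   spectrum (default 5).
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectra, label_top = 5) {
  check_spectra(spectra)
  labs_df <- spectra |>
    group_by(.data$spectrum) |>
    slice_max(.data$intensity, n = label_top, with_ties = FALSE) |>
    ungroup()
  ggplot2::ggplot(spectra, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0),
                          linewidth = 0.4) +
    ggplot2::geom_text(data = labs_df,
                       ggplot2::aes(label = round(.data$mz)),
                       vjust = -0.4, size = 2.8) +
    ggplot2::facet_wrap(ggplot2::vars(.data$spectrum), scales = "free") +
    ggplot2::labs(x = "m/z", y = "relative intensity") +
    ggplot2::expand_limits(y = 0) +
    ggplot2::theme_minimal()
}

#' Plot the precursor survival profile of a call
#'
#' @param call Output of [select_precursor()].
#' @return A ggplot object.
#' @export
plot_precursor_profile <- function(call) {
  prof <- call$profile[[1]]
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$fragmentor_voltage,
                                     y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fragmentor voltage (eV)",
                  y = sprintf("relative intensity of m/z %s", format(call$mz)),
                  title = "In-source survival of the called precursor") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the evidence scores behind a report's ranking
#'
#' @param object An `npsid_report`.
#' @param n_top Candidates to show (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot npsid_report
#' @export
autoplot.npsid_report <- function(object, n_top = 10, ...) {
  d <- head(object$candidates, n_top) |>
    mutate(formula = factor(.data$formula, levels = rev(.data$formula))) |>
    tidyr::pivot_longer(c("isotope_score", "fragment_coverage", "score"),
                        names_to = "component", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$formula,
                                  fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "score", y = NULL,
                  title = "Candidate formulas by composite evidence") +
    ggplot2::theme_minimal()
}
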