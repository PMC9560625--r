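#' Plot a spectrum
#'
#' @param object A `zooms_spectrum`.
#' @param peaks Optional `zooms_peaks` tibble to overlay as points.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot zooms_spectrum
#' @export
autoplot.zooms_spectrum <- function(object, peaks = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "m/z (Th)", y = "Intensity",
                  title = attr(object, "sample_id")) +
    ggplot2::theme_minimal()
  if (!is.null(peaks) && nrow(peaks) > 0) {
    p <- p + ggplot2::geom_point(data = as_tibble(peaks), colour = "red",
                                 size = 1)
  }
  p
}

#' Plot site-level deamidation statistics
#'
#' Mean %Gln per site and peptide with 2 SE error bars, the standard display
#' for comparing collagen preservation across contexts.
#'
#' @param stats Tibble from [aggregate_site_stats()].
#' @return A ggplot.
#' @export
plot_site_deamidation <- function(stats) {
  ggplot2::ggplot(stats,
                  ggplot2::aes(x = .data$site, y = .data$mean,
                               colour = .data$peptide)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$two_se,
                                          ymax = .data$mean + .data$two_se),
                             position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "%Gln (1 = undeamidated)",
                  colour = "Peptide") +
    ggplot2::theme_minimal()
}

#' Plot the taxonomic composition of assignments
#'
#' @param assignments Tibble from [batch_identify()].
#' @return A ggplot bar chart of assignment categories.
#' @export
plot_assignments <- function(assignments) {
  ggplot2::ggplot(assignments, ggplot2::aes(y = .data$assignment)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "Samples", y = NULL) +
    ggplot2::theme_minimal()
}
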