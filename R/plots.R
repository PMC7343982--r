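## ggplot2 displays for the result objects.

#' Plot a cycle-normalized trajectory
#'
#' Loess estimate with its 95% bootstrap band over normalized cycle days
#' 1-28; the shaded left strip marks days 1-5, when menses typically occurs.
#'
#' @param object A [fit_trajectory()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cyclo_trajectory <- function(object, ...) {
  g <- object$grid
  ggplot2::ggplot(g, ggplot2::aes(x = .data$n, y = .data$estimate)) +
    ggplot2::annotate("rect", xmin = 1, xmax = 5, ymin = -Inf, ymax = Inf,
                      fill = "red", alpha = 0.08) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "grey70", alpha = 0.5) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Normalized cycle day", y = object$measure) +
    ggplot2::theme_minimal()
}

#' Plot a periodogram
#'
#' Normalized Lomb-Scargle power against period (days), with the top peaks
#' labeled.
#'
#' @param object A [lssa()] spectrum.
#' @param k Number of peaks to label (default 2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cyclo_spectrum <- function(object, k = 2, ...) {
  pk <- peak_periods(object, k)
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$period, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Period (days)", y = "Normalized power") +
    ggplot2::theme_minimal()
  if (nrow(pk) > 0) {
    p <- p + ggplot2::geom_point(data = pk, colour = "red") +
      ggplot2::geom_text(data = pk, ggplot2::aes(label = .data$period),
                         vjust = -0.6, size = 3)
  }
  p
}

#' CST timeline for each participant
#'
#' Daily CST labels as colored tiles over study days, one row per
#' participant; red points mark reported menses days.
#'
#' @param cohort Cohort tibble (CST assigned if absent).
#' @return A ggplot.
#' @export
plot_cst_timeline <- function(cohort) {
  if (!"cst" %in% names(cohort)) cohort <- assign_cst(cohort)
  p <- ggplot2::ggplot(cohort, ggplot2::aes(x = .data$day,
                                            y = .data$participant)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$cst), height = 0.8) +
    ggplot2::scale_fill_brewer(palette = "Set1", name = "CST") +
    ggplot2::labs(x = "Study day", y = NULL) +
    ggplot2::theme_minimal()
  if ("menses" %in% names(cohort)) {
    p <- p + ggplot2::geom_point(
      data = cohort[cohort$menses %in% "menses", ],
      colour = "red", size = 0.4
    )
  }
  p
}
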