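# Tidiers and plots for score reports.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a score report into per-category rows
#'
#' @param x A `chemquiz_score`.
#' @param ... Unused.
#' @return Tibble with `category`, `n`, `k`, `accuracy`, `ci_low`,
#'   `ci_high`.
#' @export
tidy.chemquiz_score <- function(x, ...) x$by_category

#' One-row summary of a score report
#'
#' @param x A `chemquiz_score`.
#' @param ... Unused.
#' @return One-row tibble with overall `n`, `k`, `accuracy`, CI bounds and
#'   the extraction `mode`.
#' @export
glance.chemquiz_score <- function(x, ...) {
  dplyr::mutate(x$overall, mode = x$mode)
}

#' Plot per-category accuracies with confidence intervals
#'
#' @param object A `chemquiz_score`.
#' @param ... Unused.
#' @return A ggplot object: accuracy bars with 95% Wald intervals.
#' @export
autoplot.chemquiz_score <- function(object, ...) {
  df <- object$by_category
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.25) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "accuracy",
                  title = sprintf("Benchmark accuracy (%s extraction): %d/%d overall",
                                  object$mode, object$overall$k, object$overall$n)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a simulated proton spectrum as a stick diagram
#'
#' @param s1 A `spectrum_1d` from [simulate_1d()].
#' @return A ggplot object with one stick per proton class, annotated with
#'   multiplicity and integration.
#' @export
plot_spectrum_1d <- function(s1) {
  df <- s1$h_peaks
  ggplot2::ggplot(df, ggplot2::aes(x = .data$shift, y = .data$integration)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$shift, yend = 0), linewidth = 1) +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$mult, ", ", .data$integration, "H")),
                       vjust = -0.5, size = 3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "1H shift (ppm)", y = "integration",
                  title = paste0("Simulated 1H NMR: ", s1$formula)) +
    ggplot2::theme_minimal()
}
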