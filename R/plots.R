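# ggplot2 displays for the main result types.

#' Heritability estimates by method and indicator
#'
#' Dot-and-interval plot of the report's heritability table, one panel row,
#' colour per method.
#'
#' @param report A `ses_report` (or its `heritability` tibble).
#' @return A ggplot object.
#' @export
plot_heritability <- function(report) {
  tbl <- if (inherits(report, "ses_report")) report$heritability else report
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$indicator, y = .data$estimate,
                                    colour = .data$method)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = NULL, y = expression(h^2), colour = "Method") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ses_report <- function(object, ...) plot_heritability(object)

#' @export
autoplot.ace_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rho_c_assumed,
                                       y = .data$estimate,
                                       colour = .data$component,
                                       fill = .data$component)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Assumed cousin shared-environment correlation",
                  y = "Standardized variance component") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ses_pca <- function(object, ...) {
  tbl <- tidy.ses_pca(object)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$component, y = .data$explained)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1 / length(object$eigenvalues),
                        linetype = "dashed") +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = NULL, y = "Explained variance") +
    ggplot2::theme_minimal()
}
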