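# ggplot2 visualisations for the main result types.

#' @rdname plots
#' @param object A retrotx result object.
#' @param ... Unused.
#' @export
autoplot.rte_roc <- function(object, ...) {
  curve <- object$curve
  op <- object$operating_point
  ggplot2::ggplot(curve, ggplot2::aes(x = 1 - .data$specificity,
                                      y = .data$sensitivity)) +
    ggplot2::geom_step(colour = "#2c7fb8") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(data = op, colour = "#d95f02", size = 2) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC = %.3f)", object$auc)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plots for retrotx results
#'
#' `autoplot()` methods: ROC curves, selection scatter (cancer vs healthy
#' summary statistics), survival-screen hazard-ratio volcano, terminal
#' PFM base-frequency profile.
#'
#' @name plots
#' @rdname plots
#' @export
autoplot.rte_selection <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = log2(.data$healthy_ref + 0.1),
                                  y = log2(.data$cancer_median + 0.1),
                                  colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "#d95f02")) +
    ggplot2::labs(x = "log2 healthy reference + 0.1",
                  y = "log2 cancer median + 0.1") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.rte_surv_screen <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), .data$estimable)
  ggplot2::ggplot(d, ggplot2::aes(x = log2(.data$hr),
                                  y = -log10(.data$cox_p),
                                  colour = .data$cohort)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::geom_vline(xintercept = c(-1, 1), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "log2 hazard ratio (high vs low tertile)",
                  y = "-log10 Cox p") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.rte_pfm <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$frequency,
                                  colour = .data$base)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = sprintf("position (%s end)", attr(object, "end")),
                  y = "base frequency") +
    ggplot2::theme_minimal()
}
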