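#' Volcano plot of a differential-methylation fit
#'
#' Mean beta difference against -log10 q, with the dual selection
#' thresholds drawn and selected CpGs highlighted.
#'
#' @param object An `episig_diffmeth`.
#' @param q_max,min_abs_delta Thresholds to display.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot episig_diffmeth
#' @export
autoplot.episig_diffmeth <- function(object, q_max = 0.05,
                                     min_abs_delta = 0.10, ...) {
  tab <- object$table |>
    dplyr::filter(!is.na(.data$q_value), !is.na(.data$delta_beta)) |>
    dplyr::mutate(selected = .data$q_value < q_max &
                    abs(.data$delta_beta) > min_abs_delta)
  ggplot2::ggplot(tab, ggplot2::aes(.data$delta_beta,
                                    -log10(pmax(.data$q_value, 1e-300)),
                                    colour = .data$selected)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-min_abs_delta, min_abs_delta),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(q_max), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(Delta * beta~"(case - control)"),
                  y = expression(-log[10]~q),
                  colour = "selected") +
    ggplot2::theme_minimal()
}

#' Plot classifier scores by cohort
#'
#' The standard episignature read-out: per-sample calibrated case
#' probability, grouped by cohort, with the 0.5 decision boundary.
#'
#' @param scores Tibble from [score_samples()] with a `cohort` column.
#' @return A ggplot.
#' @export
plot_scores <- function(scores) {
  if (!"cohort" %in% names(scores)) abort("scores need a 'cohort' column")
  ggplot2::ggplot(dplyr::filter(scores, .data$scoreable),
                  ggplot2::aes(.data$cohort, .data$score,
                               colour = .data$call)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, size = 1.6) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "SVM case probability", colour = "call") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot DNAm age against chronological age
#'
#' @param clock_result Tibble from [age_acceleration()].
#' @return A ggplot with the identity line; vertical offsets are the age
#'   acceleration.
#' @export
plot_clock <- function(clock_result) {
  ggplot2::ggplot(clock_result,
                  ggplot2::aes(.data$chrono_age, .data$dnam_age,
                               colour = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::labs(x = "chronological age (years)",
                  y = "DNAm age (years)", colour = NULL) +
    ggplot2::theme_minimal()
}
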