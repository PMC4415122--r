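#' Decoded-choice trace plot
#'
#' The field's standard single-trial display: decoded choice on the
#' horizontal axis (negative = leftward, positive = rightward), time
#' unfolding upward, one trace per trial colored by the eventual choice.
#'
#' @param traces Choice-trace tibble.
#' @param trials Trial tibble (for choices).
#' @param highlight Optional trial ids drawn saturated (others faded).
#' @return A ggplot object.
#' @export
plot_choice_traces <- function(traces, trials, highlight = NULL) {
  df <- dplyr::left_join(traces, trials[, c("trial_id", "choice")],
                         by = "trial_id")
  df$emph <- if (is.null(highlight)) TRUE else df$trial_id %in% highlight
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$time,
                                   group = .data$trial_id,
                                   color = .data$choice,
                                   alpha = .data$emph)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_path(linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(L = "#3366BB", R = "#CC3333")) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 0.9, `FALSE` = 0.15),
                                guide = "none") +
    ggplot2::labs(x = "decoded choice (normalized)", y = "time (ms)",
                  color = "choice") +
    ggplot2::theme_minimal()
}

#' Decoder performance vs time
#'
#' @param perf Output of [performance_vs_time()].
#' @return A ggplot object.
#' @export
plot_performance_vs_time <- function(perf) {
  ggplot2::ggplot(perf, ggplot2::aes(x = .data$bin_start +
                                       (.data$bin_end - .data$bin_start) / 2,
                                     y = .data$accuracy)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, color = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "time of last decoded point (ms)",
                  y = "fraction correct", size = "trials") +
    ggplot2::theme_minimal()
}

#' Change-of-mind frequency by category, with Wilson intervals
#'
#' @param freq `proportions` tibble from [category_frequency_stats()].
#' @return A ggplot object.
#' @export
plot_event_frequencies <- function(freq) {
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$trial_class, y = .data$p)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper), width = 0.2) +
    ggplot2::labs(x = NULL, y = "P(change of mind)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Indecision regression scatter with fit
#'
#' @param indec Output of [indecision_regression()].
#' @return A ggplot object.
#' @export
plot_indecision_fit <- function(indec) {
  ggplot2::ggplot(indec$data, ggplot2::aes(x = .data$aligned, y = .data$rt)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         color = "black", linewidth = 0.5) +
    ggplot2::labs(x = "decoded choice toward eventual reach (100 ms)",
                  y = "reaction time (ms)") +
    ggplot2::theme_minimal()
}
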