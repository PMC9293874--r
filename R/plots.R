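# ggplot2 displays for schedules, real-time traces, feedback and group PSC.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a run schedule as condition blocks
#'
#' @param object an `nf_schedule`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.nf_schedule <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(xmin = .data$onset,
                                  xmax = .data$onset + .data$duration,
                                  ymin = 0, ymax = 1,
                                  fill = .data$condition)) +
    ggplot2::geom_rect(alpha = 0.8) +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = paste("Run", attr(object, "run_type"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Plot the real-time ROI residual series
#'
#' @param object an `rtp_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.rtp_result <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$residual)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$condition), size = 0.6,
                        na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "noise-reduced ROI signal (%)") +
    ggplot2::theme_minimal()
}

#' Plot a feedback trace as the displayed bar heights
#'
#' @param object a `feedback_trace`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.feedback_trace <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$bar))
  ggplot2::ggplot(d, ggplot2::aes(.data$volume, .data$bar,
                                  fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(blue = "#3366cc", red = "#cc3333",
                                          hidden = "grey70")) +
    ggplot2::facet_wrap(~block, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "volume", y = "bar height (% vs preceding rest)") +
    ggplot2::theme_minimal()
}

#' Plot per-run ROI percent signal change across subjects
#'
#' @param psc tibble with columns `subject`, `run`, `value` (e.g. the `psc`
#'   element of [run_pipeline()]'s report).
#' @return a ggplot.
#' @export
plot_psc_by_run <- function(psc) {
  ggplot2::ggplot(psc, ggplot2::aes(.data$run, .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6, size = 1) +
    ggplot2::labs(x = NULL, y = "Focus vs Describe PSC (%)") +
    ggplot2::theme_minimal()
}
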