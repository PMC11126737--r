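#' Plot a relative-proliferation sweep
#'
#' One curve per IPPI value: relative proliferation against `r/r0` on a log
#' x-axis, with the baseline (`C_P/C_P0 = 1`) and quiescence
#' (`C_P/C_P0 = 0`) levels marked.
#'
#' @param object An `nfl_sweep` from [ratio_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nfl_sweep <- function(object, ...) {
  r0 <- attr(object, "r0")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$r / .data$r0,
                               y = .data$relative_proliferation,
                               colour = factor(.data$ippi))) +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(r / r[0]),
                  y = expression(C[P] / C[P0]),
                  colour = "IPPI",
                  title = "Relative proliferation vs NADH/NAD+ ratio") +
    ggplot2::theme_minimal()
}

#' Plot a simulated trajectory
#'
#' Proliferation and NADH concentration against time, faceted by variable.
#'
#' @param object An `nfl_trajectory` from [simulate_trajectory()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nfl_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("C_P", "N"),
                              names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a hypoxia scenario grid
#'
#' IPPI over the (hypoxia severity, lactate production) grid; the iso-IPPI
#' contours are the compensation paths along which raising `k4` offsets the
#' loss of oxidative phosphorylation.
#'
#' @param object An `nfl_hypoxia` from [hypoxia_scenario()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nfl_hypoxia <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$kd2_factor, y = .data$k4,
                               fill = log10(.data$ippi))) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "kd2 scaling (1 = normoxia)", y = "k4",
                  fill = "log10 IPPI",
                  title = "Hypoxia: proliferation-quiescence competition") +
    ggplot2::theme_minimal()
}
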