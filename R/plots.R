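#' Plot a simulated trajectory
#'
#' Facets the concentration, dose and compartment cell-count histories
#' against time.
#'
#' @param object A `chemo_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chemo_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = -dplyr::all_of("time"),
                              names_to = "variable", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (arbitrary units)", y = NULL)
}

#' Plot a sensitivity envelope
#'
#' Ribbons for the min/max range and the 5-95% quantile band, with the
#' median curve on top.
#'
#' @param object A `chemo_envelope`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chemo_envelope <- function(object, ...) {
  out_lab <- switch(attr(object, "output"),
                    c = "concentration c(t)", N = "total cells N(t)")
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min, ymax = .data$max),
                         fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q05, ymax = .data$q95),
                         fill = "grey65") +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), linewidth = 0.5) +
    ggplot2::labs(x = "time (arbitrary units)", y = out_lab)
}

#' Plot an objective sweep
#'
#' @param object A `chemo_sweep`.
#' @param log_x Log-scale the parameter axis (default `TRUE`; sweeps are
#'   typically log-spaced).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chemo_sweep <- function(object, log_x = TRUE, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$param_value, y = .data$J)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = attr(object, "parameter"), y = "objective J")
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot a parameter sensitivity ranking
#'
#' @param object A `chemo_ranking`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chemo_ranking <- function(object, ...) {
  dat <- as_tibble(object)
  dat$parameter <- stats::reorder(dat$parameter, dat$score)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score, y = .data$parameter)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "normalized envelope-width score", y = NULL)
}
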