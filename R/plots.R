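# ggplot2 autoplot methods for the package's result objects.

#' @describeIn iei_distribution Plot the interval distribution as an
#'   interval-rate function; pass `empirical = ` a tibble from
#'   [empirical_distributions()] to overlay a simulated histogram.
#' @param object An `interval_dist` (autoplot).
#' @param empirical Optional empirical tibble to overlay.
#' @export
autoplot.interval_dist <- function(object, empirical = NULL, ...) {
  df <- interval_rates(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$interval * 1e3,
                                        y = .data$rate))
  if (!is.null(empirical)) {
    p <- p + ggplot2::geom_step(
      data = empirical,
      ggplot2::aes(x = .data$interval * 1e3, y = .data$rate),
      color = "grey60")
  }
  p +
    ggplot2::geom_line(linetype = if (is.null(empirical)) "solid" else
      "dashed") +
    ggplot2::labs(x = "interval (ms)",
                  y = sprintf("%ss per second", object$kind),
                  title = sprintf("%s distribution", object$kind)) +
    ggplot2::theme_minimal()
}

#' @describeIn deadtime_fixed_geometric Plot PMF, CDF and survivor function
#'   of the dead-time distribution.
#' @param object A `deadtime_dist` (autoplot).
#' @export
autoplot.deadtime_dist <- function(object, ...) {
  tidy(object) |>
    tidyr::pivot_longer(c("pmf", "cdf", "survivor"),
                        names_to = "fn", values_to = "value") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$duration * 1e3,
                                 y = .data$value)) +
    ggplot2::geom_step() +
    ggplot2::facet_wrap(~fn, scales = "free_y") +
    ggplot2::labs(x = "dead-time duration (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn event_recurrence Plot forward-recurrence distributions for
#'   selected reference bins.
#' @param object A `recurrence_matrix` (autoplot).
#' @param times Reference bin times to show (defaults to three spread over
#'   the window).
#' @export
autoplot.recurrence_matrix <- function(object, times = NULL, ...) {
  tt <- object$grid$times
  if (is.null(times)) {
    times <- tt[unique(pmax(1L, round(c(1, nrow(object$f) / 2,
                                        nrow(object$f)))))]
  }
  tidy(object) |>
    dplyr::filter(.data$time %in% times) |>
    dplyr::mutate(ref = factor(sprintf("t = %g ms", .data$time * 1e3))) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$waiting * 1e3, y = .data$prob,
                                 color = .data$ref)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "waiting time (ms)",
                  y = sprintf("f_%s", object$kind), color = NULL) +
    ggplot2::theme_minimal()
}
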