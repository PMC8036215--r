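#' Right-censored interval distributions
#'
#' Assembles the first-order inter-event-interval (IEI) and
#' inter-detection-interval (IDI) distributions over a finite observation
#' window. The probability of observing an interval of duration `w_k` is the
#' expected number of consecutive pairs separated by `w_k`, normalized by
#' the expected number of intervals per window:
#'
#' * IEI: `p_IEI(w_k) = sum_i p_event(t_i) * f_event(t_i, w_k) / n_IEIs`
#'   with `n_IEIs = n_events - 1 + p_zero`,
#' * IDI: `p_IDI(w_k) = sum_i p_detection(t_i) * f_detection(t_i, w_k) /
#'   n_IDIs` with `n_IDIs = n_detections - 1 + p_zero`,
#'
#' where `n_events = sum_i p_event(t_i)` (and likewise for detections) is
#' the expected number of points per window and `p_zero = prod_i (1 -
#' p_event(t_i))` the probability of a window containing no event at all
#' (which, with a detector ready at the window start, is also the
#' probability of no detection — a window with zero points contributes zero
#' intervals rather than minus one, hence the `+ p_zero`). The numerator
#' sums to exactly `n_intervals`, so the returned probabilities sum to 1:
#' the censoring distortion is reproduced, never corrected. This identity is
#' asserted to 1e-10 before normalizing.
#'
#' @param df For `iei_distribution()`: data frame with `time` and an
#'   event-probability column (`p_event` or `p`). For `idi_distribution()`:
#'   data frame with `time`, `p_detection` and `p_event` (as returned by
#'   [event_to_detection()] or [detection_to_event()]; `p_event` is needed
#'   for `p_zero`).
#' @param f_event,f_detection Matching [event_recurrence()] /
#'   [detection_recurrence()] matrices. `f_event` may be omitted, in which
#'   case it is computed from `df`.
#'
#' @return An object of class `interval_dist`: a list with `kind` (`"IEI"`
#'   or `"IDI"`), `grid`, `w` (interval durations `k * dt`), `probs`,
#'   `numerator`, `n_points`, `n_intervals`, `p_zero`.
#' @examples
#' g <- time_grid(0, 5e-3, 1e-4)
#' d <- deadtime_fixed_geometric(5e-4, 5e-4, 1e-4)
#' conv <- event_to_detection(sinusoid_exp_rate(g, 600, 1, 400), d)
#' fe <- event_recurrence(conv)
#' iei <- iei_distribution(conv, fe)
#' idi <- idi_distribution(conv, detection_recurrence(fe, d))
#' glance(idi)
#' @export
iei_distribution <- function(df, f_event = NULL) {
  grid <- series_grid(df)
  p <- role_probs(df, "p_event")
  if (is.null(f_event)) f_event <- event_recurrence(df)
  stopifnot(inherits(f_event, "recurrence_matrix"))
  if (f_event$kind != "event") {
    abort("`f_event` must have kind \"event\".", class = "deadtime_argument")
  }
  p_zero <- prod(1 - p)
  new_interval_dist("IEI", grid, weights = p, f = f_event$f,
                    n_points = sum(p), p_zero = p_zero)
}

#' @rdname iei_distribution
#' @export
idi_distribution <- function(df, f_detection) {
  grid <- series_grid(df)
  p_det <- series_probs(df, "p_detection")
  p_ev <- series_probs(df, "p_event")
  stopifnot(inherits(f_detection, "recurrence_matrix"))
  if (f_detection$kind != "detection") {
    abort("`f_detection` must have kind \"detection\".",
          class = "deadtime_argument")
  }
  # zero detections in a window <=> zero events (ready-at-start assumption)
  p_zero <- prod(1 - p_ev)
  new_interval_dist("IDI", grid, weights = p_det, f = f_detection$f,
                    n_points = sum(p_det), p_zero = p_zero)
}

new_interval_dist <- function(kind, grid, weights, f, n_points, p_zero) {
  m <- grid$m
  if (nrow(f) != m - 1L) {
    abort("grid mismatch: recurrence matrix does not match the series grid.",
          class = "deadtime_grid_mismatch")
  }
  numerator <- as.vector(weights[seq_len(m - 1L)] %*% f)
  n_intervals <- n_points - 1 + p_zero
  if (n_intervals < 1e-12) {
    abort(sprintf(
      "degenerate window: expected number of %ss is ~0 (%.3g).", kind,
      n_intervals), class = "deadtime_degenerate_window")
  }
  if (abs(sum(numerator) - n_intervals) > 1e-10 * max(1, n_intervals)) {
    abort(sprintf(
      "internal normalization failure: sum(numerator) = %.15g but n_%ss = %.15g.",
      sum(numerator), kind, n_intervals), class = "deadtime_internal")
  }
  structure(
    list(kind = kind, grid = grid, w = seq_len(m - 1L) * grid$dt,
         probs = numerator / n_intervals, numerator = numerator,
         n_points = n_points, n_intervals = n_intervals, p_zero = p_zero),
    class = "interval_dist"
  )
}

#' Interval distribution as per-second rates
#'
#' Rescales an interval PMF to an interval-rate function: `R(w_k) =
#' p(w_k) / dt` (intervals per second), the form usually plotted for
#' interspike-interval histograms. Multiplying by `dt` recovers the PMF.
#'
#' @param dist An `interval_dist`.
#' @return A tibble with columns `interval` (s), `probability`, `rate`
#'   (1/s).
#' @export
interval_rates <- function(dist) {
  stopifnot(inherits(dist, "interval_dist"))
  tibble::tibble(interval = dist$w, probability = dist$probs,
                 rate = dist$probs / dist$grid$dt)
}

#' @describeIn iei_distribution Tidy into a tibble with columns `interval`,
#'   `probability`, `rate`.
#' @param x An `interval_dist`.
#' @param ... Unused.
#' @export
tidy.interval_dist <- function(x, ...) interval_rates(x)

#' @describeIn iei_distribution One-row summary: kind, expected points and
#'   intervals per window, `p_zero`, distribution mean and sd (seconds), and
#'   total probability mass.
#' @export
glance.interval_dist <- function(x, ...) {
  mu <- sum(x$w * x$probs)
  v <- sum(x$w^2 * x$probs) - mu^2
  tibble::tibble(
    kind = x$kind, n_points = x$n_points, n_intervals = x$n_intervals,
    p_zero = x$p_zero, mean = mu, sd = sqrt(max(v, 0)),
    total_mass = sum(x$probs)
  )
}

#' Summary statistics of an interval distribution
#'
#' @param dist An `interval_dist`.
#' @return A list with `mean` (s), `sd` (s) and `total_mass`.
#' @export
interval_summary <- function(dist) {
  g <- glance(dist)
  list(mean = g$mean, sd = g$sd, total_mass = g$total_mass)
}

#' @export
print.interval_dist <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<interval_dist> %s on [%g, %g] s (dt = %g s)\n",
    x$kind, x$grid$t_min, x$grid$t_max, x$grid$dt))
  cat(sprintf(
    "  n_points = %.4g, n_intervals = %.4g, p_zero = %.4g\n",
    x$n_points, x$n_intervals, x$p_zero))
  cat(sprintf("  mean = %.4g s, sd = %.4g s, mass = %.6g\n",
              g$mean, g$sd, g$total_mass))
  invisible(x)
}
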