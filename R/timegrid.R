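#' Discretized observation window
#'
#' Defines the time discretization used throughout the package: the window
#' `[t_min, t_max]` is divided into `m` bins of width `dt`, and each bin is
#' labeled by the time point at its right edge, `t_i = t_min + i * dt`
#' (1-based), so `t_m = t_max`. All per-bin series (event probability,
#' detection probability, dead-state probability) live on such a grid.
#'
#' @param t_min,t_max Window start and end, in seconds (`t_max > t_min`).
#' @param dt Bin width in seconds (`dt > 0`). `(t_max - t_min) / dt` must be
#'   an integer to within a relative tolerance of 1e-9.
#'
#' @return An object of class `time_grid`: a list with elements `t_min`,
#'   `t_max`, `dt`, `m` (number of bins) and `times` (right-edge bin labels).
#' @examples
#' g <- time_grid(0, 5e-3, 1e-4)
#' g$m          # 50
#' g$times[1]   # 1e-4
#' @export
time_grid <- function(t_min, t_max, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    abort("`dt` must be a single positive number (seconds).",
          class = "deadtime_argument")
  }
  if (t_max <= t_min) {
    abort("`t_max` must be greater than `t_min`.", class = "deadtime_argument")
  }
  m_real <- (t_max - t_min) / dt
  m <- round(m_real)
  if (m < 1 || abs(m_real - m) > 1e-9 * max(1, abs(m_real))) {
    abort(
      sprintf("grid mismatch: (t_max - t_min)/dt = %.12g is not an integer.",
              m_real),
      class = "deadtime_grid_mismatch"
    )
  }
  structure(
    list(t_min = t_min, t_max = t_max, dt = dt, m = as.integer(m),
         times = t_min + seq_len(m) * dt),
    class = "time_grid"
  )
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf(
    "<time_grid> [%g, %g] s, dt = %g s, m = %d bins (right-edge labels)\n",
    x$t_min, x$t_max, x$dt, x$m))
  invisible(x)
}

#' @export
format.time_grid <- function(x, ...) {
  sprintf("time_grid(%g, %g, %g)", x$t_min, x$t_max, x$dt)
}

# Infer the grid underlying a series tibble with a `time` column; validates
# uniform spacing (relative 1e-9). Returns a time_grid.
series_grid <- function(df) {
  if (!is.data.frame(df) || !"time" %in% names(df)) {
    abort("expected a data frame with a `time` column.",
          class = "deadtime_argument")
  }
  tm <- df$time
  if (length(tm) < 1L) {
    abort("series has no rows.", class = "deadtime_argument")
  }
  if (length(tm) == 1L) {
    dt <- tm[1]
    if (dt <= 0) abort("single-bin series must have time > 0 (right edge).",
                       class = "deadtime_argument")
    return(time_grid(0, dt, dt))
  }
  steps <- diff(tm)
  dt <- steps[1]
  if (dt <= 0 || any(abs(steps - dt) > 1e-9 * dt)) {
    abort("grid mismatch: `time` values are not uniformly spaced.",
          class = "deadtime_grid_mismatch")
  }
  time_grid(tm[1] - dt, tm[length(tm)], dt)
}

# Check that a series' times match a declared grid.
check_grid_match <- function(df, grid, what = "series") {
  if (nrow(df) != grid$m ||
      any(abs(df$time - grid$times) > 1e-9 * max(grid$dt, abs(grid$times)))) {
    bad <- if (nrow(df) == grid$m) {
      which(abs(df$time - grid$times) >
              1e-9 * max(grid$dt, abs(grid$times)))[1]
    } else NA_integer_
    abort(
      sprintf("grid mismatch: %s does not match the declared grid%s.", what,
              if (is.na(bad)) sprintf(" (%d rows vs %d bins)", nrow(df), grid$m)
              else sprintf(" (first mismatch at row %d)", bad)),
      class = "deadtime_grid_mismatch"
    )
  }
  invisible(df)
}

#' Convert between rate and per-bin probability
#'
#' A rate series `R(t_i)` (events/s) on a grid with bin width `dt` seconds is
#' equivalent to the per-bin probability series `p(t_i) = R(t_i) * dt`; the
#' probability of more than one event per bin is neglected, which is the
#' discrete-time approximation the whole method is built on. `rate_to_prob()`
#' adds/overwrites the `p` column; `prob_to_rate()` recovers `rate = p / dt`.
#' The two are exact inverses.
#'
#' @param df A data frame with a `time` column (right-edge labels, seconds)
#'   and a `rate` column (events/s) for `rate_to_prob()`, or a `p` column for
#'   `prob_to_rate()`.
#' @param grid Optional [time_grid()] to validate the `time` column against.
#'
#' @return A tibble with columns `time`, `rate`, `p`.
#' @examples
#' g <- time_grid(0, 5e-3, 1e-4)
#' rate_to_prob(constant_rate(g, 1000))
#' @export
rate_to_prob <- function(df, grid = NULL) {
  g <- if (is.null(grid)) series_grid(df) else {
    check_grid_match(df, grid)
    grid
  }
  if (!"rate" %in% names(df)) {
    abort("expected a `rate` column (events/s).", class = "deadtime_argument")
  }
  if (any(!is.finite(df$rate)) || any(df$rate < 0)) {
    abort("rates must be finite and non-negative.",
          class = "deadtime_argument")
  }
  p <- df$rate * g$dt
  if (any(p > 1)) {
    k <- which(p > 1)[1]
    abort(
      sprintf(paste0("probability overflow: rate * dt = %.6g > 1 at ",
                     "t = %g s; the time step is too coarse."),
              p[k], df$time[k]),
      class = "deadtime_overflow"
    )
  }
  tibble::tibble(time = df$time, rate = df$rate, p = p)
}

#' @rdname rate_to_prob
#' @export
prob_to_rate <- function(df, grid = NULL) {
  g <- if (is.null(grid)) series_grid(df) else {
    check_grid_match(df, grid)
    grid
  }
  if (!"p" %in% names(df)) {
    abort("expected a `p` column (per-bin probability).",
          class = "deadtime_argument")
  }
  if (any(df$p < 0) || any(df$p > 1)) {
    abort("probabilities must lie in [0, 1].", class = "deadtime_argument")
  }
  tibble::tibble(time = df$time, rate = df$p / g$dt, p = df$p)
}

# Extract a named probability column as a bare numeric vector, validating
# range. Used by the pipeline internals.
series_probs <- function(df, col = "p") {
  if (!col %in% names(df)) {
    abort(sprintf("expected a `%s` column.", col), class = "deadtime_argument")
  }
  p <- df[[col]]
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", col),
          class = "deadtime_argument")
  }
  p
}
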