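#' Forward-recurrence distributions
#'
#' `event_recurrence()` computes, for every bin `t_i` except the last, the
#' (incomplete) distribution of waiting times `w_k = k * dt` to the next
#' event: `f_event(t_i, w_k) = p_event(t_{i+k}) * prod_{h=i+1}^{i+k-1} (1 -
#' p_event(t_h))`, i.e. the joint probability that the next `k - 1` bins are
#' empty and bin `i + k` contains an event. Waiting times that would extend
#' beyond the window edge are not represented (right censoring), so row sums
#' are below 1.
#'
#' `detection_recurrence()` turns this into the distribution of waiting
#' times to the next detection, conditional on a detection at `t_i`: the
#' dead time drawn at `t_i` has duration `d_j` with probability
#' `g_dead(d_j)`, blocks all waiting times shorter than `d_j`, and detection
#' becomes possible again at elapsed times `>= d_j`, following the event
#' recurrence from there:
#' `f_detection(t_i, w_k) = sum_{j=1}^{k} g_dead(d_j) *
#' f_event(t_{i+j-1}, w_{k-j+1})`. Because a detection is assumed at `t_i`,
#' these waiting times are the inter-detection intervals themselves.
#'
#' @param df Data frame with `time` and an event-probability column
#'   (`p_event` or `p`); at least 2 bins.
#' @param f_event A `recurrence_matrix` of kind `"event"`.
#' @param dist Dead-time distribution on the same `dt`.
#'
#' @return An object of class `recurrence_matrix`: a list with `grid`,
#'   `kind` (`"event"` or `"detection"`), and `f`, a dense `(m-1) x (m-1)`
#'   matrix whose row `i` holds `f(t_i, w_k)` for `k = 1..m-i` (structural
#'   zeros beyond the window edge).
#' @examples
#' g <- time_grid(0, 5e-3, 1e-4)
#' fe <- event_recurrence(sinusoid_exp_rate(g, 600, 1, 400))
#' fd <- detection_recurrence(fe, deadtime_fixed_geometric(5e-4, 5e-4, 1e-4))
#' @export
event_recurrence <- function(df) {
  grid <- series_grid(df)
  p <- role_probs(df, "p_event")
  m <- grid$m
  if (m < 2) {
    abort("need at least 2 bins to form a recurrence distribution.",
          class = "deadtime_argument")
  }
  f <- matrix(0, m - 1L, m - 1L)
  for (i in seq_len(m - 1L)) {
    L <- m - i
    pp <- p[(i + 1L):m]
    surv <- if (L > 1L) c(1, cumprod(1 - pp[seq_len(L - 1L)])) else 1
    f[i, seq_len(L)] <- pp * surv
  }
  new_recurrence_matrix(grid, "event", f)
}

#' @rdname event_recurrence
#' @export
detection_recurrence <- function(f_event, dist) {
  stopifnot(inherits(f_event, "recurrence_matrix"))
  if (f_event$kind != "event") {
    abort("`f_event` must be a recurrence matrix of kind \"event\".",
          class = "deadtime_argument")
  }
  check_dt_match(f_event$grid, dist)
  fe <- f_event$f
  mm1 <- nrow(fe)
  m <- mm1 + 1L
  g <- deadtime_pmf_vec(dist, mm1)
  fd <- matrix(0, mm1, mm1)
  for (j in which(g > 0)) {
    # f_det[i, k] += g[j] * f_event[i + j - 1, k - j + 1]
    fd[seq_len(m - j), j:mm1] <- fd[seq_len(m - j), j:mm1] +
      g[j] * fe[j:mm1, seq_len(mm1 - j + 1L), drop = FALSE]
  }
  new_recurrence_matrix(f_event$grid, "detection", fd)
}

#' Periodic-rate duplication of recurrence distributions
#'
#' When the event probability series is periodic on the grid, the forward
#' recurrence distribution at two bins one period apart is identical except
#' that the later one is truncated harder by the window edge. It therefore
#' suffices to compute rows for the bins of the first cycle and duplicate
#' them (truncated) to later cycles; the result is identical to the full
#' computation, entry for entry, including floating-point evaluation order.
#'
#' @param df Data frame with `time` and an event-probability column.
#' @param period_bins Period in bins; must divide the window length in bins,
#'   and the series must repeat with this period (relative tolerance 1e-12),
#'   otherwise a "not periodic" error is raised.
#' @param dist Optional dead-time distribution; when supplied the duplicated
#'   event matrix is convolved into a detection-kind matrix via
#'   [detection_recurrence()].
#'
#' @return A `recurrence_matrix` (kind `"event"`, or `"detection"` when
#'   `dist` is given).
#' @export
periodic_recurrence <- function(df, period_bins, dist = NULL) {
  grid <- series_grid(df)
  p <- role_probs(df, "p_event")
  m <- grid$m
  P <- as.integer(period_bins)
  if (is.na(P) || P < 1 || P > m || m %% P != 0) {
    abort("`period_bins` must be a positive divisor of the window length.",
          class = "deadtime_argument")
  }
  if (P < m) {
    tol <- 1e-12 * max(1, max(p))
    if (any(abs(p[seq_len(m - P)] - p[(P + 1L):m]) > tol)) {
      abort("not periodic: series does not repeat with the declared period.",
            class = "deadtime_not_periodic")
    }
  }
  f <- matrix(0, m - 1L, m - 1L)
  for (i in seq_len(min(P, m - 1L))) {
    L <- m - i
    pp <- p[(i + 1L):m]
    surv <- if (L > 1L) c(1, cumprod(1 - pp[seq_len(L - 1L)])) else 1
    f[i, seq_len(L)] <- pp * surv
    # duplicate (incompletely) to the same phase in later cycles
    i2 <- i + P
    while (i2 <= m - 1L) {
      f[i2, seq_len(m - i2)] <- f[i, seq_len(m - i2)]
      i2 <- i2 + P
    }
  }
  out <- new_recurrence_matrix(grid, "event", f)
  if (!is.null(dist)) out <- detection_recurrence(out, dist)
  out
}

new_recurrence_matrix <- function(grid, kind, f) {
  structure(list(grid = grid, kind = kind, f = f),
            class = "recurrence_matrix")
}

#' @export
print.recurrence_matrix <- function(x, ...) {
  cat(sprintf(
    "<recurrence_matrix> kind = %s, %d rows (t_1..t_%d), dt = %g s\n",
    x$kind, nrow(x$f), nrow(x$f), x$grid$dt))
  invisible(x)
}

#' @describeIn event_recurrence Tidy into a long tibble with columns `time`
#'   (reference bin `t_i`), `waiting` (`w_k`), and `prob`, keeping only
#'   entries inside the observation window.
#' @param x A `recurrence_matrix`.
#' @param ... Unused.
#' @export
tidy.recurrence_matrix <- function(x, ...) {
  mm1 <- nrow(x$f)
  idx <- which(row(x$f) + col(x$f) <= mm1 + 1L, arr.ind = TRUE)
  tibble::tibble(
    time = x$grid$times[idx[, 1L]],
    waiting = idx[, 2L] * x$grid$dt,
    prob = x$f[idx]
  ) |> dplyr::arrange(.data$time, .data$waiting)
}
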