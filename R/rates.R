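#' Rate-function generators
#'
#' Built-in event/detection rate generators on a [time_grid()]. Each returns
#' a tibble with columns `time` (right-edge bin labels, seconds), `rate`
#' (events/s) and `p` (per-bin probability, `rate * dt`).
#'
#' * `constant_rate()` — a homogeneous process.
#' * `sinusoid_exp_rate()` — a sinusoid passed through an exponential,
#'   `R(t) = A * exp(B * sin(2 * pi * f * t))`: `A` (events/s) is the rate
#'   where the sinusoid crosses zero, `B` is a dimensionless slope factor and
#'   `f` the frequency in Hz. When the period `1/(f * dt)` is an integer
#'   number of bins the series is evaluated by folding bin indices into the
#'   first cycle, so that grid periodicity holds exactly in floating point
#'   (this is what the periodic-duplication optimization of
#'   [periodic_recurrence()] relies on).
#' * `random_walk_rate()` — a rate trajectory obtained by cumulatively
#'   summing i.i.d. uniform steps on `[-step_bound, step_bound]` events/s,
#'   starting from `initial_rate` at the first bin. Trajectories that would
#'   go negative are clipped at 0 by default (`on_negative = "error"` raises
#'   instead). Reproducible from `seed`; R's global RNG state is left
#'   untouched.
#'
#' Any generated per-bin probability exceeding 1 raises a probability
#' overflow error (the time step is too coarse for the requested rate).
#'
#' @param grid A [time_grid()].
#' @param rate,A,B,f,initial_rate,step_bound Generator parameters, see above.
#' @param seed Integer seed for the random walk.
#' @param on_negative `"clip"` (default) or `"error"`.
#'
#' @return A tibble with columns `time`, `rate`, `p`.
#' @examples
#' g <- time_grid(0, 5e-3, 1e-4)
#' sinusoid_exp_rate(g, A = 600, B = 1, f = 400)
#' @name rate_generators
NULL

#' @rdname rate_generators
#' @export
constant_rate <- function(grid, rate) {
  stopifnot(inherits(grid, "time_grid"))
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0) {
    abort("`rate` must be a single non-negative number (events/s).",
          class = "deadtime_argument")
  }
  rate_to_prob(tibble::tibble(time = grid$times, rate = rep(rate, grid$m)),
               grid = grid)
}

#' @rdname rate_generators
#' @export
sinusoid_exp_rate <- function(grid, A, B, f) {
  stopifnot(inherits(grid, "time_grid"))
  if (!is.numeric(A) || length(A) != 1L || A < 0) {
    abort("`A` must be a single non-negative scale (events/s).",
          class = "deadtime_argument")
  }
  if (!is.numeric(f) || length(f) != 1L || f <= 0) {
    abort("`f` must be a single positive frequency (Hz).",
          class = "deadtime_argument")
  }
  period_real <- 1 / (f * grid$dt)
  period <- round(period_real)
  idx <- seq_len(grid$m)
  if (period >= 1 && abs(period_real - period) <= 1e-9 * period_real) {
    # integer period in bins: fold into the first cycle for exact periodicity
    t_eval <- grid$t_min + (((idx - 1L) %% period) + 1L) * grid$dt
  } else {
    t_eval <- grid$times
  }
  r <- A * exp(B * sin(2 * pi * f * t_eval))
  rate_to_prob(tibble::tibble(time = grid$times, rate = r), grid = grid)
}

#' @rdname rate_generators
#' @export
random_walk_rate <- function(grid, initial_rate, step_bound, seed = NULL,
                             on_negative = c("clip", "error")) {
  stopifnot(inherits(grid, "time_grid"))
  on_negative <- match.arg(on_negative)
  if (!is.numeric(initial_rate) || length(initial_rate) != 1L ||
      initial_rate < 0) {
    abort("`initial_rate` must be a single non-negative number (events/s).",
          class = "deadtime_argument")
  }
  if (!is.numeric(step_bound) || length(step_bound) != 1L || step_bound < 0) {
    abort("`step_bound` must be a single non-negative number (events/s).",
          class = "deadtime_argument")
  }
  steps <- if (is.null(seed)) {
    stats::runif(grid$m - 1L, -step_bound, step_bound)
  } else {
    withr::with_seed(seed, stats::runif(grid$m - 1L, -step_bound, step_bound))
  }
  r <- cumsum(c(initial_rate, steps))
  if (any(r < 0)) {
    if (on_negative == "error") {
      abort("random-walk rate went negative.", class = "deadtime_argument")
    }
    r <- pmax(r, 0)
  }
  rate_to_prob(tibble::tibble(time = grid$times, rate = r), grid = grid)
}
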