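#' Monte-Carlo simulation of the dead-time-modified process
#'
#' Simulates the discrete-time process directly: in each run, every bin `i`
#' contains an event independently with probability `p_event(t_i)`; an event
#' is detected iff the time elapsed since the last detection is at least the
#' dead time drawn at that detection (the detector is ready at the first
#' bin); each detection draws a fresh dead-time duration by inverse-CDF
#' sampling from the stored PMF. Undetected events never prolong a dead time
#' (nonparalyzable). Consecutive-event and consecutive-detection intervals
#' are accumulated into histograms, so right censoring by the window edge
#' emerges naturally.
#'
#' The simulator uses its own counter-based RNG (one splitmix64 stream per
#' run, keyed by `(seed, run)`), so results are fully reproducible from
#' `seed`, run `r`'s draws do not depend on `n_runs`, and R's global RNG
#' state is untouched. The dead-time family is never special-cased: the
#' simulator sees only the stored PMF, which keeps it an independent check
#' of the analytic distributions.
#'
#' @param df Data frame with `time` and an event-probability column
#'   (`p_event` or `p`).
#' @param dist Dead-time distribution on the same `dt`.
#' @param n_runs Number of independent windows to simulate (`>= 1`).
#' @param seed Integer seed.
#'
#' @return An object of class `deadtime_sim`: a list with `grid`, `n_runs`,
#'   `seed`, per-bin `event_counts` and `detection_counts`, interval
#'   histograms `iei_hist` and `idi_hist` (counts at durations `k * dt`,
#'   `k = 1..m-1`), `total_ieis`, `total_idis`, and `zero_event_runs`.
#' @examples
#' g <- time_grid(0, 5e-3, 1e-4)
#' d <- deadtime_fixed_geometric(5e-4, 5e-4, 1e-4)
#' sim <- simulate_process(sinusoid_exp_rate(g, 600, 1, 400), d,
#'                         n_runs = 1000, seed = 1)
#' @export
simulate_process <- function(df, dist, n_runs, seed) {
  grid <- series_grid(df)
  check_dt_match(grid, dist)
  p <- role_probs(df, "p_event")
  if (!is.numeric(n_runs) || length(n_runs) != 1L || n_runs < 1) {
    abort("`n_runs` must be a positive integer.", class = "deadtime_argument")
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single integer.", class = "deadtime_argument")
  }
  res <- sim_deadtime_cpp(p, dist$cdf, as.integer(n_runs), as.numeric(seed))
  structure(
    list(grid = grid, n_runs = as.integer(n_runs), seed = seed,
         event_counts = res$event_counts,
         detection_counts = res$detection_counts,
         iei_hist = res$iei_hist, idi_hist = res$idi_hist,
         total_ieis = sum(res$iei_hist), total_idis = sum(res$idi_hist),
         zero_event_runs = res$zero_event_runs),
    class = "deadtime_sim"
  )
}

#' @export
print.deadtime_sim <- function(x, ...) {
  cat(sprintf(
    "<deadtime_sim> %d runs on %s: %.0f events, %.0f detections, %.0f IEIs, %.0f IDIs\n",
    x$n_runs, format(x$grid), sum(x$event_counts), sum(x$detection_counts),
    x$total_ieis, x$total_idis))
  invisible(x)
}

#' Empirical interval distributions from a simulation
#'
#' Normalizes the simulated interval histograms to empirical PMFs for
#' overlay with (and testing against) the numerically computed
#' distributions.
#'
#' @param sim A [simulate_process()] result with at least one interval
#'   observed.
#' @return A named list with elements `iei` and `idi`, each a tibble with
#'   columns `interval` (s), `count`, `probability` and `rate` (1/s), and
#'   attribute `n_intervals`.
#' @export
empirical_distributions <- function(sim) {
  stopifnot(inherits(sim, "deadtime_sim"))
  one <- function(hist, n, kind) {
    if (n < 1) {
      abort(sprintf("no intervals observed (%s).", kind),
            class = "deadtime_argument")
    }
    out <- tibble::tibble(
      interval = seq_along(hist) * sim$grid$dt, count = hist,
      probability = hist / n, rate = hist / n / sim$grid$dt)
    attr(out, "n_intervals") <- n
    out
  }
  list(iei = one(sim$iei_hist, sim$total_ieis, "IEI"),
       idi = one(sim$idi_hist, sim$total_idis, "IDI"))
}

#' Statistical agreement between numerical and empirical distributions
#'
#' Operationalizes "close agreement" between a numerically computed interval
#' distribution and its Monte-Carlo counterpart. Two statistics are used:
#'
#' * per-bin z-scores `(p_emp - p_num) / sqrt(p_num (1 - p_num) / n)`,
#'   evaluated only where the expected count `n * p_num` is at least
#'   `min_expected` (default 5, the usual chi-square rule of thumb); the
#'   remaining low-expectation bins are pooled into a single aggregate
#'   z-score, since a per-bin z is not meaningful when the expected count is
#'   a small fraction of one;
#' * the total-variation distance `0.5 * sum |p_emp - p_num|`.
#'
#' The test passes when `max |z| <= z_max` and TV `<= tv_max`.
#'
#' @param numerical An `interval_dist`.
#' @param empirical Matching tibble from [empirical_distributions()] (or any
#'   data frame with `probability` and `count` columns of the same length).
#' @param n_intervals Total interval count behind `empirical`; defaults to
#'   `sum(empirical$count)`.
#' @param z_max,tv_max,min_expected Test thresholds.
#'
#' @return A list with `max_z`, `tv`, `n_intervals` and logical `pass`.
#' @export
agreement_test <- function(numerical, empirical, n_intervals = NULL,
                           z_max = 5, tv_max = 0.01, min_expected = 5) {
  stopifnot(inherits(numerical, "interval_dist"))
  p_num <- numerical$probs
  if (nrow(empirical) != length(p_num)) {
    abort("grid mismatch: empirical and numerical distributions differ in length.",
          class = "deadtime_grid_mismatch")
  }
  n <- if (is.null(n_intervals)) sum(empirical$count) else n_intervals
  p_emp <- empirical$probability
  big <- n * p_num >= min_expected
  z_bin <- if (any(big)) {
    max(abs(p_emp[big] - p_num[big]) /
          sqrt(p_num[big] * (1 - p_num[big]) / n))
  } else 0
  p_tail_num <- sum(p_num[!big])
  p_tail_emp <- sum(p_emp[!big])
  z_tail <- if (p_tail_num > 0) {
    abs(p_tail_emp - p_tail_num) /
      sqrt(p_tail_num * (1 - p_tail_num) / n)
  } else if (p_tail_emp > 0) Inf else 0
  max_z <- max(z_bin, z_tail)
  tv <- 0.5 * sum(abs(p_emp - p_num))
  list(max_z = max_z, tv = tv, n_intervals = n,
       pass = max_z <= z_max && tv <= tv_max)
}
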