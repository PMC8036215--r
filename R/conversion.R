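# Event <-> detection rate conversion through the dead-state probability.

# pick a probability column by role, falling back to bare `p`
role_probs <- function(df, role) {
  col <- if (role %in% names(df)) role else "p"
  series_probs(df, col)
}

check_dt_match <- function(grid, dist) {
  if (abs(grid$dt - dist$dt) > 1e-9 * grid$dt) {
    abort("grid mismatch: dead-time distribution uses a different `dt`.",
          class = "deadtime_grid_mismatch")
  }
}

#' Probability of the detector being in a dead state
#'
#' At bin `t_i`, the detector is dead if some earlier bin `t_h` produced a
#' detection whose dead time extends through `t_i`:
#' `p_dead(t_i) = sum_{h=1}^{i-1} p_detection(t_h) * S_dead(d_{i-h})`, with
#' `p_dead(t_1) = 0` (the detector is assumed ready at the window start).
#' The terms are mutually exclusive across `h` (a dead time covering `t_i`
#' precludes any intervening detection), so the sum is itself a probability.
#'
#' The sum is a linear (zero-padded) convolution of the detection series
#' with the dead-time survivor function; `method = "fft"` evaluates it with
#' FFT-based convolution, `method = "direct"` with the triangular sum. The
#' two agree to better than 1e-12 absolute.
#'
#' @param df Data frame with `time` and a detection-probability column
#'   (`p_detection` or `p`).
#' @param dist A [deadtime_fixed_geometric()] / [deadtime_pmf()] object on
#'   the same `dt`.
#' @param method `"direct"` (default) or `"fft"`.
#'
#' @return A tibble with columns `time`, `p_dead`.
#' @export
dead_probability <- function(df, dist, method = c("direct", "fft")) {
  method <- match.arg(method)
  grid <- series_grid(df)
  check_dt_match(grid, dist)
  p_det <- role_probs(df, "p_detection")
  p_dead <- dead_prob_vec(p_det, dist, method)
  if (any(p_dead > 1 + 1e-9)) {
    abort("inconsistent detection series: implied p_dead exceeds 1.",
          class = "deadtime_inconsistent")
  }
  tibble::tibble(time = df$time, p_dead = p_dead)
}

dead_prob_vec <- function(p_det, dist, method = "direct") {
  m <- length(p_det)
  if (m == 1L) return(0)
  S <- deadtime_survivor_vec(dist, m - 1L)
  if (method == "fft") {
    cv <- stats::convolve(p_det, rev(S), type = "open")
    p_dead <- c(0, pmin(pmax(cv[seq_len(m - 1L)], 0), 1))
  } else {
    p_dead <- numeric(m)
    for (i in 2:m) {
      h <- seq_len(i - 1L)
      p_dead[i] <- sum(p_det[h] * S[i - h])
    }
  }
  p_dead
}

#' Convert between detection and event probability series
#'
#' A detection requires an event and a ready detector, so
#' `p_detection(t_i) = p_event(t_i) * (1 - p_dead(t_i))`.
#'
#' `detection_to_event()` inverts this: `p_event = p_detection / (1 -
#' p_dead)`, where `p_dead` follows from the (known) detection series alone.
#' The inversion is undefined where `p_dead = 1` (a bin lying inside the
#' fixed portion of a dead time following a certain detection): the event
#' probability there is unrecoverable and an error is raised.
#'
#' `event_to_detection()` runs the forward direction. Because `p_dead(t_i)`
#' depends on the detection probabilities of all earlier bins while
#' `p_detection(t_i)` depends on `p_dead(t_i)` at the same bin, both are
#' computed bin by bin in a single sequential pass. The forward direction is
#' always well defined, and the two directions are exact inverses of each
#' other (up to roundoff) wherever `p_dead` stays away from 1.
#'
#' @param df Data frame with `time` and a probability column: `p_detection`
#'   (or `p`) for `detection_to_event()`, `p_event` (or `p`) for
#'   `event_to_detection()`.
#' @param dist Dead-time distribution on the same `dt`.
#' @param method Method for the dead-state convolution in
#'   `detection_to_event()`: `"direct"` or `"fft"`.
#'
#' @return A tibble with columns `time`, `p_event`, `p_detection`, `p_dead`.
#' @examples
#' g <- time_grid(0, 5e-3, 1e-4)
#' d <- deadtime_fixed_geometric(5e-4, 5e-4, 1e-4)
#' conv <- event_to_detection(constant_rate(g, 1000), d)
#' @export
detection_to_event <- function(df, dist, method = c("direct", "fft")) {
  method <- match.arg(method)
  grid <- series_grid(df)
  check_dt_match(grid, dist)
  p_det <- role_probs(df, "p_detection")
  p_dead <- dead_prob_vec(p_det, dist, method)
  if (any(p_dead > 1 + 1e-9)) {
    abort("inconsistent detection series: implied p_dead exceeds 1.",
          class = "deadtime_inconsistent")
  }
  blocked <- p_dead >= 1 - 1e-9
  if (any(blocked)) {
    abort(
      sprintf(paste0("unrecoverable event probability: p_dead = 1 at ",
                     "t = %g s (bin inside a certain dead time)."),
              df$time[which(blocked)[1]]),
      class = "deadtime_unrecoverable"
    )
  }
  p_event <- p_det / (1 - p_dead)
  if (any(p_event > 1 + 1e-9)) {
    abort("inconsistent detection series: implied p_event exceeds 1.",
          class = "deadtime_inconsistent")
  }
  tibble::tibble(time = df$time, p_event = pmin(p_event, 1),
                 p_detection = p_det, p_dead = p_dead)
}

#' @rdname detection_to_event
#' @export
event_to_detection <- function(df, dist) {
  grid <- series_grid(df)
  check_dt_match(grid, dist)
  p_ev <- role_probs(df, "p_event")
  m <- grid$m
  S <- if (m >= 2) deadtime_survivor_vec(dist, m - 1L) else numeric(0)
  p_det <- numeric(m)
  p_dead <- numeric(m)
  p_det[1] <- p_ev[1]
  if (m >= 2) {
    for (i in 2:m) {
      h <- seq_len(i - 1L)
      p_dead[i] <- sum(p_det[h] * S[i - h])
      p_det[i] <- p_ev[i] * (1 - p_dead[i])
    }
  }
  tibble::tibble(time = df$time, p_event = p_ev, p_detection = p_det,
                 p_dead = p_dead)
}
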