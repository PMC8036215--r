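#' Exhaustive-enumeration oracle for tiny instances
#'
#' Computes the exact expectations of the dead-time-modified process by brute
#' force: every event pattern over the `m` bins is enumerated with its
#' probability, and within each pattern every combination of dead-time draws
#' is enumerated with its PMF weight, applying the same detection rule as
#' [simulate_process()] (ready iff elapsed bins since the last detection
#' `>=` the drawn duration; detector ready at the first bin). Any residual
#' PMF mass beyond the stored support is treated as a dead time longer than
#' the window (exact within the window for distributions truncated at or
#' beyond the window length).
#'
#' This is deliberately independent of the analytic recursions and serves as
#' the reference they are tested against. The cost is roughly
#' `(1 + s)^m` paths, with `s` the dead-time support size; instances beyond
#' about two million paths are refused.
#'
#' @param df Data frame with `time` and an event-probability column.
#' @param dist Dead-time distribution on the same `dt`.
#'
#' @return A list with exact `p_detection`, `p_dead` (per bin), expected
#'   interval-count histograms `iei_counts`, `idi_counts` (durations
#'   `k * dt`), normalized `p_iei`, `p_idi`, and scalars `n_events`,
#'   `n_detections`, `p_zero`, `n_ieis`, `n_idis`.
#' @export
enumeration_oracle <- function(df, dist) {
  grid <- series_grid(df)
  check_dt_match(grid, dist)
  p <- role_probs(df, "p_event")
  m <- grid$m
  support <- which(dist$pmf > 0)
  residual <- 1 - sum(dist$pmf)
  if (residual < 0) residual <- 0
  s_eff <- length(support) + (residual > 1e-15)
  if (m > 12 || length(support) > 4) {
    abort("instance too large for exhaustive enumeration (m <= 12, support <= 4).",
          class = "deadtime_argument")
  }
  if ((1 + s_eff)^m > 2^21) {
    abort("instance too large for exhaustive enumeration (too many paths).",
          class = "deadtime_argument")
  }

  p_det <- numeric(m)
  p_dead <- numeric(m)
  iei <- numeric(max(m - 1L, 0L))
  idi <- numeric(max(m - 1L, 0L))
  p_zero <- 0

  g_pmf <- dist$pmf
  recurse <- function(i, w, last_event, last_det, j_dead) {
    if (w == 0) return(invisible())
    if (i > m) {
      if (last_event == 0L) p_zero <<- p_zero + w
      return(invisible())
    }
    dead <- last_det > 0L && (i - last_det) < j_dead
    if (dead) p_dead[i] <<- p_dead[i] + w
    pe <- p[i]
    # no event this bin
    recurse(i + 1L, w * (1 - pe), last_event, last_det, j_dead)
    if (pe > 0) {
      we <- w * pe
      if (last_event > 0L) iei[i - last_event] <<- iei[i - last_event] + we
      if (!dead) {
        p_det[i] <<- p_det[i] + we
        if (last_det > 0L) idi[i - last_det] <<- idi[i - last_det] + we
        for (j in support) {
          recurse(i + 1L, we * g_pmf[j], i, i, j)
        }
        if (residual > 0) recurse(i + 1L, we * residual, i, i, m + 1L)
      } else {
        recurse(i + 1L, we, i, last_det, j_dead)
      }
    }
    invisible()
  }
  recurse(1L, 1, 0L, 0L, 0L)

  n_events <- sum(p)
  n_detections <- sum(p_det)
  n_ieis <- n_events - 1 + p_zero
  n_idis <- n_detections - 1 + p_zero
  list(
    p_detection = p_det, p_dead = p_dead,
    iei_counts = iei, idi_counts = idi,
    p_iei = if (n_ieis > 1e-12) iei / n_ieis else rep(NA_real_, length(iei)),
    p_idi = if (n_idis > 1e-12) idi / n_idis else rep(NA_real_, length(idi)),
    n_events = n_events, n_detections = n_detections, p_zero = p_zero,
    n_ieis = n_ieis, n_idis = n_idis
  )
}
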