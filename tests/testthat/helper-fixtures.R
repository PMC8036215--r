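# Shared fixtures: the running example process (5-ms window, 0.1-ms bins,
# sinusoid-exponential rate) and the fixed-plus-geometric dead-time
# distribution with d_fixed = mu_rand = 0.5 ms.

DT <- 1e-4

example_grid <- function() time_grid(0, 5e-3, DT)

example_deadtime <- function(dt = DT) deadtime_fixed_geometric(5e-4, 5e-4, dt)

example_rates <- function() sinusoid_exp_rate(example_grid(), 600, 1, 400)

as_event <- function(df) dplyr::rename(df, p_event = "p")
as_detection <- function(df) dplyr::rename(df, p_detection = "p")

# one-bin dead time: never blocks anything (detections == events)
degenerate_deadtime <- function(dt = DT) deadtime_pmf(dt, 1, dt)

# random tiny instance for oracle comparisons; dead-time PMF has full mass
random_tiny_instance <- function(seed) {
  withr::with_seed(seed, {
    m <- sample(5:8, 1)
    grid <- time_grid(0, m * DT, DT)
    p <- stats::runif(m, 0.02, 0.7)
    s <- sample(1:3, 1)
    durations <- sort(sample(1:3, s)) * DT
    probs <- stats::runif(s)
    probs <- probs / sum(probs)
    list(df = tibble::tibble(time = grid$times, p = p),
         dist = deadtime_pmf(durations, probs, DT))
  })
}

run_interval_pipeline <- function(df_event, dist) {
  conv <- event_to_detection(df_event, dist)
  fe <- event_recurrence(conv)
  fd <- detection_recurrence(fe, dist)
  list(conv = conv, f_event = fe, f_detection = fd,
       iei = iei_distribution(conv, fe),
       idi = idi_distribution(conv, fd))
}
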