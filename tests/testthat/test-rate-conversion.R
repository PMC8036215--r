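test_that("dead-state probability is zero at the first bin and hand-checkable", {
  d <- example_deadtime()
  withr::with_seed(5, {
    df <- as_detection(
      rate_to_prob(tibble::tibble(time = example_grid()$times,
                                  rate = stats::runif(50, 0, 700))))
  })
  pd <- dead_probability(df, d)
  expect_equal(pd$p_dead[1], 0)

  # deterministic two-bin dead time: S(dt) = 1, S(2 dt) = 0
  g3 <- time_grid(0, 3e-4, 1e-4)
  det <- tibble::tibble(time = g3$times, p_detection = c(0.5, 0.5, 0.5))
  pd3 <- dead_probability(det, deadtime_pmf(2e-4, 1, 1e-4))
  expect_equal(pd3$p_dead, c(0, 0.5, 0.5))

  # one-bin dead time: survivor vanishes on its whole support
  pd0 <- dead_probability(df, degenerate_deadtime())
  expect_equal(pd0$p_dead, rep(0, 50))
})

test_that("direct and FFT convolution paths agree to 1e-12", {
  d <- example_deadtime()
  conv <- event_to_detection(as_event(example_rates()), d)
  p1 <- dead_probability(conv, d, method = "direct")
  p2 <- dead_probability(conv, d, method = "fft")
  expect_lt(max(abs(p1$p_dead - p2$p_dead)), 1e-12)
})

test_that("detection -> event inversion honors the ready-at-start assumption", {
  d <- example_deadtime()
  # a detection series consistent with the dead-time model: the one the
  # forward conversion of the example event process produces
  det <- event_to_detection(as_event(example_rates()),
                            d)[c("time", "p_detection")]
  out <- detection_to_event(det, d)
  expect_equal(out$p_event[1], out$p_detection[1])
  expect_true(all(out$p_event >= out$p_detection))
  expect_true(all(out$p_event[-1] > out$p_detection[-1]))
  expect_true(all(out$p_event <= 1))

  # one-bin dead time never blocks: identity conversion
  out0 <- detection_to_event(det, degenerate_deadtime())
  expect_equal(out0$p_event, out0$p_detection)
})

test_that("unrecoverable and inconsistent detection series raise errors", {
  g <- time_grid(0, 3e-4, 1e-4)
  two_bin <- deadtime_pmf(2e-4, 1, 1e-4)  # S(dt) = 1: bin after a detection is dead
  sure <- tibble::tibble(time = g$times, p_detection = c(1, 0.3, 0.3))
  expect_error(detection_to_event(sure, two_bin),
               class = "deadtime_unrecoverable")

  big <- tibble::tibble(time = g$times, p_detection = c(0.9, 0.9, 0))
  expect_error(detection_to_event(big, two_bin),
               class = "deadtime_inconsistent")
})

test_that("event <-> detection conversions are mutual inverses", {
  d <- example_deadtime()
  g <- example_grid()
  withr::with_seed(21, {
    for (rep in 1:10) {
      p_ev <- stats::runif(g$m, 0, 0.6)
      fwd <- event_to_detection(
        tibble::tibble(time = g$times, p_event = p_ev), d)
      back <- detection_to_event(fwd[c("time", "p_detection")], d)
      expect_lt(max(abs(back$p_event - p_ev)), 1e-10)
      expect_lt(max(abs(back$p_dead - fwd$p_dead)), 1e-10)
      # and the reverse composition
      fwd2 <- event_to_detection(back[c("time", "p_event")], d)
      expect_lt(max(abs(fwd2$p_detection - fwd$p_detection)), 1e-10)
    }
  })
})

test_that("zero event series converts to zero everything", {
  g <- example_grid()
  out <- event_to_detection(
    tibble::tibble(time = g$times, p_event = rep(0, g$m)),
    example_deadtime())
  expect_equal(out$p_detection, rep(0, g$m))
  expect_equal(out$p_dead, rep(0, g$m))
})

test_that("simulated per-bin frequencies match the analytic series", {
  g <- time_grid(0, 3e-3, 1e-4)  # 30 bins
  d <- example_deadtime()
  conv <- event_to_detection(constant_rate(g, 1000) |> as_event(), d)
  n <- 2e4
  sim <- simulate_process(conv, d, n_runs = n, seed = 99)
  se_ev <- sqrt(conv$p_event * (1 - conv$p_event) / n)
  se_det <- sqrt(conv$p_detection * (1 - conv$p_detection) / n)
  expect_true(all(abs(sim$event_counts / n - conv$p_event) <= 5 * se_ev))
  expect_true(all(abs(sim$detection_counts / n - conv$p_detection) <=
                    5 * se_det))
})
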