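test_that("three-bin homogeneous example matches exhaustive expectations", {
  g <- time_grid(0, 3e-3, 1e-3)
  df <- tibble::tibble(time = g$times, p_event = rep(0.5, 3))
  iei <- iei_distribution(df)
  expect_equal(iei$n_points, 1.5)
  expect_equal(iei$p_zero, 0.125)
  expect_equal(iei$n_intervals, 0.625)
  expect_equal(iei$probs, c(0.8, 0.2), tolerance = 1e-12)
  # mean/sd from the enumerated distribution
  g1 <- glance(iei)
  expect_equal(g1$mean, 1.2e-3, tolerance = 1e-12)
  expect_equal(g1$total_mass, 1, tolerance = 1e-12)
})

test_that("an empty window is rejected as degenerate", {
  g <- time_grid(0, 3e-3, 1e-3)
  df <- tibble::tibble(time = g$times, p_event = rep(0, 3))
  expect_error(iei_distribution(df), class = "deadtime_degenerate_window")
})

test_that("one-bin dead time makes the IDI identical to the IEI", {
  res <- run_interval_pipeline(as_event(example_rates()),
                               degenerate_deadtime())
  expect_equal(res$idi$probs, res$iei$probs, tolerance = 1e-12)
  expect_equal(res$idi$n_points, res$iei$n_points, tolerance = 1e-12)
})

test_that("IEI and IDI distributions are normalized on diverse processes", {
  d <- example_deadtime()
  g <- example_grid()
  processes <- list(
    sinusoid = example_rates(),
    walk = random_walk_rate(g, 600, 75, seed = 8),
    homogeneous = constant_rate(g, 1000)
  )
  for (df in processes) {
    res <- run_interval_pipeline(as_event(df), d)
    expect_equal(sum(res$iei$probs), 1, tolerance = 1e-8)
    expect_equal(sum(res$idi$probs), 1, tolerance = 1e-8)
    expect_true(all(res$iei$probs >= 0))
    expect_true(all(res$idi$probs >= 0))
  }
})

test_that("interval rates are the PMF divided by dt", {
  g <- time_grid(0, 3e-3, 1e-3)
  iei <- iei_distribution(tibble::tibble(time = g$times,
                                         p_event = rep(0.5, 3)))
  rts <- interval_rates(iei)
  expect_equal(rts$rate, c(800, 200))
  expect_equal(rts$rate * 1e-3, rts$probability)  # round trip
  expect_equal(tidy(iei), rts)
})

test_that("summary statistics cover degenerate and uniform shapes", {
  # two-bin window: single possible interval, sd = 0
  g <- time_grid(0, 2e-4, 1e-4)
  one <- iei_distribution(tibble::tibble(time = g$times,
                                         p_event = c(0.5, 0.5)))
  expect_equal(one$probs, 1)
  s <- interval_summary(one)
  expect_equal(s$mean, 1e-4)
  expect_equal(s$sd, 0)
  expect_equal(s$total_mass, 1)
})

test_that("homogeneous IEIs approach the geometric law, censored from above", {
  p <- 0.05
  g <- time_grid(0, 200 * 1e-4, 1e-4)
  iei <- iei_distribution(tibble::tibble(time = g$times,
                                         p_event = rep(p, 200)))
  geom <- p * (1 - p)^(seq_len(199) - 1)
  # early bins agree closely
  expect_equal(iei$probs[1:20], geom[1:20], tolerance = 0.15)
  # right censoring depresses the observed tail below the geometric tail
  expect_true(all(iei$probs[150:199] < geom[150:199]))
})
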