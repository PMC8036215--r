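test_that("event recurrence reproduces its defining product form", {
  g <- example_grid()
  withr::with_seed(31, {
    p <- stats::runif(g$m, 0, 0.8)
  })
  fe <- event_recurrence(tibble::tibble(time = g$times, p = p))
  m <- g$m
  # k = 1 column is the next bin's event probability
  expect_equal(fe$f[cbind(1:(m - 1), 1)], p[2:m])
  # spot-check the full product form
  for (i in c(1L, 10L, 33L)) {
    for (k in c(2L, 5L, m - i)) {
      expect_equal(fe$f[i, k],
                   p[i + k] * prod(1 - p[(i + 1):(i + k - 1)]),
                   tolerance = 1e-12)
    }
  }
  # structural zeros beyond the window edge
  expect_true(all(fe$f[row(fe$f) + col(fe$f) > m] == 0))
})

test_that("homogeneous and certain-event processes give closed-form rows", {
  g <- time_grid(0, 2e-3, 1e-4)
  m <- g$m
  fe <- event_recurrence(tibble::tibble(time = g$times, p = rep(0.1, m)))
  for (i in c(1L, 7L, 15L)) {
    k <- seq_len(m - i)
    expect_equal(fe$f[i, k], 0.1 * 0.9^(k - 1), tolerance = 1e-12)
  }

  f1 <- event_recurrence(tibble::tibble(time = g$times, p = rep(1, m)))
  expect_equal(f1$f[, 1], rep(1, m - 1))
  expect_true(all(f1$f[, -1] == 0))
})

test_that("row sums equal the probability of another event in the window", {
  g <- example_grid()
  withr::with_seed(32, p <- stats::runif(g$m, 0, 0.6))
  fe <- event_recurrence(tibble::tibble(time = g$times, p = p))
  m <- g$m
  for (i in seq_len(m - 1)) {
    expect_equal(sum(fe$f[i, ]), 1 - prod(1 - p[(i + 1):m]),
                 tolerance = 1e-10)
  }
  expect_true(all(rowSums(fe$f) <= 1 + 1e-9))
})

test_that("detection recurrence collapses correctly for degenerate dead times", {
  rates <- example_rates()
  fe <- event_recurrence(rates)
  # one-bin dead time: only the j = 1 term survives with weight 1
  fd0 <- detection_recurrence(fe, degenerate_deadtime())
  expect_equal(fd0$f, fe$f)

  # deterministic dead time j* = 3: a single shifted term
  jstar <- 3L
  fd3 <- detection_recurrence(fe, deadtime_pmf(jstar * DT, 1, DT))
  mm1 <- nrow(fe$f)
  expect_true(all(fd3$f[, seq_len(jstar - 1)] == 0))
  for (i in c(1L, 10L, 30L)) {
    for (k in jstar:(mm1 - i + 1)) {
      if (i + jstar - 1 <= mm1) {
        expect_equal(fd3$f[i, k], fe$f[i + jstar - 1, k - jstar + 1])
      }
    }
  }
})

test_that("waiting times within the fixed dead-time portion are impossible", {
  d <- example_deadtime()  # d_fixed = 0.5 ms = 5 bins
  fd <- detection_recurrence(event_recurrence(example_rates()), d)
  expect_true(all(fd$f[, 1:5] == 0))
  expect_true(any(fd$f[, 6] > 0))
})

test_that("periodic duplication equals the full computation bit for bit", {
  rates <- example_rates()  # f = 400 Hz on a 5-ms window: period 25 bins
  fe_full <- event_recurrence(rates)
  fe_per <- periodic_recurrence(rates, 25)
  expect_identical(fe_per$f, fe_full$f)

  # rows one period apart agree on overlapping waiting times
  expect_identical(fe_per$f[26, 1:24], fe_per$f[1, 1:24])

  # one-cycle declaration is trivially the full computation
  fe_one <- periodic_recurrence(rates, 50)
  expect_identical(fe_one$f, fe_full$f)

  # with a dead-time distribution the duplicated matrix feeds the
  # detection-recurrence convolution unchanged
  d <- example_deadtime()
  expect_identical(periodic_recurrence(rates, 25, dist = d)$f,
                   detection_recurrence(fe_full, d)$f)
})

test_that("periodicity is validated", {
  withr::with_seed(33, {
    g <- example_grid()
    rnd <- tibble::tibble(time = g$times, p = stats::runif(g$m, 0, 0.5))
  })
  expect_error(periodic_recurrence(rnd, 25),
               class = "deadtime_not_periodic")
  expect_error(periodic_recurrence(example_rates(), 24),
               class = "deadtime_argument")  # does not divide window
})

test_that("entries depend only on bins up to i + k (monotone censoring)", {
  g <- example_grid()
  withr::with_seed(34, p <- stats::runif(g$m, 0, 0.6))
  full <- event_recurrence(tibble::tibble(time = g$times, p = p))
  mshort <- 30L
  short <- event_recurrence(
    tibble::tibble(time = g$times[1:mshort], p = p[1:mshort]))
  for (i in seq_len(mshort - 1)) {
    k <- seq_len(mshort - i)
    expect_identical(short$f[i, k], full$f[i, k])
  }
})
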