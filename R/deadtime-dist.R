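#' Dead-time distributions on the time grid
#'
#' After every detection the detector is dead for a random duration
#' `d_dead`, during which further events go undetected (nonparalyzable: an
#' undetected event does not prolong the dead time). Durations live on the
#' same grid as the observation window: `d_j = j * dt`, `j = 1, 2, ...`.
#'
#' `deadtime_fixed_geometric()` builds the fixed-plus-geometric family
#' `d_dead = d_fixed + d_rand`, where `d_rand` is geometric with mean
#' `mu_rand` (success probability `dt / mu_rand` per bin) — the discrete
#' analogue of a fixed-plus-exponential refractory period. Its CDF is
#' `G(d_j) = 1 - (1 - dt/mu_rand)^((d_j - d_fixed)/dt)` for
#' `d_j >= d_fixed` and 0 below; the PMF is strictly 0 for
#' `d_j <= d_fixed`, so the shortest possible dead time is `d_fixed + dt`.
#'
#' `deadtime_pmf()` builds a dead-time distribution from an arbitrary PMF on
#' the grid. Total mass may be at most 1 (+1e-9 for rounding, in which case
#' it is renormalized to exactly 1); mass below 1 represents a truncated
#' distribution.
#'
#' The stored support is truncated where the survivor function drops below
#' 1e-12 (or at `d_max` if given); the algorithms that consume the
#' distribution extend the geometric family analytically beyond the stored
#' support, so truncation never affects the numerical method.
#'
#' @param d_fixed Fixed portion of the dead time, seconds; must be a
#'   non-negative integer multiple of `dt`.
#' @param mu_rand Mean of the geometric portion, seconds; must be `>= dt`.
#' @param dt Bin width in seconds.
#' @param d_max Optional truncation point for the stored support, seconds;
#'   must be `>= d_fixed + dt`.
#' @param durations,probs For `deadtime_pmf()`: dead-time durations (positive
#'   integer multiples of `dt`) and their probabilities.
#'
#' @return An object of class `deadtime_dist` with fields `dt`, `durations`,
#'   `pmf`, `cdf`, `survivor`, `mean`, `family`, `params`.
#' @examples
#' d <- deadtime_fixed_geometric(5e-4, 5e-4, 1e-4)
#' mean_dead_time(d)       # 1e-3 s
#' tidy(d)
#' @export
deadtime_fixed_geometric <- function(d_fixed, mu_rand, dt, d_max = NULL) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    abort("`dt` must be a single positive number.", class = "deadtime_argument")
  }
  if (!is.numeric(mu_rand) || length(mu_rand) != 1L || mu_rand < dt) {
    abort("`mu_rand` must be >= dt (per-bin success probability <= 1).",
          class = "deadtime_argument")
  }
  if (!is.numeric(d_fixed) || length(d_fixed) != 1L || d_fixed < 0) {
    abort("`d_fixed` must be a single non-negative number.",
          class = "deadtime_argument")
  }
  j_fix_real <- d_fixed / dt
  j_fix <- round(j_fix_real)
  if (abs(j_fix_real - j_fix) > 1e-9 * max(1, j_fix_real)) {
    abort("grid mismatch: `d_fixed` is not an integer multiple of `dt`.",
          class = "deadtime_grid_mismatch")
  }
  q <- dt / mu_rand
  if (!is.null(d_max)) {
    if (d_max < d_fixed + dt - 1e-9 * dt) {
      abort("`d_max` must be at least d_fixed + dt.",
            class = "deadtime_argument")
    }
    J <- as.integer(round(d_max / dt))
  } else {
    # smallest n with (1-q)^n < 1e-12 beyond the fixed portion
    n_tail <- if (q >= 1) 1L else as.integer(ceiling(log(1e-12) / log1p(-q)))
    J <- j_fix + max(1L, n_tail)
  }
  j <- seq_len(J)
  pmf <- ifelse(j > j_fix, q * (1 - q)^(j - j_fix - 1L), 0)
  surv <- ifelse(j >= j_fix, (1 - q)^(j - j_fix), 1)
  new_deadtime_dist(
    dt = dt, pmf = pmf, cdf = 1 - surv, survivor = surv,
    mean = d_fixed + mu_rand,
    family = "fixed_plus_geometric",
    params = list(d_fixed = j_fix * dt, mu_rand = mu_rand)
  )
}

#' @rdname deadtime_fixed_geometric
#' @export
deadtime_pmf <- function(durations, probs, dt) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    abort("`dt` must be a single positive number.", class = "deadtime_argument")
  }
  if (length(durations) != length(probs) || length(durations) == 0L) {
    abort("`durations` and `probs` must be non-empty and the same length.",
          class = "deadtime_argument")
  }
  if (any(probs < 0)) {
    abort("dead-time probabilities must be non-negative.",
          class = "deadtime_argument")
  }
  total <- sum(probs)
  if (total > 1 + 1e-9) {
    abort(sprintf("dead-time PMF mass %.12g exceeds 1.", total),
          class = "deadtime_argument")
  }
  if (total > 1) probs <- probs / total
  j_real <- durations / dt
  j <- round(j_real)
  if (any(j < 1) || any(abs(j_real - j) > 1e-9 * pmax(1, j_real))) {
    abort("grid mismatch: durations must be positive integer multiples of `dt`.",
          class = "deadtime_grid_mismatch")
  }
  if (anyDuplicated(j)) {
    abort("duplicated durations in dead-time PMF.", class = "deadtime_argument")
  }
  J <- max(j)
  pmf <- numeric(J)
  pmf[j] <- probs
  cdf <- cumsum(pmf)
  new_deadtime_dist(
    dt = dt, pmf = pmf, cdf = cdf, survivor = 1 - cdf,
    mean = sum(seq_len(J) * dt * pmf),
    family = "pmf", params = list()
  )
}

new_deadtime_dist <- function(dt, pmf, cdf, survivor, mean, family, params) {
  structure(
    list(dt = dt, durations = seq_along(pmf) * dt, pmf = pmf, cdf = cdf,
         survivor = survivor, mean = mean, family = family, params = params),
    class = "deadtime_dist"
  )
}

#' Mean dead time
#'
#' For the fixed-plus-geometric family this is the analytic mean
#' `d_fixed + mu_rand` (the geometric portion has mean exactly `mu_rand`);
#' for arbitrary PMFs it is the truncated sum `sum(d_j * pmf[j])`.
#'
#' @param dist A [deadtime_fixed_geometric()] / [deadtime_pmf()] object.
#' @return Mean dead-time duration in seconds.
#' @export
mean_dead_time <- function(dist) {
  stopifnot(inherits(dist, "deadtime_dist"))
  dist$mean
}

# Survivor function S(d_j) evaluated for j = 1..n, extending beyond the
# stored support: analytically for the geometric family, by the residual
# mass (constant) for arbitrary PMFs.
deadtime_survivor_vec <- function(dist, n) {
  J <- length(dist$pmf)
  if (n <= J) return(dist$survivor[seq_len(n)])
  if (dist$family == "fixed_plus_geometric") {
    q <- dist$dt / dist$params$mu_rand
    j_fix <- round(dist$params$d_fixed / dist$dt)
    j <- seq_len(n)
    ifelse(j >= j_fix, (1 - q)^(j - j_fix), 1)
  } else {
    c(dist$survivor, rep(dist$survivor[J], n - J))
  }
}

# PMF g(d_j) for j = 1..n, analytic beyond stored support for the geometric
# family, zero-padded otherwise.
deadtime_pmf_vec <- function(dist, n) {
  J <- length(dist$pmf)
  if (n <= J) return(dist$pmf[seq_len(n)])
  if (dist$family == "fixed_plus_geometric") {
    q <- dist$dt / dist$params$mu_rand
    j_fix <- round(dist$params$d_fixed / dist$dt)
    j <- seq_len(n)
    ifelse(j > j_fix, q * (1 - q)^(j - j_fix - 1L), 0)
  } else {
    c(dist$pmf, numeric(n - J))
  }
}

#' @export
print.deadtime_dist <- function(x, ...) {
  cat(sprintf(
    "<deadtime_dist> %s, dt = %g s, support %g..%g s, mean = %g s\n",
    x$family, x$dt, x$durations[1], x$durations[length(x$durations)], x$mean))
  if (x$family == "fixed_plus_geometric") {
    cat(sprintf("  d_fixed = %g s, mu_rand = %g s\n",
                x$params$d_fixed, x$params$mu_rand))
  }
  invisible(x)
}

#' @describeIn deadtime_fixed_geometric Tidy the distribution into a tibble
#'   with columns `duration`, `pmf`, `cdf`, `survivor`.
#' @param x A `deadtime_dist`.
#' @param ... Unused.
#' @export
tidy.deadtime_dist <- function(x, ...) {
  tibble::tibble(duration = x$durations, pmf = x$pmf, cdf = x$cdf,
                 survivor = x$survivor)
}
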