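---
title: "Computing dead-time-modified interval distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing dead-time-modified interval distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deadtime)
```

## The model

The package works with two coupled point processes on a finite observation
window `[t_min, t_max]`: an inhomogeneous Poisson *event* process with rate
`R_event(t)`, and the *detection* process obtained by passing its events
through a nonparalyzable detector. Each detection triggers an independent
random dead time `d_dead`; events arriving while the elapsed time since the
last detection is smaller than that dead time go undetected, and an
undetected event never prolongs the dead time. Three assumptions are
load-bearing:

* the window is observed in discrete bins of width `Δt`, small enough that
  each bin holds at most one event in practice (per-bin probability
  `p = R·Δt` must not exceed 1, and for sinusoidal rates we follow the rule
  of thumb `Δt ≤ 1/(200·f)`);
* the detector is **ready at the window start** (`p_dead(t_1) = 0`): the
  process either begins with the window or is negligibly active before it;
* dead times are i.i.d. draws from one distribution, so the detection
  process is an ordinary or inhomogeneous *renewal* process. Nonrenewal
  processes, paralyzable detectors and equilibrium (possibly-dead-at-start)
  conditions are out of scope.

Bins are labeled by their right edges, `t_i = t_min + i·Δt` (1-based,
`t_m = t_max`); dead-time durations `d_j = j·Δt` and waiting times
`w_k = k·Δt` live on the same grid. This single convention is used
everywhere — public APIs speak in physical seconds, and all index algebra
in the recursions is done on this labeling, which is what keeps the three
convolution-style formulas below free of off-by-one drift.

## Dead-time distributions

`deadtime_fixed_geometric(d_fixed, mu_rand, dt)` implements the
fixed-plus-geometric family `d_dead = d_fixed + d_rand`, the discrete
analogue of the fixed-plus-exponential refractory period: the geometric
portion has per-bin success probability `Δt/μ_rand` (hence the requirement
`μ_rand ≥ Δt`), its PMF is strictly zero for `d_j ≤ d_fixed`, and the
shortest realizable dead time is `d_fixed + Δt`. The analytic mean is
exactly `d_fixed + μ_rand`. As `Δt → 0` the PMF over `Δt` converges to the
shifted-exponential density; the test suite checks the sup-norm error
decreases over `Δt ∈ {0.1, 0.05, 0.025}` ms.

The stored support is truncated where the survivor function falls below
1e-12. The truncation is purely representational: the conversion and
recurrence algorithms request survivor/PMF values through accessors that
extend the geometric family *analytically* to any length (and pad arbitrary
PMFs with their residual mass), so no algorithmic quantity depends on the
truncation point. `deadtime_pmf()` accepts any PMF on the grid with total
mass ≤ 1; mass may be left below 1 to represent distributions truncated
elsewhere.

## The four steps

**Dead-state probability and rate conversion.** The probability that the
detector is dead at `t_i` is
`p_dead(t_i) = Σ_{h=1}^{i−1} p_detection(t_h)·S_dead(d_{i−h})`, a linear
convolution of the detection series with the survivor function (the events
"last detection at `t_h` with a dead time covering `t_i`" are mutually
exclusive, so the sum is itself a probability). Two execution paths are
provided — the triangular direct sum and FFT-based convolution
(`stats::convolve`, zero-padded; circular wraparound would be wrong here) —
and they agree to 1e-12; the FFT path exists because the direct sum is the
`O(m²)` part of the conversion. `p_detection = p_event·(1 − p_dead)`
closes the system. Going from a known detection series to the event series
divides instead, and fails with an explicit error where `p_dead` reaches 1
(a bin inside the fixed portion of a dead time following a certain
detection: the event probability there is genuinely unrecoverable; we
error rather than clip, with a 1e-9 guard band before the division).
Going from a known event series forward, `p_dead(t_i)` needs the detection
probabilities of all earlier bins while `p_detection(t_i)` needs
`p_dead(t_i)`, so the two are computed interleaved, bin by bin. Both
directions are first-class and are exact mutual inverses (tested to
1e-10), because the method needs both series regardless of which was
supplied.

**Recurrence to the next event.** `f_event(t_i, w_k)` multiplies the
probability of an event at `t_{i+k}` by the running product of
no-event probabilities in between. The products are computed by per-row
`cumprod`, not in log space: all quantities here are bounded well away
from underflow at realistic rates, and `cumprod` keeps the arithmetic
identical between the full and the periodic code paths (below). Entries
whose waiting time would leave the window are simply not represented —
the distributions are intentionally incomplete, which is how right
censoring enters every downstream quantity. Storage is a dense
`(m−1)×(m−1)` upper-left-justified matrix with structural zeros, which
makes step 4 a plain vector–matrix product.

**Recurrence to the next detection.** Conditional on a detection at `t_i`
with drawn dead time `d_j`, detection is impossible at elapsed times
`< d_j` and resumes with the event recurrence from the last blocked bin:
`f_detection(t_i, w_k) = Σ_{j=1}^{k} g_dead(d_j)·f_event(t_{i+j−1}, w_{k−j+1})`.
The `i+j−1` / `k−j+1` indexing encodes the convention that an event
arriving at elapsed time exactly `d_j` *is* detected ("ready at elapsed ≥
drawn dead time"); the simulator and the enumeration oracle implement the
identical convention, and the steady-state benchmark below is sensitive to
it, so the three implementations cross-validate the choice. The sum is
evaluated as one shifted-submatrix update per support point of `g_dead`
(`O(J·m²)` rather than the naive `O(m³)`).

**Interval distributions.** The expected number of intervals of length
`w_k` per window is the weighted column sum of the recurrence matrix;
dividing by `n_intervals = n_points − 1 + p_zero` yields a PMF. The
`+ p_zero` term (probability of a completely empty window,
`Π(1 − p_event)`; by the ready-at-start assumption zero detections occur
iff zero events occur) accounts for windows that contribute zero rather
than minus one intervals. The identity "numerator total = expected
interval count" holds algebraically; the implementation asserts it to
1e-10 before dividing and refuses windows whose expected interval count is
below 1e-12 (a ratio of two near-zero expectations carries no
information). No censoring correction is ever applied: reproducing the
censored distribution is the point. Rates are obtained by dividing the
PMF by `Δt`.

## Periodic rates

For a rate that is periodic on the grid with period `P` bins, the
recurrence row at `t_{i+P}` equals the row at `t_i` truncated harder by
the window edge, so only the first cycle's rows are computed and the rest
are copied. Because copied rows reuse the identical floating-point
results, the shortcut is bit-identical to the full computation — the test
suite compares with `identical()`. To make grid periodicity itself exact,
`sinusoid_exp_rate()` folds bin indices into the first cycle whenever the
declared frequency yields an integer period in bins (evaluating
`sin(2πf·t_i)` naively differs across cycles in the last ulp).
`periodic_recurrence()` validates the declared period (divisor of the
window length; series repeats to 1e-12 relative) and errors otherwise.

## The simulator and the oracle

The Monte-Carlo simulator (`simulate_process()`, C++ core) draws each
bin's event as an independent Bernoulli variable, applies the same
ready-at-elapsed-`≥ d` rule, and samples dead times by inverse CDF on the
stored PMF — the geometric family is deliberately *not* special-cased, so
the simulator independently checks the closed-form CDF/PMF expressions.
Each run has its own counter-based RNG stream keyed by `(seed, run)`
(splitmix64), so run `r` is the same random experiment no matter how many
runs are requested, results are reproducible from the seed alone, and R's
global RNG state is untouched.

The enumeration oracle (`enumeration_oracle()`) computes *exact*
expectations for tiny instances (`m ≤ 12`, dead-time support ≤ 4, path
budget ~2e6) by summing over every event pattern and every dead-time draw
with the same detection rule. The strongest correctness property in the
test suite is that the full analytic pipeline matches the oracle to 1e-10
on dozens of randomized instances — the oracle shares no code with the
recursions it checks.

**Agreement statistics.** To operationalize "the numerical and simulated
distributions agree", we compare per-bin z-scores
`(p_emp − p_num)/√(p_num(1 − p_num)/n)` and the total-variation distance,
passing at `max|z| ≤ 5` and `TV ≤ 0.01` with `n = 1e5` runs. A raw per-bin
z is statistically meaningless in far-tail bins whose expected count is a
small fraction of one — a single stray count there produces an arbitrarily
large |z| with non-negligible probability even for an exact method — so,
following the standard chi-square rule of thumb, per-bin z-scores are
evaluated only where the expected count is at least 5 and all remaining
bins are pooled into one aggregate z. The thresholds are this package's
own calibration of visual closeness, not an external standard.

## Study conditions and problem sizes

The defaults used throughout the examples and tests are: `Δt = 0.1` ms;
sinusoid-exponential rate with `A = 600` events/s, `B = 1`, `f = 400` Hz
on a 5-ms window (two full cycles, period 25 bins); random-walk rate
starting at 600 events/s with uniform steps on ±75 events/s on the same
5-ms grid (negative excursions clipped at 0; the examples stay positive,
and a strict mode errors instead); homogeneous benchmark at 1000 events/s;
dead times with `d_fixed = μ_rand = 0.5` ms (mean 1 ms). The homogeneous
benchmark uses a 30-ms window for the steady-state rate (the transient
decays on the ~2-ms scale of the mean inter-detection interval, so the
final 5 ms are fully settled) and a 100-ms window for interval-mean
computations (censoring bias ~1%); simulation checks use 1e5 runs, which
puts the Monte-Carlo TV noise comfortably under the 0.01 criterion.

For the homogeneous benchmark the detection process is a renewal process
whose steady-state rate is the inverse of its mean inter-detection
interval. With per-bin event probability `p`, an interval decomposes into
the dead time (mean `d_fixed + μ_rand` = 1 ms) plus the wait from the end
of the dead time to the next event; because an event landing exactly at
the end of the dead time is detected, that conditional wait has mean
`(1/p − 1)·Δt` = 0.9 ms. Hence 1/(1.9 ms) ≈ 526.3 detections/s, which the
conversion recursion reproduces to four significant figures. Note the
distinction between that conditional wait and the mean of the IEI
*distribution* itself: consecutive events in adjacent bins are one bin
apart, so the uncensored IEI mean is `Δt/p` = 1.0 ms, and the censored
mean over a 100-ms window computed by the pipeline is 0.991 ms. The two
0.9-ish quantities are easily conflated; the package always reports the
distribution mean.

## Degenerate inputs and numerical guards

* grid construction requires an integer bin count (relative tolerance
  1e-9, chosen for float arguments like `5e-3/1e-4`);
* `rate·Δt > 1` anywhere is a probability-overflow error, never a clip;
* a detection series implying `p_dead > 1` or `p_event > 1` is rejected as
  inconsistent with the dead-time model;
* an all-zero (or single-possible-point) window is a degenerate-window
  error rather than a silent zero distribution;
* a one-bin dead time (`d = Δt` with probability 1) never blocks anything
  and collapses the whole pipeline to the pure event process — used as an
  internal consistency check (IDI ≡ IEI).

## Limitations

The method is one-directional (rates → intervals; interval distributions
do not identify the rate function), discrete-time (results converge to the
continuous-time answer as `Δt → 0`, at `O(m²)`–`O(J·m²)` cost growth), and
restricted to the ready-at-start, nonparalyzable, renewal setting. The
synthetic generators emulate stationary-parameter laboratory conditions:
real spike trains with slow rate drift across repetitions, history effects
beyond one dead time, or detector paralysis are outside what a passing
test suite here can certify.
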