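#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Self-contained counter-based RNG: each run gets its own splitmix64 stream
// keyed by (seed, run), so run r's draws do not depend on n_runs and results
// are reproducible independently of R's global RNG state.
static inline uint64_t splitmix64_next(uint64_t &x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline double u01(uint64_t &state) {
  // 53-bit uniform in [0, 1)
  return (splitmix64_next(state) >> 11) * (1.0 / 9007199254740992.0);
}

// One Bernoulli event draw per bin; a detection occurs iff the event falls
// while the detector is ready: (i - last_det) >= j_dead (bins). Each
// detection draws a fresh dead time by inverse CDF on the stored PMF
// (renormalized by its total mass). Undetected events never extend a dead
// time (nonparalyzable).
// [[Rcpp::export]]
List sim_deadtime_cpp(NumericVector p, NumericVector cdf, int n_runs,
                      double seed) {
  const int m = p.size();
  const int J = cdf.size();
  const double total = J > 0 ? cdf[J - 1] : 0.0;
  NumericVector event_counts(m), detection_counts(m);
  NumericVector iei_hist(std::max(m - 1, 0)), idi_hist(std::max(m - 1, 0));
  double zero_event_runs = 0.0;
  const uint64_t seed_u = (uint64_t)((int64_t)seed);

  for (int r = 0; r < n_runs; ++r) {
    uint64_t key = seed_u ^ (0xD2B74407B1CE6E93ULL * (uint64_t)(r + 1));
    uint64_t state = key;
    splitmix64_next(state); // decorrelate nearby keys
    int last_event = 0, last_det = 0, j_dead = 0;
    bool any_event = false;
    for (int i = 1; i <= m; ++i) {
      if (u01(state) < p[i - 1]) {
        any_event = true;
        event_counts[i - 1] += 1.0;
        if (last_event > 0) iei_hist[i - last_event - 1] += 1.0;
        last_event = i;
        if (last_det == 0 || (i - last_det) >= j_dead) {
          detection_counts[i - 1] += 1.0;
          if (last_det > 0) idi_hist[i - last_det - 1] += 1.0;
          last_det = i;
          // inverse-CDF draw of the dead-time duration (in bins)
          double u = u01(state) * total;
          int lo = 0, hi = J - 1;
          while (lo < hi) {
            int mid = (lo + hi) / 2;
            if (cdf[mid] >= u) hi = mid; else lo = mid + 1;
          }
          j_dead = lo + 1;
        }
      }
    }
    if (!any_event) zero_event_runs += 1.0;
  }

  return List::create(
    _["event_counts"] = event_counts,
    _["detection_counts"] = detection_counts,
    _["iei_hist"] = iei_hist,
    _["idi_hist"] = idi_hist,
    _["zero_event_runs"] = zero_event_runs);
}
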