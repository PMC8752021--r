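#ifndef EVOXPLORE_SAMPLING_H
#define EVOXPLORE_SAMPLING_H

#include <Rcpp.h>
#include <cmath>

// Exact binomial sampling by CDF inversion on R's uniform stream.
// One uniform per call; O(1) for the zero outcome, which dominates when
// n*p is small (the usual case for per-step event probabilities).
static inline int rbinom_inv(int n, double p) {
  if (n <= 0 || p <= 0.0) return 0;
  if (p >= 1.0) return n;
  double q = 1.0 - p;
  double pmf = std::pow(q, (double)n);
  double u = unif_rand();
  if (pmf > 0.0) {
    if (u < pmf) return 0;
    double cdf = pmf;
    double ratio = p / q;
    for (int k = 0; k < n; ++k) {
      pmf *= ratio * (double)(n - k) / (double)(k + 1);
      cdf += pmf;
      if (u < cdf) return k + 1;
    }
    return n;
  }
  // (1-p)^n underflowed: fall back to R's sampler (consumes its own draws)
  return (int)R::rbinom((double)n, p);
}

// uniform integer in [0, n)
static inline int rand_index(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

#endif
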