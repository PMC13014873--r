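#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Online Kohonen training: winner-take-all with a Gaussian neighbourhood
// whose learning rate and radius decay linearly over the presentation
// schedule. The presentation order and the initial weights are generated
// in R (under the caller's seed), so training is deterministic here.
// Samples and weights are handled feature-major (one contiguous block
// per sample/neuron) for cache efficiency.
// [[Rcpp::export]]
NumericMatrix cpp_som_train(NumericMatrix X, NumericMatrix W0,
                            IntegerVector order, NumericMatrix coords,
                            double alpha0, double alpha1,
                            double radius0, double radius1) {
  const int n = X.nrow(), p = X.ncol(), m = W0.nrow();
  std::vector<double> xt((size_t)n * p), wt((size_t)m * p);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) xt[(size_t)i * p + j] = X(i, j);
  for (int k = 0; k < m; ++k)
    for (int j = 0; j < p; ++j) wt[(size_t)k * p + j] = W0(k, j);

  const int steps = order.size();
  for (int t = 0; t < steps; ++t) {
    const double* x = &xt[(size_t)(order[t] - 1) * p];
    const double frac = steps > 1 ? (double)t / (steps - 1) : 0.0;
    const double alpha = alpha0 + (alpha1 - alpha0) * frac;
    double radius = radius0 + (radius1 - radius0) * frac;
    if (radius < 1e-8) radius = 1e-8;
    int best = 0;
    double bestd = R_PosInf;
    for (int k = 0; k < m; ++k) {
      const double* w = &wt[(size_t)k * p];
      double d = 0;
      for (int j = 0; j < p; ++j) {
        const double diff = w[j] - x[j];
        d += diff * diff;
        if (d >= bestd) break;
      }
      if (d < bestd) { bestd = d; best = k; }
    }
    const double bx = coords(best, 0), by = coords(best, 1);
    const double two_r2 = 2.0 * radius * radius;
    for (int k = 0; k < m; ++k) {
      const double dx = coords(k, 0) - bx, dy = coords(k, 1) - by;
      const double h = std::exp(-(dx * dx + dy * dy) / two_r2);
      if (h < 1e-4) continue;
      const double ah = alpha * h;
      double* w = &wt[(size_t)k * p];
      for (int j = 0; j < p; ++j)
        w[j] += ah * (x[j] - w[j]);
    }
  }
  NumericMatrix W(m, p);
  for (int k = 0; k < m; ++k)
    for (int j = 0; j < p; ++j) W(k, j) = wt[(size_t)k * p + j];
  return W;
}

// Squared-Euclidean best-matching unit per row of X over the given neuron
// subset (1-based indices into W). Returns 1-based indices into `subset`.
// [[Rcpp::export]]
IntegerVector cpp_som_bmu(NumericMatrix X, NumericMatrix W,
                          IntegerVector subset) {
  const int n = X.nrow(), p = X.ncol(), m = subset.size();
  std::vector<double> xt((size_t)n * p), wt((size_t)m * p);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) xt[(size_t)i * p + j] = X(i, j);
  for (int s = 0; s < m; ++s)
    for (int j = 0; j < p; ++j) wt[(size_t)s * p + j] = W(subset[s] - 1, j);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const double* x = &xt[(size_t)i * p];
    int best = 0;
    double bestd = R_PosInf;
    for (int s = 0; s < m; ++s) {
      const double* w = &wt[(size_t)s * p];
      double d = 0;
      for (int j = 0; j < p; ++j) {
        const double diff = w[j] - x[j];
        d += diff * diff;
        if (d >= bestd) break;
      }
      if (d < bestd) { bestd = d; best = s; }
    }
    out[i] = best + 1;
  }
  return out;
}
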