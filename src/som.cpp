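#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Online Kohonen training on a 1-D chain of M neurons.
//
// data    : N x D input rows (temporal order irrelevant here; `order` rules)
// weights : M x D initial weight vectors
// order   : epochs x N matrix of 1-based row indices (the presentation order,
//           drawn in R so all randomness stays in R's RNG)
// cosine  : winner matching metric; updates are the additive Kohonen rule
//           either way
// Learning rate and neighborhood radius decay exponentially from their
// initial to final values over the total number of presentation steps.
// [[Rcpp::export]]
NumericMatrix som_train_cpp(const NumericMatrix& data,
                            const NumericMatrix& weights,
                            const IntegerMatrix& order,
                            bool cosine,
                            double lr0, double lr_final,
                            double sigma0, double sigma_final) {
  const int N = data.nrow(), D = data.ncol(), M = weights.nrow();
  const int E = order.nrow();
  NumericMatrix W = clone(weights);
  if (E == 0 || N == 0) return W;

  const R_xlen_t total = (R_xlen_t)E * N;
  std::vector<double> f(D);
  R_xlen_t t = 0;

  for (int e = 0; e < E; ++e) {
    for (int i = 0; i < N; ++i, ++t) {
      const int j = order(e, i) - 1;
      double nf = 0.0;
      for (int d = 0; d < D; ++d) { f[d] = data(j, d); nf += f[d] * f[d]; }

      // winner search; strict '<' keeps the lowest index on ties
      int b = 0;
      double best = R_PosInf;
      for (int m = 0; m < M; ++m) {
        double dist;
        if (cosine) {
          double dot = 0.0, nw = 0.0;
          for (int d = 0; d < D; ++d) {
            dot += f[d] * W(m, d);
            nw += W(m, d) * W(m, d);
          }
          dist = (nw > 0.0 && nf > 0.0) ? 1.0 - dot / std::sqrt(nf * nw)
                                        : R_PosInf;
        } else {
          double s = 0.0;
          for (int d = 0; d < D; ++d) {
            const double diff = f[d] - W(m, d);
            s += diff * diff;
          }
          dist = s; // squared: same argmin
        }
        if (dist < best) { best = dist; b = m; }
      }

      const double frac = (total > 1) ? (double)t / (double)(total - 1) : 0.0;
      const double alpha = lr0 * std::pow(lr_final / lr0, frac);
      const double sigma = sigma0 * std::pow(sigma_final / sigma0, frac);

      for (int m = 0; m < M; ++m) {
        const double dm = (double)(m - b);
        const double a = alpha * std::exp(-(dm * dm) / (2.0 * sigma * sigma));
        if (a < 1e-12) continue;
        for (int d = 0; d < D; ++d) W(m, d) += a * (f[d] - W(m, d));
      }
    }
  }
  return W;
}
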