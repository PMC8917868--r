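#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sequential Kohonen update over one full training schedule.
//
// data:    n x d training rows (already preprocessed)
// weights: u x d initial unit weights (modified copy returned)
// order:   0-based row indices, one entry per presentation, concatenated
//          over epochs (length = total presentations)
// hx, hy:  cube-coordinate components of each unit on the hexagonal
//          lattice (z = -x-y implied); lattice distance between units is
//          (|dx| + |dy| + |dz|) / 2
// alpha0, sigma0, lambda: learning-rate / neighbourhood schedule
//   alpha(t) = alpha0 * exp(-t/lambda)
//   sigma(t) = max(sigma0 * exp(-t/lambda), sigma_min)
// [[Rcpp::export(name = ".som_train_cpp")]]
NumericMatrix som_train_cpp(const NumericMatrix& data,
                            NumericMatrix weights,
                            const IntegerVector& order,
                            const NumericVector& hx,
                            const NumericVector& hy,
                            double alpha0, double sigma0, double lambda,
                            double sigma_min) {
  const int d = data.ncol();
  const int u = weights.nrow();
  const int total = order.size();
  NumericMatrix w = clone(weights);

  for (int t = 0; t < total; ++t) {
    const int row = order[t];
    // winning unit: smallest Euclidean distance in experiment space
    int win = 0;
    double best = R_PosInf;
    for (int j = 0; j < u; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = data(row, k) - w(j, k);
        s += diff * diff;
      }
      if (s < best) { best = s; win = j; }
    }
    const double decay = std::exp(-(double)t / lambda);
    const double alpha = alpha0 * decay;
    double sigma = sigma0 * decay;
    if (sigma < sigma_min) sigma = sigma_min;
    const double denom = 2.0 * sigma * sigma;
    const double wx = hx[win], wy = hy[win];
    for (int j = 0; j < u; ++j) {
      const double dx = std::fabs(hx[j] - wx);
      const double dy = std::fabs(hy[j] - wy);
      const double dz = std::fabs((-hx[j] - hy[j]) - (-wx - wy));
      const double ld = 0.5 * (dx + dy + dz);
      const double h = alpha * std::exp(-(ld * ld) / denom);
      if (h < 1e-12) continue;
      for (int k = 0; k < d; ++k)
        w(j, k) += h * (data(row, k) - w(j, k));
    }
  }
  return w;
}

// Best-matching unit (0-based) and distance for each data row; ties broken
// by lowest unit index.
// [[Rcpp::export(name = ".som_bmu_cpp")]]
List som_bmu_cpp(const NumericMatrix& data, const NumericMatrix& weights) {
  const int n = data.nrow(), u = weights.nrow(), d = data.ncol();
  IntegerVector bmu(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    int win = 0;
    double best = R_PosInf;
    for (int j = 0; j < u; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = data(i, k) - weights(j, k);
        s += diff * diff;
      }
      if (s < best) { best = s; win = j; }
    }
    bmu[i] = win;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["bmu"] = bmu, _["dist"] = dist);
}
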