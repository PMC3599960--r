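#include <Rcpp.h>
using namespace Rcpp;

// Iterative SOM training loop.
//
// data:    N x M gene profiles (rows are presented to the map)
// weights: K x M metagene profiles, modified in place on a copy
// gx, gy:  grid coordinates of the K tiles (1-based, row-major)
// order:   0-based gene index per presentation (length = #presentations)
// rate:    learning rate per presentation
// radius:  Gaussian neighborhood sigma per presentation; sigma <= 0 means
//          update the best-matching unit only
//
// Deterministic: all stochastic choices (presentation order) are made by
// the caller. Neighborhood factors below 1e-12 are skipped; at that level
// the update is below double precision of any realistic weight.
// [[Rcpp::export(name = ".som_train_cpp")]]
NumericMatrix som_train_cpp(NumericMatrix data, NumericMatrix weights,
                            IntegerVector gx, IntegerVector gy,
                            IntegerVector order, NumericVector rate,
                            NumericVector radius) {
  const int M = data.ncol();
  const int K = weights.nrow();
  if (weights.ncol() != M) stop("weight/data dimension mismatch");
  NumericMatrix W = clone(weights);
  const int P = order.size();

  for (int p = 0; p < P; ++p) {
    const int g = order[p];
    // best matching unit: minimal squared Euclidean distance, ties -> lowest index
    int bmu = 0;
    double best = R_PosInf;
    for (int k = 0; k < K; ++k) {
      double d = 0.0;
      for (int j = 0; j < M; ++j) {
        const double diff = W(k, j) - data(g, j);
        d += diff * diff;
      }
      if (d < best) { best = d; bmu = k; }
    }
    const double lr = rate[p];
    const double sg = radius[p];
    if (lr == 0.0) continue;
    if (sg <= 0.0) {
      for (int j = 0; j < M; ++j)
        W(bmu, j) += lr * (data(g, j) - W(bmu, j));
    } else {
      const double denom = 2.0 * sg * sg;
      const int bx = gx[bmu], by = gy[bmu];
      for (int k = 0; k < K; ++k) {
        const double dx = gx[k] - bx, dy = gy[k] - by;
        const double f = std::exp(-(dx * dx + dy * dy) / denom);
        if (f < 1e-12) continue;
        const double step = lr * f;
        for (int j = 0; j < M; ++j)
          W(k, j) += step * (data(g, j) - W(k, j));
      }
    }
    if ((p & 1023) == 0) {
      // periodic sanity check: abort with context if weights degenerate
      for (int j = 0; j < M; ++j) {
        if (!R_finite(W(bmu, j)))
          stop("non-finite weight at presentation %d (gene index %d)", p + 1, g + 1);
      }
    }
  }
  return W;
}

// Best-matching unit per gene for a fixed map (final mapping step).
// Returns 1-based tile indices; ties resolved to the lowest index.
// [[Rcpp::export(name = ".som_bmu_cpp")]]
IntegerVector som_bmu_cpp(NumericMatrix data, NumericMatrix weights) {
  const int N = data.nrow(), M = data.ncol(), K = weights.nrow();
  IntegerVector out(N);
  for (int g = 0; g < N; ++g) {
    int bmu = 0;
    double best = R_PosInf;
    for (int k = 0; k < K; ++k) {
      double d = 0.0;
      for (int j = 0; j < M; ++j) {
        const double diff = weights(k, j) - data(g, j);
        d += diff * diff;
      }
      if (d < best) { best = d; bmu = k; }
    }
    out[g] = bmu + 1;
  }
  return out;
}
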