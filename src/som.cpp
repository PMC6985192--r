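#include <Rcpp.h>
using namespace Rcpp;

// Online Kohonen training. Xt: d x n samples (one sample per column, so a
// sample is contiguous in memory). init: 1-based column indices of Xt used
// to initialize the codebook. order: 1-based presentation order
// (epochs * n entries). The learning rate decays linearly from alpha_start
// to alpha_end and the lattice-neighborhood radius from
// max(xdim, ydim) / 2 to 1 over the whole schedule. The radius is the
// 3-sigma support of the Gaussian neighborhood kernel, so late training
// refines essentially only the best-matching unit. Neurons with a
// neighborhood weight below 0.01 are skipped (numerical cutoff).
// Returns the codebook as a d x m matrix (one neuron per column).
// [[Rcpp::export]]
NumericMatrix som_train_cpp(const NumericMatrix& Xt, int xdim, int ydim,
                            const IntegerVector& init,
                            const IntegerVector& order,
                            double alpha_start, double alpha_end) {
  const int d = Xt.nrow();
  const int m = xdim * ydim;
  NumericMatrix W(d, m);
  const double* x_ptr = Xt.begin();
  double* w_ptr = W.begin();
  for (int k = 0; k < m; ++k) {
    const double* src = x_ptr + (size_t)(init[k] - 1) * d;
    std::copy(src, src + d, w_ptr + (size_t)k * d);
  }
  std::vector<double> gx(m), gy(m);
  for (int k = 0; k < m; ++k) {
    gx[k] = k % xdim;
    gy[k] = k / xdim;
  }
  const double r_start = std::max(xdim, ydim) / 2.0;
  const double r_end = 1.0;
  const R_xlen_t T = order.size();
  for (R_xlen_t t = 0; t < T; ++t) {
    const double frac = (T > 1) ? (double)t / (double)(T - 1) : 0.0;
    const double alpha = alpha_start + (alpha_end - alpha_start) * frac;
    const double radius = r_start + (r_end - r_start) * frac;
    const double sigma = radius / 3.0;  // radius = 3-sigma support
    const double denom = 2.0 * sigma * sigma;
    const double* x = x_ptr + (size_t)(order[t] - 1) * d;
    // best-matching unit, ties to the lowest index
    int bmu = 0;
    double best = R_PosInf;
    for (int k = 0; k < m; ++k) {
      const double* w = w_ptr + (size_t)k * d;
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        const double diff = x[j] - w[j];
        s += diff * diff;
      }
      if (s < best) { best = s; bmu = k; }
    }
    const double bx = gx[bmu], by = gy[bmu];
    for (int k = 0; k < m; ++k) {
      const double dx = gx[k] - bx, dy = gy[k] - by;
      const double h = std::exp(-(dx * dx + dy * dy) / denom);
      if (h < 0.01) continue;
      const double eta = alpha * h;
      double* w = w_ptr + (size_t)k * d;
      for (int j = 0; j < d; ++j) w[j] += eta * (x[j] - w[j]);
    }
    if ((t & 4095) == 0) Rcpp::checkUserInterrupt();
  }
  return W;
}

// Best-matching unit (1-based) for each column of Xt (d x n) against the
// codebook Wt (d x m, one neuron per column).
// [[Rcpp::export]]
IntegerVector som_bmu_cpp(const NumericMatrix& Xt, const NumericMatrix& Wt) {
  const int d = Xt.nrow(), n = Xt.ncol(), m = Wt.ncol();
  IntegerVector out(n);
  const double* x_ptr = Xt.begin();
  const double* w_ptr = Wt.begin();
  for (int i = 0; i < n; ++i) {
    const double* x = x_ptr + (size_t)i * d;
    int bmu = 0;
    double best = R_PosInf;
    for (int k = 0; k < m; ++k) {
      const double* w = w_ptr + (size_t)k * d;
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        const double diff = x[j] - w[j];
        s += diff * diff;
      }
      if (s < best) { best = s; bmu = k; }
    }
    out[i] = bmu + 1;
  }
  return out;
}
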