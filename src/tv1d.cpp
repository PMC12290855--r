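#include <Rcpp.h>
using namespace Rcpp;

// Exact solution of min_x 0.5*||x - y||^2 + lambda * TV(x) for one series,
// by Condat's direct (taut-string equivalent) algorithm; O(n) typical.
static void tv1d_denoise(const double* input, double* output, const int width,
                         const double lambda) {
  if (width <= 0) return;
  if (lambda <= 0.0) {
    for (int i = 0; i < width; ++i) output[i] = input[i];
    return;
  }
  int k = 0, k0 = 0;
  double umin = lambda, umax = -lambda;
  double vmin = input[0] - lambda, vmax = input[0] + lambda;
  int kplus = 0, kminus = 0;
  const double twolambda = 2.0 * lambda;
  const double minlambda = -lambda;
  for (;;) {
    while (k == width - 1) {
      if (umin < 0.0) {
        do output[k0++] = vmin; while (k0 <= kminus);
        umax = (vmin = input[kminus = k = k0]) + (umin = lambda) - vmax;
      } else if (umax > 0.0) {
        do output[k0++] = vmax; while (k0 <= kplus);
        umin = (vmax = input[kplus = k = k0]) + (umax = minlambda) - vmin;
      } else {
        vmin += umin / (k - k0 + 1);
        do output[k0++] = vmin; while (k0 <= k);
        return;
      }
    }
    if ((umin += input[k + 1] - vmin) < minlambda) {
      do output[k0++] = vmin; while (k0 <= kminus);
      vmax = (vmin = input[kplus = kminus = k = k0]) + twolambda;
      umin = lambda; umax = minlambda;
    } else if ((umax += input[k + 1] - vmax) > lambda) {
      do output[k0++] = vmax; while (k0 <= kplus);
      vmin = (vmax = input[kplus = kminus = k = k0]) - twolambda;
      umin = lambda; umax = minlambda;
    } else {
      k++;
      if (umin >= lambda) {
        vmin += (umin - lambda) / ((kminus = k) - k0 + 1);
        umin = lambda;
      }
      if (umax <= minlambda) {
        vmax += (umax + lambda) / ((kplus = k) - k0 + 1);
        umax = minlambda;
      }
    }
  }
}

// [[Rcpp::export(name = ".tv1d_prox_mat")]]
NumericMatrix tv1d_prox_mat(const NumericMatrix& y,
                            const NumericVector& lambda) {
  const int n = y.nrow(), m = y.ncol();
  if (lambda.size() != m) stop("lambda must have one entry per column");
  NumericMatrix out(n, m);
  std::vector<double> buf(n);
  for (int j = 0; j < m; ++j) {
    tv1d_denoise(&y(0, j), buf.data(), n, lambda[j]);
    for (int i = 0; i < n; ++i) out(i, j) = buf[i];
  }
  return out;
}
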