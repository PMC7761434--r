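#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Mean over ordered pairs (i != j) of exp(-d(i,j)^n / r_abs), where d is the
// Chebyshev distance between window-mean-centred m-templates of x.
// Uses the first (N - m) templates of the embedding so that the pair counts
// for dimensions m and m+1 stay comparable (the SampEn/FE convention).
// [[Rcpp::export(name = ".phi_kernel")]]
double phi_kernel(NumericVector x, int m, double n_grad, double r_abs) {
  const int N = x.size();
  const int cnt = N - m;  // number of template vectors used
  if (m < 1) stop("embedding dimension m must be >= 1");
  if (cnt < 2) stop("sequence too short: need length >= m + 2 (= %d)", m + 2);
  if (!(r_abs > 0.0)) stop("similarity tolerance r_abs must be > 0");

  // centred templates: t_i[l] = x[i + l] - mean(x[i .. i + m - 1])
  std::vector<double> mu(cnt);
  for (int i = 0; i < cnt; ++i) {
    double s = 0.0;
    for (int l = 0; l < m; ++l) s += x[i + l];
    mu[i] = s / m;
  }

  const bool sq = (n_grad == 2.0), lin = (n_grad == 1.0);
  double acc = 0.0;
  for (int i = 0; i < cnt - 1; ++i) {
    for (int j = i + 1; j < cnt; ++j) {
      double d = 0.0;
      for (int l = 0; l < m; ++l) {
        double diff = std::fabs((x[i + l] - mu[i]) - (x[j + l] - mu[j]));
        if (diff > d) d = diff;
      }
      double w = sq ? d * d : (lin ? d : std::pow(d, n_grad));
      acc += std::exp(-w / r_abs);
    }
  }
  // upper triangle doubled == ordered-pair mean (the kernel is symmetric)
  return 2.0 * acc / (static_cast<double>(cnt) * (cnt - 1));
}
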