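#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Sliding-window Anderson-Darling statistic against the standard normal
// reference, one value per coefficient, with periodic (circular) boundary
// extension so every window is a full l*l multiset of genuine coefficients.
//
// tau = -L - (1/L) * sum_{t=1..L} (2t-1) [ln F(z_(t)) + ln(1 - F(z_(L+1-t)))]
// with z_(1..L) the ascending order statistics of the window and F the
// standard normal CDF clipped to [eps, 1-eps].
// [[Rcpp::export(name = ".ad_tau_map_cpp")]]
NumericMatrix ad_tau_map_cpp(const NumericMatrix& band, int l, double eps) {
  if (l < 2 || l % 2 == 0) stop("window side must be odd and >= 3");
  const int nr = band.nrow(), nc = band.ncol();
  const int r = l / 2, L = l * l;
  NumericMatrix tau(nr, nc);

  // Precompute wrapped row/col indices.
  std::vector<int> rowidx(nr + 2 * r), colidx(nc + 2 * r);
  for (int i = 0; i < nr + 2 * r; ++i) rowidx[i] = ((i - r) % nr + nr) % nr;
  for (int j = 0; j < nc + 2 * r; ++j) colidx[j] = ((j - r) % nc + nc) % nc;

  const double lo = eps, hi = 1.0 - eps;
  std::vector<double> z(L), lf(L), lq(L);

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = 0; dj < l; ++dj) {
        const int cj = colidx[j + dj];
        for (int di = 0; di < l; ++di)
          z[k++] = band(rowidx[i + di], cj);
      }
      std::sort(z.begin(), z.end());
      for (int t = 0; t < L; ++t) {
        double F = R::pnorm(z[t], 0.0, 1.0, 1, 0);
        if (F < lo) F = lo; else if (F > hi) F = hi;
        lf[t] = std::log(F);
        lq[t] = std::log1p(-F) < std::log(lo) ? std::log(lo) : std::log1p(-F);
      }
      double s = 0.0;
      for (int t = 0; t < L; ++t)
        s += (2.0 * (t + 1) - 1.0) * (lf[t] + lq[L - 1 - t]);
      tau(i, j) = -L - s / L;
    }
  }
  return tau;
}

// One analysis step of a periodized two-channel filter bank, applied along
// the columns of x:  out[k, j] = sum_m h[m] * x[(2k + m + off) mod n, j].
// Rows are handled by transposing at the call site.
// [[Rcpp::export(name = ".conv_down_per_cpp")]]
NumericMatrix conv_down_per_cpp(const NumericMatrix& x,
                                const NumericVector& h, int off) {
  const int n = x.nrow(), nc = x.ncol(), M = h.size();
  if (n % 2 != 0) stop("signal length must be even");
  const int nh = n / 2;
  NumericMatrix out(nh, nc);
  std::vector<int> idx(nh * M);
  for (int m = 0; m < M; ++m)
    for (int k = 0; k < nh; ++k)
      idx[m * nh + k] = ((2 * k + m + off) % n + n) % n;
  for (int j = 0; j < nc; ++j) {
    const double* xc = &x(0, j);
    double* oc = &out(0, j);
    for (int m = 0; m < M; ++m) {
      const double hm = h[m];
      const int* id = &idx[m * nh];
      for (int k = 0; k < nh; ++k) oc[k] += hm * xc[id[k]];
    }
  }
  return out;
}

// Adjoint of conv_down_per_cpp (equals the synthesis step for an
// orthonormal bank): y[(2k + m + off) mod n, j] += h[m] * a[k, j].
// [[Rcpp::export(name = ".conv_up_per_cpp")]]
NumericMatrix conv_up_per_cpp(const NumericMatrix& a,
                              const NumericVector& h, int n, int off) {
  const int nh = a.nrow(), nc = a.ncol(), M = h.size();
  if (n != 2 * nh) stop("output length must be twice the input length");
  NumericMatrix out(n, nc);
  std::vector<int> idx(nh * M);
  for (int m = 0; m < M; ++m)
    for (int k = 0; k < nh; ++k)
      idx[m * nh + k] = ((2 * k + m + off) % n + n) % n;
  for (int j = 0; j < nc; ++j) {
    const double* ac = &a(0, j);
    double* oc = &out(0, j);
    for (int m = 0; m < M; ++m) {
      const double hm = h[m];
      const int* id = &idx[m * nh];
      for (int k = 0; k < nh; ++k) oc[id[k]] += hm * ac[k];
    }
  }
  return out;
}
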