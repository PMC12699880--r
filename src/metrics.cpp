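#include <Rcpp.h>
using namespace Rcpp;

// Ordinal (permutation) symbolization. Window t is
// (x[t], x[t+tau], ..., x[t+(m-1)tau]); its symbol is the 0-based
// lexicographic rank (Lehmer code) of the stable argsort permutation, i.e.
// the permutation p with x[p[0]] <= x[p[1]] <= ... and ties resolved by
// order of occurrence.
// [[Rcpp::export(name = ".ordinal_codes_cpp")]]
IntegerVector ordinal_codes_cpp(NumericVector x, int m, int tau) {
  int n = x.size();
  int n_sym = n - (m - 1) * tau;
  if (n_sym < 1) stop("signal too short for this embedding");
  IntegerVector out(n_sym);
  std::vector<int> perm(m);
  std::vector<int> fact(m);
  fact[m - 1] = 1;
  for (int i = m - 2; i >= 0; --i) fact[i] = fact[i + 1] * (m - 1 - i);
  for (int t = 0; t < n_sym; ++t) {
    for (int j = 0; j < m; ++j) perm[j] = j;
    std::stable_sort(perm.begin(), perm.end(), [&](int a, int b) {
      return x[t + a * tau] < x[t + b * tau];
    });
    int code = 0;
    for (int i = 0; i < m; ++i) {
      int smaller = 0;
      for (int j = i + 1; j < m; ++j)
        if (perm[j] < perm[i]) ++smaller;
      code += smaller * fact[i];
    }
    out[t] = code;
  }
  return out;
}

static double entropy_nats(const std::vector<int>& counts, int n, int* k_nz) {
  double h = 0.0;
  int k = 0;
  for (size_t i = 0; i < counts.size(); ++i) {
    if (counts[i] > 0) {
      double p = (double)counts[i] / n;
      h -= p * std::log(p);
      ++k;
    }
  }
  if (k_nz) *k_nz = k;
  return h;
}

// Plug-in mutual information (bits) between symbol streams sx[t] and
// sy[t + lag], with Miller-Madow bias correction
// (K_x + K_y - K_xy - 1) / (2 n) nats added, K_* = occupied cells.
static double mi_at_lag(const IntegerVector& sx, const IntegerVector& sy,
                        int K, int lag) {
  int n = std::min((int)sx.size(), (int)sy.size() - lag);
  if (n < 2) return NA_REAL;
  std::vector<int> cx(K, 0), cy(K, 0), cxy((size_t)K * K, 0);
  for (int t = 0; t < n; ++t) {
    int a = sx[t], b = sy[t + lag];
    ++cx[a]; ++cy[b]; ++cxy[(size_t)a * K + b];
  }
  int kx, ky, kxy;
  double hx = entropy_nats(cx, n, &kx);
  double hy = entropy_nats(cy, n, &ky);
  double hxy = entropy_nats(cxy, n, &kxy);
  double mi = hx + hy - hxy + (kx + ky - kxy - 1.0) / (2.0 * n);
  return mi / std::log(2.0);
}

// Direction-symmetrized lag profile: value at index d (d = 0..max_lag) is
// max[I(x_t ; y_{t+d}), I(y_t ; x_{t+d})], i.e. the MI over signed lags
// +-d, which is symmetric in (x, y) and reaches the self-information
// ceiling for a pure delayed copy.
// [[Rcpp::export(name = ".mi_lag_profile_cpp")]]
NumericVector mi_lag_profile_cpp(IntegerVector sx, IntegerVector sy,
                                 int K, int max_lag) {
  NumericVector out(max_lag + 1);
  for (int d = 0; d <= max_lag; ++d) {
    double a = mi_at_lag(sx, sy, K, d);
    double b = mi_at_lag(sy, sx, K, d);
    out[d] = std::max(a, b);
  }
  return out;
}

// Lempel-Ziv (1976) exhaustive-history production count c(n)
// (Kaspar & Schuster recursion).
// [[Rcpp::export(name = ".lz76_count_cpp")]]
int lz76_count_cpp(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  int c = 1, l = 1, i = 0, k = 1, kmax = 1;
  while (true) {
    if (s[i + k - 1] != s[l + k - 1]) {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    } else {
      ++k;
      if (l + k > n) { ++c; break; }
    }
  }
  return c;
}
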