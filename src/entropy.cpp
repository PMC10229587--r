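#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Pairwise template-matching kernels (sample entropy, fuzzy entropy) and
// the Lempel-Ziv 1976 phrase-counting complexity.  All are O(n^2) in the
// segment length and therefore live in compiled code.

// [[Rcpp::export]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int N = n - m;  // number of (m+1)-extendable templates
  if (N < 2 || r <= 0.0) return 0.0;
  long long A = 0, B = 0;
  for (int i = 0; i < N - 1; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs(x[i + k] - x[j + k]);
        if (dd > d) d = dd;
        if (d > r) { ok = false; break; }
      }
      if (!ok) continue;
      ++B;
      double dd = std::fabs(x[i + m] - x[j + m]);
      if (dd <= r) ++A;
    }
  }
  // Conventions: no m-matches at all -> maximal value log(#pairs);
  // m-matches but no (m+1)-match -> capped at log(2B) (A treated as 1/2).
  if (B == 0) return std::log((double)N * (N - 1.0) / 2.0);
  if (A == 0) return std::log(2.0 * (double)B);
  return -std::log((double)A / (double)B);
}

// [[Rcpp::export]]
double fuzzyen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1 || r <= 0.0) return 0.0;
  // rolling means for baseline removal of templates of length m and m+1
  std::vector<double> mu_m(n - m + 1), mu_m1(n - m);
  {
    double s = 0.0;
    for (int i = 0; i < m; ++i) s += x[i];
    mu_m[0] = s / m;
    for (int i = 1; i + m <= n; ++i) {
      s += x[i + m - 1] - x[i - 1];
      mu_m[i] = s / m;
    }
    s = 0.0;
    for (int i = 0; i < m + 1; ++i) s += x[i];
    mu_m1[0] = s / (m + 1);
    for (int i = 1; i + m + 1 <= n; ++i) {
      s += x[i + m] - x[i - 1];
      mu_m1[i] = s / (m + 1);
    }
  }
  int Nm = n - m;  // use n-m templates for both lengths (standard FuzzyEn)
  double phi_m = 0.0, phi_m1 = 0.0;
  long long cnt = 0;
  // memberships below exp(-36) are negligible against sums over ~n^2 pairs
  const double cut = 6.0 * r;
  for (int i = 0; i < Nm - 1; ++i) {
    for (int j = i + 1; j < Nm; ++j) {
      double d = 0.0;
      bool far = false;
      for (int k = 0; k < m; ++k) {
        double dd = std::fabs((x[i + k] - mu_m[i]) - (x[j + k] - mu_m[j]));
        if (dd > d) d = dd;
        if (d > cut) { far = true; break; }
      }
      if (!far) phi_m += std::exp(-(d * d) / (r * r));
      d = 0.0;
      far = false;
      for (int k = 0; k <= m; ++k) {
        double dd = std::fabs((x[i + k] - mu_m1[i]) - (x[j + k] - mu_m1[j]));
        if (dd > d) d = dd;
        if (d > cut) { far = true; break; }
      }
      if (!far) phi_m1 += std::exp(-(d * d) / (r * r));
      ++cnt;
    }
  }
  if (cnt == 0 || phi_m <= 0.0 || phi_m1 <= 0.0) return 0.0;
  return std::log(phi_m / phi_m1);
}

// [[Rcpp::export]]
int lz76_cpp(IntegerVector s) {
  // Kaspar-Schuster phrase counting on a symbol sequence.
  int n = s.size();
  if (n == 0) return 0;
  int c = 1, i = 0, k = 1, kmax = 1, l = 1;
  bool stop = false;
  while (!stop) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) {
        ++c;
        stop = true;
      }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {
        ++c;
        l += kmax;
        if (l + 1 > n) {
          stop = true;
        } else {
          i = 0;
          k = 1;
          kmax = 1;
        }
      } else {
        k = 1;
      }
    }
  }
  return c;
}
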