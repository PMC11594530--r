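#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Discrete prolate spheroidal (Slepian) sequences via the symmetric
// tridiagonal commuting matrix (Percival & Walden 1993, eq. 8.4):
//   diag[i]    = ((N-1-2i)/2)^2 cos(2 pi W),  i = 0..N-1
//   offdiag[i] = i (N - i) / 2,               i = 1..N-1
// The k eigenvectors with largest eigenvalues are the first k tapers.
// Eigenvalues found by Sturm bisection, eigenvectors by inverse iteration
// with a partially pivoted tridiagonal solve.

static int sturm_count(const std::vector<double>& d,
                       const std::vector<double>& e2, double x) {
  // number of eigenvalues strictly less than x
  int n = (int)d.size(), count = 0;
  double q = d[0] - x;
  if (q < 0) ++count;
  for (int i = 1; i < n; ++i) {
    if (q == 0.0) q = 1e-300;
    q = d[i] - x - e2[i] / q;
    if (q < 0) ++count;
  }
  return count;
}

// Solve (T - lam I) x = b, T tridiagonal (d, e), with partial pivoting.
static void tridiag_shift_solve(const std::vector<double>& d,
                                const std::vector<double>& e, double lam,
                                std::vector<double>& x) {
  int n = (int)d.size();
  std::vector<double> a(n), b(n, 0.0), c(n, 0.0), f(n, 0.0);
  for (int i = 0; i < n; ++i) a[i] = d[i] - lam;
  for (int i = 0; i < n - 1; ++i) { b[i] = e[i + 1]; c[i] = e[i + 1]; }
  // a: diagonal, b: super, c: sub (c[i] couples row i+1 to col i), f: 2nd super
  for (int i = 0; i < n - 1; ++i) {
    if (std::fabs(c[i]) > std::fabs(a[i])) {
      std::swap(a[i], c[i]);
      double t = b[i]; b[i] = a[i + 1]; a[i + 1] = t;
      f[i] = b[i + 1]; b[i + 1] = 0.0;
      std::swap(x[i], x[i + 1]);
    }
    if (a[i] == 0.0) a[i] = 1e-300;
    double m = c[i] / a[i];
    a[i + 1] -= m * b[i];
    if (i + 2 < n) b[i + 1] -= m * f[i];
    x[i + 1] -= m * x[i];
  }
  if (a[n - 1] == 0.0) a[n - 1] = 1e-300;
  x[n - 1] /= a[n - 1];
  if (n >= 2) x[n - 2] = (x[n - 2] - b[n - 2] * x[n - 1]) / a[n - 2];
  for (int i = n - 3; i >= 0; --i)
    x[i] = (x[i] - b[i] * x[i + 1] - f[i] * x[i + 2]) / a[i];
}

// [[Rcpp::export]]
NumericMatrix dpss_cpp(int n, double nw, int k) {
  if (n < 2 || k < 1 || k > n) stop("invalid dpss request");
  double W = nw / n;
  std::vector<double> d(n), e(n, 0.0), e2(n, 0.0);
  double c2w = std::cos(2.0 * M_PI * W);
  for (int i = 0; i < n; ++i) {
    double hi = (n - 1 - 2.0 * i) / 2.0;
    d[i] = hi * hi * c2w;
  }
  for (int i = 1; i < n; ++i) { e[i] = i * (n - i) / 2.0; e2[i] = e[i] * e[i]; }

  // Gerschgorin bounds
  double lo = d[0], hi = d[0];
  for (int i = 0; i < n; ++i) {
    double r = ((i > 0) ? std::fabs(e[i]) : 0.0) +
               ((i + 1 < n) ? std::fabs(e[i + 1]) : 0.0);
    lo = std::min(lo, d[i] - r);
    hi = std::max(hi, d[i] + r);
  }

  NumericMatrix tapers(n, k);
  std::vector<std::vector<double> > found;
  for (int j = 0; j < k; ++j) {
    // j-th largest eigenvalue: index n-1-j (0-based, ascending)
    int target = n - 1 - j;  // want count of eigenvalues < x to cross target+1
    double a = lo, b = hi;
    for (int it = 0; it < 90; ++it) {
      double mid = 0.5 * (a + b);
      if (sturm_count(d, e2, mid) > target) b = mid; else a = mid;
      if (b - a < 1e-12 * std::max(1.0, std::fabs(b))) break;
    }
    double lam = 0.5 * (a + b);

    std::vector<double> x(n);
    for (int i = 0; i < n; ++i) x[i] = 1.0 / (1.0 + i % 7);  // deterministic seed
    for (int it = 0; it < 6; ++it) {
      // orthogonalise against previously found vectors (clustered eigenvalues)
      for (size_t f = 0; f < found.size(); ++f) {
        double dot = 0;
        for (int i = 0; i < n; ++i) dot += x[i] * found[f][i];
        for (int i = 0; i < n; ++i) x[i] -= dot * found[f][i];
      }
      double nrm = 0;
      for (int i = 0; i < n; ++i) nrm += x[i] * x[i];
      nrm = std::sqrt(nrm);
      for (int i = 0; i < n; ++i) x[i] /= nrm;
      tridiag_shift_solve(d, e, lam, x);
      nrm = 0;
      for (int i = 0; i < n; ++i) nrm += x[i] * x[i];
      nrm = std::sqrt(nrm);
      for (int i = 0; i < n; ++i) x[i] /= nrm;
    }
    // sign convention: symmetric tapers have positive mean; antisymmetric
    // tapers start with a positive lobe
    double mean = 0;
    for (int i = 0; i < n; ++i) mean += x[i];
    bool flip;
    if (j % 2 == 0) flip = mean < 0;
    else {
      double lobe = 0;
      for (int i = 0; i < n / 2; ++i) lobe += x[i];
      flip = lobe < 0;
    }
    if (flip) for (int i = 0; i < n; ++i) x[i] = -x[i];
    for (int i = 0; i < n; ++i) tapers(i, j) = x[i];
    found.push_back(x);
  }
  return tapers;
}
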