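#include <Rcpp.h>
using namespace Rcpp;

// Solve A z = b for a symmetric positive-definite banded matrix A with
// lower bandwidth p, via an in-band Cholesky factorisation (no pivoting;
// SPD is guaranteed for the penalized least-squares systems built by
// whittaker_smooth, where A = diag(w) + lam * D'D with w > 0, lam >= 0).
//
// Band storage (lower, by row): bands(i, b) = A[i + b, i] = A[i, i + b],
// b = 0..p; entries with i + b >= n are ignored.
//
// [[Rcpp::export]]
NumericVector banded_spd_solve(NumericMatrix bands, NumericVector b) {
  const int n = bands.nrow();
  const int p = bands.ncol() - 1;
  if (b.size() != n) stop("rhs length does not match band matrix");
  NumericMatrix L(clone(bands));

  for (int j = 0; j < n; ++j) {
    // subtract contributions of previous columns k in [j-p, j-1]
    const int k0 = j - p > 0 ? j - p : 0;
    for (int k = k0; k < j; ++k) {
      const double ljk = L(k, j - k);
      const int imax = k + p < n - 1 ? k + p : n - 1;
      for (int i = j; i <= imax; ++i)
        L(j, i - j) -= ljk * L(k, i - k);
    }
    const double d = L(j, 0);
    if (!(d > 0.0)) stop("banded system not positive definite");
    const double r = std::sqrt(d);
    L(j, 0) = r;
    const int bmax = (p < n - 1 - j) ? p : n - 1 - j;
    for (int c = 1; c <= bmax; ++c) L(j, c) /= r;
  }

  // forward substitution L y = b
  NumericVector z(clone(b));
  for (int i = 0; i < n; ++i) {
    double s = z[i];
    const int k0 = i - p > 0 ? i - p : 0;
    for (int k = k0; k < i; ++k) s -= L(k, i - k) * z[k];
    z[i] = s / L(i, 0);
  }
  // back substitution L' x = y
  for (int i = n - 1; i >= 0; --i) {
    double s = z[i];
    const int kmax = (i + p < n - 1) ? i + p : n - 1;
    for (int k = i + 1; k <= kmax; ++k) s -= L(i, k - i) * z[k];
    z[i] = s / L(i, 0);
  }
  return z;
}
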