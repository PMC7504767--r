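// Fused Matern(nu = 3/2) kernel evaluation. The raster stage queries the
// Gaussian-process posterior mean at 280 x 300 = 84,000 pixels against up
// to ~1000 training points; building the full cross-covariance in R would
// allocate several hundred MB, so the kernel-weight products are fused.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Matern 3/2 covariance matrix among rows of X (n x 2), unit variance.
// [[Rcpp::export]]
NumericMatrix matern32_kernel(NumericMatrix X, double length_scale) {
  const int n = X.nrow();
  const double c = std::sqrt(3.0) / length_scale;
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i) {
    K(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      const double dx = X(i, 0) - X(j, 0);
      const double dy = X(i, 1) - X(j, 1);
      const double d = c * std::sqrt(dx * dx + dy * dy);
      const double k = (1.0 + d) * std::exp(-d);
      K(i, j) = k;
      K(j, i) = k;
    }
  }
  return K;
}

// Posterior mean at query points A (m x 2): K(A, X) %*% w without
// materializing K(A, X).
// [[Rcpp::export]]
NumericVector matern32_cross_mult(NumericMatrix A, NumericMatrix X,
                                  NumericVector w, double length_scale) {
  const int m = A.nrow(), n = X.nrow();
  const double c = std::sqrt(3.0) / length_scale;
  NumericVector out(m);
  for (int i = 0; i < m; ++i) {
    const double ax = A(i, 0), ay = A(i, 1);
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      const double dx = ax - X(j, 0);
      const double dy = ay - X(j, 1);
      const double d = c * std::sqrt(dx * dx + dy * dy);
      s += (1.0 + d) * std::exp(-d) * w[j];
    }
    out[i] = s;
  }
  return out;
}

// Cross-covariance matrix K(A, X) for small query sets (predict method).
// [[Rcpp::export]]
NumericMatrix matern32_cross(NumericMatrix A, NumericMatrix X,
                             double length_scale) {
  const int m = A.nrow(), n = X.nrow();
  const double c = std::sqrt(3.0) / length_scale;
  NumericMatrix K(m, n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      const double dx = A(i, 0) - X(j, 0);
      const double dy = A(i, 1) - X(j, 1);
      const double d = c * std::sqrt(dx * dx + dy * dy);
      K(i, j) = (1.0 + d) * std::exp(-d);
    }
  }
  return K;
}

// One SMACOF run (unweighted metric stress, Guttman transform),
// iterated until the relative stress decrease falls below tol.
// [[Rcpp::export]]
List smacof_engine(NumericMatrix dm, NumericMatrix x0, int max_iter,
                   double tol) {
  const int n = dm.nrow();
  NumericMatrix x = clone(x0);
  std::vector<double> trace;
  std::vector<double> rs(n), sx(n), sy(n);
  double stress = R_PosInf;
  for (int iter = 0; iter <= max_iter; ++iter) {
    double s = 0.0;
    std::fill(rs.begin(), rs.end(), 0.0);
    std::fill(sx.begin(), sx.end(), 0.0);
    std::fill(sy.begin(), sy.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      const double xi = x(i, 0), yi = x(i, 1);
      for (int j = i + 1; j < n; ++j) {
        const double dx = xi - x(j, 0);
        const double dy = yi - x(j, 1);
        const double d = std::sqrt(dx * dx + dy * dy);
        const double delta = dm(i, j);
        const double diff = delta - d;
        s += diff * diff;
        const double r = d > 0.0 ? delta / d : 0.0;
        rs[i] += r;  rs[j] += r;
        sx[i] += r * x(j, 0);  sy[i] += r * x(j, 1);
        sx[j] += r * xi;       sy[j] += r * yi;
      }
    }
    trace.push_back(s);
    const bool converged =
        (stress - s) < tol * std::max(stress, 1e-300) && iter > 0;
    stress = s;
    if (converged || iter == max_iter) break;
    for (int i = 0; i < n; ++i) {
      const double nx = (rs[i] * x(i, 0) - sx[i]) / n;
      const double ny = (rs[i] * x(i, 1) - sy[i]) / n;
      x(i, 0) = nx;
      x(i, 1) = ny;
    }
  }
  return List::create(_["coords"] = x, _["stress"] = stress,
                      _["trace"] = NumericVector(trace.begin(), trace.end()));
}
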