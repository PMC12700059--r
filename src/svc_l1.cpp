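#include <Rcpp.h>
using namespace Rcpp;

// FISTA solver for the L1-penalized squared-hinge linear SVC:
//   min_{w,b}  ||w||_1 + C * sum_i max(0, 1 - y_i (x_i . w + b))^2
// The intercept b is unpenalized. C is the inverse regularization
// strength: sparsity increases as C decreases. The objective is convex
// and the smooth part has Lipschitz gradient bounded by
// 2 C lambda_max(Xb' Xb), with Xb = [X, 1]; the step size uses a power
// iteration estimate of that spectral norm.

static double spectral_norm_sq(const NumericMatrix& X, int iters) {
  int n = X.nrow(), p = X.ncol() + 1;  // + intercept column of ones
  std::vector<double> v(p, 1.0 / std::sqrt((double)p)), u(n), w(p);
  double s = 0.0;
  for (int it = 0; it < iters; ++it) {
    for (int i = 0; i < n; ++i) {
      double acc = v[p - 1];
      for (int j = 0; j < p - 1; ++j) acc += X(i, j) * v[j];
      u[i] = acc;
    }
    for (int j = 0; j < p - 1; ++j) {
      double acc = 0.0;
      for (int i = 0; i < n; ++i) acc += X(i, j) * u[i];
      w[j] = acc;
    }
    double acc = 0.0;
    for (int i = 0; i < n; ++i) acc += u[i];
    w[p - 1] = acc;
    double nrm = 0.0;
    for (int j = 0; j < p; ++j) nrm += w[j] * w[j];
    nrm = std::sqrt(nrm);
    if (nrm <= 0) return 1.0;
    for (int j = 0; j < p; ++j) v[j] = w[j] / nrm;
    s = nrm;  // ||X'Xv|| -> lambda_max(X'X) as v converges
  }
  return s;
}

static double objective(const NumericMatrix& X, const NumericVector& y,
                        double C, const std::vector<double>& w, double b) {
  int n = X.nrow(), p = X.ncol();
  double loss = 0.0;
  for (int i = 0; i < n; ++i) {
    double d = b;
    for (int j = 0; j < p; ++j) d += X(i, j) * w[j];
    double m = 1.0 - y[i] * d;
    if (m > 0) loss += m * m;
  }
  double l1 = 0.0;
  for (int j = 0; j < p; ++j) l1 += std::fabs(w[j]);
  return l1 + C * loss;
}

// [[Rcpp::export(name = ".svc_l1_sqhinge")]]
List svc_l1_sqhinge(NumericMatrix X, NumericVector y, double C,
                    int max_iter = 2000, double tol = 1e-10) {
  int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  double L = 2.0 * C * spectral_norm_sq(X, 30);
  if (!(L > 0)) L = 1.0;
  L *= 1.05;  // safety margin on the power-iteration estimate
  std::vector<double> w(p, 0.0), wz(p, 0.0), wprev(p, 0.0);
  double b = 0.0, bz = 0.0, bprev = 0.0, t = 1.0;
  std::vector<double> grad(p), margin(n);
  double obj_prev = objective(X, y, C, w, b);
  for (int it = 0; it < max_iter; ++it) {
    // gradient of the smooth part at the extrapolated point (wz, bz)
    double gb = 0.0;
    std::fill(grad.begin(), grad.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double d = bz;
      for (int j = 0; j < p; ++j) d += X(i, j) * wz[j];
      double m = 1.0 - y[i] * d;
      if (m > 0) {
        double g = -2.0 * C * y[i] * m;
        gb += g;
        for (int j = 0; j < p; ++j) grad[j] += g * X(i, j);
      }
    }
    // proximal step: soft-threshold w, plain step on b
    double thr = 1.0 / L;
    for (int j = 0; j < p; ++j) {
      double z = wz[j] - grad[j] / L;
      double wn = (z > thr) ? z - thr : ((z < -thr) ? z + thr : 0.0);
      wprev[j] = w[j];
      w[j] = wn;
    }
    bprev = b;
    b = bz - gb / L;
    double tn = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * t * t));
    double mom = (t - 1.0) / tn;
    for (int j = 0; j < p; ++j) wz[j] = w[j] + mom * (w[j] - wprev[j]);
    bz = b + mom * (b - bprev);
    t = tn;
    if ((it + 1) % 20 == 0 || it + 1 == max_iter) {
      double obj = objective(X, y, C, w, b);
      if (obj > obj_prev) {  // restart momentum if we overshot
        t = 1.0;
        std::copy(w.begin(), w.end(), wz.begin());
        bz = b;
      }
      double rel = std::fabs(obj_prev - obj) /
        std::max(1.0, std::fabs(obj_prev));
      obj_prev = obj;
      if (rel < tol && it + 1 > 40) break;
    }
  }
  return List::create(_["w"] = NumericVector(w.begin(), w.end()),
                      _["b"] = b,
                      _["objective"] = objective(X, y, C, w, b));
}
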