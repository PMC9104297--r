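#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Biexponential (Bateman) response as a second-order recursion.
// k[i] = m * (a^i - b^i), a = exp(-1/(fs*tau_decay)), b = exp(-1/(fs*tau_rise)),
// so y = k * p obeys  y[i] = (a+b) y[i-1] - a b y[i-2] + m (a-b) p[i-1].
// transpose = true applies the adjoint (time-reversed) operator.
static void kconv(const std::vector<double> &p, std::vector<double> &y,
                  double d1, double d2, double m1, bool transpose) {
  const int n = (int)p.size();
  double y1 = 0.0, y2 = 0.0;
  if (!transpose) {
    for (int i = 0; i < n; ++i) {
      double pin = (i >= 1) ? p[i - 1] : 0.0;
      double yi = d1 * y1 + d2 * y2 + m1 * pin;
      y[i] = yi; y2 = y1; y1 = yi;
    }
  } else {
    for (int i = n - 1; i >= 0; --i) {
      double pin = (i + 1 < n) ? p[i + 1] : 0.0;
      double yi = d1 * y1 + d2 * y2 + m1 * pin;
      y[i] = yi; y2 = y1; y1 = yi;
    }
  }
}

// Dense column-major views of the tonic basis and its penalised
// normal-matrix inverse, held in plain buffers for the hot loops.
struct TonicProj {
  int n, q;
  std::vector<double> A;    // n x q, column-major
  std::vector<double> Minv; // q x q, column-major
  TonicProj(const NumericMatrix &A_, const NumericMatrix &Minv_)
      : n(A_.nrow()), q(A_.ncol()),
        A(A_.begin(), A_.end()), Minv(Minv_.begin(), Minv_.end()) {}
};

// w = v - A Minv A' v   (residual after penalised tonic projection)
static void wapply(const std::vector<double> &v, std::vector<double> &w,
                   const TonicProj &P,
                   std::vector<double> &tq, std::vector<double> &uq) {
  const int n = P.n, q = P.q;
  const double *a = P.A.data();
  for (int j = 0; j < q; ++j) {
    const double *col = a + (size_t)j * n;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += col[i] * v[i];
    tq[j] = s;
  }
  const double *mi = P.Minv.data();
  for (int j = 0; j < q; ++j) {
    double s = 0.0;
    for (int l = 0; l < q; ++l) s += mi[j + (size_t)l * q] * tq[l];
    uq[j] = s;
  }
  std::copy(v.begin(), v.end(), w.begin());
  for (int j = 0; j < q; ++j) {
    const double *col = a + (size_t)j * n;
    const double u = uq[j];
    for (int i = 0; i < n; ++i) w[i] -= col[i] * u;
  }
}

static double dot(const std::vector<double> &a, const std::vector<double> &b) {
  double s = 0.0;
  for (size_t i = 0; i < a.size(); ++i) s += a[i] * b[i];
  return s;
}

// f(p) = 0.5 (x - Kp)' W (x - Kp) + alpha * sum(p); returns f, fills r and wr
static double objective(const std::vector<double> &p, const std::vector<double> &x,
                        double d1, double d2, double m1, double alpha,
                        const TonicProj &P,
                        std::vector<double> &kp, std::vector<double> &r,
                        std::vector<double> &wr,
                        std::vector<double> &tq, std::vector<double> &uq) {
  const int n = (int)p.size();
  kconv(p, kp, d1, d2, m1, false);
  double sp = 0.0;
  for (int i = 0; i < n; ++i) { r[i] = x[i] - kp[i]; sp += p[i]; }
  wapply(r, wr, P, tq, uq);
  return 0.5 * dot(r, wr) + alpha * sp;
}

// Largest eigenvalue of K' W K by power iteration (W, K'WK are sym. PSD).
static double lipschitz(int n, double d1, double d2, double m1,
                        const TonicProj &P) {
  std::vector<double> v(n, 1.0 / std::sqrt((double)n)), kv(n), wv(n), gv(n);
  std::vector<double> tq(P.q), uq(P.q);
  double lam = 1.0;
  for (int it = 0; it < 60; ++it) {
    kconv(v, kv, d1, d2, m1, false);
    wapply(kv, wv, P, tq, uq);
    kconv(wv, gv, d1, d2, m1, true);
    lam = std::sqrt(dot(gv, gv));
    if (lam <= 0) return 1.0;
    for (int i = 0; i < n; ++i) v[i] = gv[i] / lam;
  }
  return lam;
}

//' @title Sparse non-negative deconvolution solver (internal)
//' @description Solves min_{p >= 0} 0.5 (x-Kp)' W (x-Kp) + alpha ||p||_1 by
//' FISTA with monotone restart, where K is the biexponential convolution
//' operator given by recursion coefficients and W = I - A Minv A' is the
//' residual operator of the penalised tonic basis. Internal; called by
//' [decompose()].
//' @keywords internal
//' @noRd
// [[Rcpp::export(name = ".fista_eda")]]
List fista_eda(NumericVector x, double d1, double d2, double m1,
               NumericMatrix A, NumericMatrix Minv,
               double alpha, int maxit, double tol) {
  const int n = x.size();
  std::vector<double> xx(x.begin(), x.end());
  std::vector<double> p(n, 0.0), pold(n, 0.0), y(n, 0.0), pn(n, 0.0);
  std::vector<double> kp(n), r(n), wr(n), g(n);
  TonicProj P(A, Minv);
  std::vector<double> tq(P.q), uq(P.q);

  double L = 1.05 * lipschitz(n, d1, d2, m1, P);
  if (!(L > 0) || !std::isfinite(L)) L = 1.0;

  double fold = objective(p, xx, d1, d2, m1, alpha, P, kp, r, wr, tq, uq);
  double tk = 1.0;
  int it = 0, calm = 0;
  bool converged = false;
  double f = fold;

  for (it = 1; it <= maxit; ++it) {
    // gradient of the smooth part at y
    kconv(y, kp, d1, d2, m1, false);
    for (int i = 0; i < n; ++i) r[i] = xx[i] - kp[i];
    wapply(r, wr, P, tq, uq);
    kconv(wr, g, d1, d2, m1, true); // g = K' W (x - Ky); gradient = -g

    // proximal step: shift by alpha/L and project onto p >= 0
    for (int i = 0; i < n; ++i) {
      double v = y[i] + (g[i] - alpha) / L;
      pn[i] = (v > 0.0) ? v : 0.0;
    }
    double fn = objective(pn, xx, d1, d2, m1, alpha, P, kp, r, wr, tq, uq);

    if (fn > fold + 1e-12 * std::fabs(fold)) {
      // restart momentum from the last accepted iterate; if a plain step
      // from p itself fails to descend, the step size was too long
      if (dot(y, y) == dot(p, p) && std::equal(y.begin(), y.end(), p.begin())) {
        L *= 2.0;
      }
      y = p;
      tk = 1.0;
      calm = 0;
      continue;
    }

    double tk1 = 0.5 * (1.0 + std::sqrt(1.0 + 4.0 * tk * tk));
    for (int i = 0; i < n; ++i) {
      double mom = ((tk - 1.0) / tk1) * (pn[i] - p[i]);
      pold[i] = p[i];
      p[i] = pn[i];
      y[i] = pn[i] + mom;
    }
    tk = tk1;
    f = fn;

    if (std::fabs(fold - fn) <= tol * std::max(1.0, std::fabs(fn))) {
      if (++calm >= 5) { converged = true; break; }
    } else {
      calm = 0;
    }
    fold = fn;
  }

  return List::create(_["driver"] = NumericVector(p.begin(), p.end()),
                      _["objective"] = f,
                      _["iterations"] = it,
                      _["converged"] = converged,
                      _["lipschitz"] = L);
}

//' @title Biexponential convolution (internal)
//' @keywords internal
//' @noRd
// [[Rcpp::export(name = ".kconv_eda")]]
NumericVector kconv_eda(NumericVector p, double d1, double d2, double m1,
                        bool transpose) {
  std::vector<double> pp(p.begin(), p.end()), y(p.size());
  kconv(pp, y, d1, d2, m1, transpose);
  return NumericVector(y.begin(), y.end());
}
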