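// Adomian-decomposition (generalized power-series) stepping core for Caputo
// systems of order 0 < q <= 1.  All series are kept as "plain" coefficients
// a_i = c_i / Gamma(i*q + 1), so that the local solution of a component is
// x(h) = sum_i a_i * h^(i*q) and products of powers multiply exactly.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double kGuard = 1e6; // divergence guard on any state component

// Order-i plain coefficient of w = tanh(u), given valid w[0..i-1] and u
// coefficients a[0..i].  Uses the formal-derivative recursion
// w' = (1 - w^2) u' in the series variable.
static double tanh_next_coef(const double* a, const double* w, int i) {
  if (i == 0) return std::tanh(a[0]);
  double s = 0.0;
  for (int k = 0; k < i; ++k) {
    double w2k = 0.0; // (w^2)_k, needs w up to order k <= i-1
    for (int l = 0; l <= k; ++l) w2k += w[l] * w[k - l];
    s += (((k == 0) ? 1.0 : 0.0) - w2k) * (i - k) * a[i - k];
  }
  return s / i;
}

// Nonlinear terms are rows of a numeric matrix with columns
// (row, type, i, j, coef); type 1 = coef * tanh(x_i), type 2 = coef * x_i * x_j.
class AdmEngine {
public:
  int n, M, nt;
  double q;
  std::vector<double> L, g, coef, r;
  std::vector<int> trow, ttype, ti, tj;
  std::vector<double> A;  // plain coefficients, component-major: A[c*(M+1)+i]
  std::vector<double> TW; // tanh-series workspace per term
  std::vector<double> F;  // field series coefficient at the current order

  AdmEngine(const NumericMatrix& L_, const NumericMatrix& terms,
            const NumericVector& g_, double q_, int M_)
      : n(L_.nrow()), M(M_), nt(terms.nrow()), q(q_),
        L(L_.begin(), L_.end()), g(g_.begin(), g_.end()),
        A((size_t)L_.nrow() * (M_ + 1)),
        TW((size_t)terms.nrow() * (M_ + 1)), F(L_.nrow()) {
    trow.resize(nt); ttype.resize(nt); ti.resize(nt); tj.resize(nt);
    coef.resize(nt);
    for (int t = 0; t < nt; ++t) {
      trow[t] = (int)terms(t, 0) - 1;
      ttype[t] = (int)terms(t, 1);
      ti[t] = (int)terms(t, 2) - 1;
      tj[t] = (int)terms(t, 3) - 1;
      coef[t] = terms(t, 4);
    }
    // r[i] = Gamma(i q + 1) / Gamma((i+1) q + 1): power-rule factor mapping
    // the order-i field coefficient to the order-(i+1) state coefficient.
    r.resize(M);
    for (int i = 0; i < M; ++i)
      r[i] = std::exp(std::lgamma(i * q + 1.0) - std::lgamma((i + 1) * q + 1.0));
  }

  // Fill A with the plain series coefficients of the local expansion at x0.
  void coeffs(const double* x0) {
    for (int c = 0; c < n; ++c) A[(size_t)c * (M + 1)] = x0[c];
    for (int i = 0; i < M; ++i) {
      for (int t = 0; t < nt; ++t) { // extend tanh workspaces to order i
        if (ttype[t] != 1) continue;
        const double* a = &A[(size_t)ti[t] * (M + 1)];
        TW[(size_t)t * (M + 1) + i] = tanh_next_coef(a, &TW[(size_t)t * (M + 1)], i);
      }
      for (int rI = 0; rI < n; ++rI) {
        double s = (i == 0) ? g[rI] : 0.0;
        for (int c = 0; c < n; ++c) s += L[rI + (size_t)n * c] * A[(size_t)c * (M + 1) + i];
        F[rI] = s;
      }
      for (int t = 0; t < nt; ++t) {
        double v;
        if (ttype[t] == 1) {
          v = TW[(size_t)t * (M + 1) + i];
        } else {
          const double* a = &A[(size_t)ti[t] * (M + 1)];
          const double* b = &A[(size_t)tj[t] * (M + 1)];
          v = 0.0;
          for (int k = 0; k <= i; ++k) v += a[k] * b[i - k];
        }
        F[trow[t]] += coef[t] * v;
      }
      for (int c = 0; c < n; ++c) A[(size_t)c * (M + 1) + i + 1] = r[i] * F[c];
    }
  }

  // One M-term step; hp[i] = h^(i*q).  Returns false on divergence.
  bool step(const double* x, double* out, const double* hp) {
    coeffs(x);
    bool ok = true;
    for (int c = 0; c < n; ++c) {
      double s = 0.0;
      for (int i = 0; i <= M; ++i) s += A[(size_t)c * (M + 1) + i] * hp[i];
      out[c] = s;
      if (!std::isfinite(s) || std::fabs(s) > kGuard) ok = false;
    }
    return ok;
  }
};

static std::vector<double> h_powers(double h, double q, int M) {
  std::vector<double> hp(M + 1);
  for (int i = 0; i <= M; ++i) hp[i] = std::pow(h, i * q);
  return hp;
}

// [[Rcpp::export(name = ".adm_coefficients_cpp")]]
NumericMatrix adm_coefficients_cpp(NumericMatrix L, NumericMatrix terms,
                                   NumericVector g, double q,
                                   NumericVector state0, int M) {
  AdmEngine e(L, terms, g, q, M);
  e.coeffs(state0.begin());
  NumericMatrix out(e.n, M + 1); // rows: components, cols: orders 0..M
  for (int c = 0; c < e.n; ++c)
    for (int i = 0; i <= M; ++i) out(c, i) = e.A[(size_t)c * (M + 1) + i];
  return out;
}

// [[Rcpp::export(name = ".adm_step_cpp")]]
NumericVector adm_step_cpp(NumericMatrix L, NumericMatrix terms,
                           NumericVector g, double q, NumericVector state,
                           double h, int M) {
  AdmEngine e(L, terms, g, q, M);
  std::vector<double> hp = h_powers(h, q, M);
  NumericVector out(e.n);
  e.step(state.begin(), REAL(out), hp.data());
  return out;
}

// [[Rcpp::export(name = ".adm_integrate_cpp")]]
List adm_integrate_cpp(NumericMatrix L, NumericMatrix terms, NumericVector g,
                       double q, NumericVector state0, double h, int n_steps,
                       int M) {
  AdmEngine e(L, terms, g, q, M);
  std::vector<double> hp = h_powers(h, q, M);
  NumericMatrix states(n_steps + 1, e.n);
  std::vector<double> x(state0.begin(), state0.end()), y(e.n);
  for (int c = 0; c < e.n; ++c) states(0, c) = x[c];
  int diverged_at = -1;
  for (int k = 1; k <= n_steps; ++k) {
    bool ok = e.step(x.data(), y.data(), hp.data());
    for (int c = 0; c < e.n; ++c) states(k, c) = y[c];
    if (!ok) { diverged_at = k; break; }
    x.swap(y);
  }
  if (diverged_at > 0)
    for (int k = diverged_at + 1; k <= n_steps; ++k)
      for (int c = 0; c < e.n; ++c) states(k, c) = NA_REAL;
  return List::create(_["states"] = states, _["diverged_at"] = diverged_at);
}

// Tangent-map Lyapunov spectrum: propagate an orthonormal frame through the
// central-difference Jacobian of the one-step ADM map, re-orthonormalising by
// modified Gram-Schmidt each step, and average log diagonal growth over the
// post-transient steps, divided by the step size.
// [[Rcpp::export(name = ".lyapunov_cpp")]]
List lyapunov_cpp(NumericMatrix L, NumericMatrix terms, NumericVector g,
                  double q, NumericVector state0, double h, int n_steps,
                  int n_discard, int M, int n_exp, double delta) {
  AdmEngine e(L, terms, g, q, M);
  const int n = e.n;
  std::vector<double> hp = h_powers(h, q, M);
  std::vector<double> x(state0.begin(), state0.end());
  std::vector<double> base(n), xp(n), yp(n), ym(n);
  std::vector<double> J((size_t)n * n), Q((size_t)n * n_exp, 0.0),
      Z((size_t)n * n_exp);
  for (int k = 0; k < n_exp; ++k) Q[(size_t)k * n + k] = 1.0;
  std::vector<double> sums(n_exp, 0.0);
  int n_acc = 0, diverged_at = -1;
  for (int step = 1; step <= n_steps; ++step) {
    if (!e.step(x.data(), base.data(), hp.data())) { diverged_at = step; break; }
    for (int d = 0; d < n; ++d) { // Jacobian column d of the step map
      xp = x; xp[d] += delta;
      e.step(xp.data(), yp.data(), hp.data());
      xp[d] = x[d] - delta;
      e.step(xp.data(), ym.data(), hp.data());
      for (int c = 0; c < n; ++c)
        J[(size_t)d * n + c] = (yp[c] - ym[c]) / (2.0 * delta);
    }
    for (int k = 0; k < n_exp; ++k) { // Z = J %*% Q
      for (int c = 0; c < n; ++c) {
        double s = 0.0;
        for (int d = 0; d < n; ++d) s += J[(size_t)d * n + c] * Q[(size_t)k * n + d];
        Z[(size_t)k * n + c] = s;
      }
    }
    bool degenerate = false;
    for (int k = 0; k < n_exp; ++k) { // modified Gram-Schmidt
      double nrm = 0.0;
      for (int c = 0; c < n; ++c) nrm += Z[(size_t)k * n + c] * Z[(size_t)k * n + c];
      nrm = std::sqrt(nrm);
      if (!(nrm > 0.0) || !std::isfinite(nrm)) { degenerate = true; break; }
      for (int c = 0; c < n; ++c) Z[(size_t)k * n + c] /= nrm;
      if (step > n_discard) sums[k] += std::log(nrm);
      for (int l = k + 1; l < n_exp; ++l) {
        double dot = 0.0;
        for (int c = 0; c < n; ++c) dot += Z[(size_t)k * n + c] * Z[(size_t)l * n + c];
        for (int c = 0; c < n; ++c) Z[(size_t)l * n + c] -= dot * Z[(size_t)k * n + c];
      }
    }
    if (degenerate) { diverged_at = step; break; }
    if (step > n_discard) ++n_acc;
    Q.swap(Z);
    x.swap(base);
  }
  NumericVector les(n_exp, NA_REAL);
  if (n_acc > 0)
    for (int k = 0; k < n_exp; ++k) les[k] = sums[k] / (n_acc * h);
  return List::create(_["les"] = les, _["n_used"] = n_acc,
                      _["diverged_at"] = diverged_at);
}

// Two-term reduced-step trajectory with an audit of the first discarded
// series term: advances with x + a1*h^q only, while recording the running
// per-component maximum of |a2| * h^(2q) (= |c2| h^(2q)/Gamma(2q+1)).
// [[Rcpp::export(name = ".two_term_audit_cpp")]]
List two_term_audit_cpp(NumericMatrix L, NumericMatrix terms, NumericVector g,
                        double q, NumericVector state0, double h,
                        double n_steps) {
  AdmEngine e(L, terms, g, q, /*M=*/2);
  const int n = e.n;
  const double hq = std::pow(h, q), h2q = std::pow(h, 2.0 * q);
  std::vector<double> x(state0.begin(), state0.end());
  NumericVector maxabs(n, 0.0);
  double diverged_at = -1;
  const long long steps = (long long)n_steps;
  for (long long k = 1; k <= steps; ++k) {
    e.coeffs(x.data());
    bool ok = true;
    for (int c = 0; c < n; ++c) {
      const double* a = &e.A[(size_t)c * 3];
      double second = std::fabs(a[2]) * h2q;
      if (second > maxabs[c]) maxabs[c] = second;
      x[c] = a[0] + a[1] * hq;
      if (!std::isfinite(x[c]) || std::fabs(x[c]) > kGuard) ok = false;
    }
    if (!ok) { diverged_at = (double)k; break; }
  }
  NumericVector fin(n);
  for (int c = 0; c < n; ++c) fin[c] = x[c];
  return List::create(_["max_abs_second"] = maxabs, _["final_state"] = fin,
                      _["diverged_at"] = diverged_at);
}

// [[Rcpp::export(name = ".series_product_cpp")]]
NumericVector series_product_cpp(NumericVector a, NumericVector b, int M) {
  NumericVector out(M + 1);
  for (int i = 0; i <= M; ++i) {
    double s = 0.0;
    for (int k = 0; k <= i; ++k) s += a[k] * b[i - k];
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export(name = ".series_tanh_cpp")]]
NumericVector series_tanh_cpp(NumericVector a, int M) {
  NumericVector w(M + 1);
  for (int i = 0; i <= M; ++i)
    w[i] = tanh_next_coef(REAL(a), REAL(w), i);
  return w;
}
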