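// Marginal log-likelihood of two-part / marginalized two-part / one-part
// longitudinal models by (adaptive) Gauss-Hermite quadrature over the
// subject-level random intercepts.  Families:
//   0 binary-only      : logistic zero part, 1-D integral over u1
//   1 continuous-only  : GG density on all supplied records, 1-D over u2
//                        (the caller subsets to positives for the two-part
//                        continuous component, or substitutes the one-part
//                        zero constant)
//   2 two-part, correlated random intercepts : 2-D over (u1, u2)
//   3 marginalized two-part                  : 2-D over (u1, u2)
// Random-effect SDs below SD_TOL are treated as exactly zero and their
// dimension is dropped from the integral.

#include <Rcpp.h>
using namespace Rcpp;

static const double LN_THRESH = 1e-4;   // lognormal-limit switch on |k|
static const double SD_TOL    = 1e-8;
static const double LOG_SQRT_2PI = 0.91893853320467274178;

static inline double log_expit(double x) {
  return x > 0 ? -log1p(std::exp(-x)) : x - log1p(std::exp(x));
}

static inline double gg_logpdf(double y, double mu, double sigma, double k) {
  double ly = std::log(y);
  if (std::fabs(k) <= LN_THRESH) {
    double z = (ly - mu) / sigma;
    return -0.5 * z * z - ly - std::log(sigma) - LOG_SQRT_2PI;
  }
  double eta = 1.0 / (k * k);
  double sgn = (k > 0) ? 1.0 : -1.0;
  double u = sgn * (ly - mu) / sigma;
  return eta * std::log(eta) - std::log(sigma) - ly - lgamma(eta)
       - 0.5 * std::log(eta) + u * std::sqrt(eta)
       - eta * std::exp(std::fabs(k) * u);
}

static inline double gg_offset_c(double sigma, double k) {
  if (std::fabs(k) <= LN_THRESH) return 0.5 * sigma * sigma;
  double eta = 1.0 / (k * k);
  return sigma * std::log(k * k) / k + lgamma(eta + sigma / k) - lgamma(eta);
}

// per-observation quantities that do not depend on the random effects are
// precomputed once per likelihood evaluation
struct Model {
  std::vector<double> lpz;    // z'alpha
  std::vector<double> lpx;    // x'coef
  std::vector<double> ly;     // log y
  std::vector<char> pos;      // y > threshold
  double k, sigma, C;
  // generalized-gamma constants
  bool lognormal;
  double gg_const;            // terms of log f free of y and mu
  double sqrt_eta, eta, absk, sgn, inv_sigma;
  int family;

  void set_dist(double k_, double sigma_) {
    k = k_; sigma = sigma_; C = gg_offset_c(sigma, k);
    inv_sigma = 1.0 / sigma;
    lognormal = std::fabs(k) <= LN_THRESH;
    if (lognormal) {
      gg_const = -std::log(sigma) - LOG_SQRT_2PI;
    } else {
      eta = 1.0 / (k * k);
      absk = std::fabs(k);
      sgn = (k > 0) ? 1.0 : -1.0;
      sqrt_eta = std::sqrt(eta);
      gg_const = eta * std::log(eta) - std::log(sigma) - lgamma(eta)
               - 0.5 * std::log(eta);
    }
  }

  inline double logpdf(int j, double mu) const {
    if (lognormal) {
      double z = (ly[j] - mu) * inv_sigma;
      return gg_const - 0.5 * z * z - ly[j];
    }
    double u = sgn * (ly[j] - mu) * inv_sigma;
    return gg_const - ly[j] + u * sqrt_eta - eta * std::exp(absk * u);
  }
};

// conditional log-likelihood of records [i0, i0+len) given (u1, u2)
static double cond_ll(const Model& m, int i0, int len, double u1, double u2) {
  double ll = 0.0;
  for (int j = i0; j < i0 + len; ++j) {
    if (m.family == 1) {
      ll += m.logpdf(j, m.lpx[j] + u2);
      continue;
    }
    double lp = m.lpz[j] + u1;
    if (m.family == 0) {
      ll += m.pos[j] ? log_expit(lp) : log_expit(-lp);
      continue;
    }
    if (!m.pos[j]) {
      ll += log_expit(-lp);
    } else {
      double lpi = log_expit(lp);
      double mu = m.lpx[j] + u2;
      if (m.family == 3) mu += -lpi - m.C;   // marginalized location
      ll += lpi + m.logpdf(j, mu);
    }
  }
  return ll;
}

struct REStruct {
  int dim;            // 0, 1 or 2 active random effects
  bool use1, use2;    // which of (u1, u2) is active
  double sd1, sd2, rho;
};

// log density of the active random effects at (u1, u2)
static double log_q(const REStruct& re, double u1, double u2) {
  if (re.dim == 0) return 0.0;
  if (re.dim == 1) {
    double s = re.use1 ? re.sd1 : re.sd2;
    double u = re.use1 ? u1 : u2;
    double z = u / s;
    return -0.5 * z * z - std::log(s) - LOG_SQRT_2PI;
  }
  double a = u1 / re.sd1, b = u2 / re.sd2, r = re.rho, omr = 1.0 - r * r;
  return -(a * a - 2.0 * r * a * b + b * b) / (2.0 * omr)
       - std::log(re.sd1) - std::log(re.sd2) - 0.5 * std::log(omr)
       - 2.0 * LOG_SQRT_2PI;
}

// joint log density h(u) = cond_ll + log q, in active coordinates v[0..dim)
static double h_fun(const Model& m, const REStruct& re, int i0, int len,
                    const double* v) {
  double u1 = 0.0, u2 = 0.0;
  if (re.dim == 2) { u1 = v[0]; u2 = v[1]; }
  else if (re.dim == 1) { if (re.use1) u1 = v[0]; else u2 = v[0]; }
  return cond_ll(m, i0, len, u1, u2) + log_q(re, u1, u2);
}

// Newton mode search with finite-difference derivatives; returns true on
// success and fills mode, neg-Hessian A (row-major, dim x dim)
static bool find_mode(const Model& m, const REStruct& re, int i0, int len,
                      double* mode, double* A, double tol) {
  const double eps = 1e-4;
  int d = re.dim;
  double h0 = h_fun(m, re, i0, len, mode);
  if (!std::isfinite(h0)) { mode[0] = mode[1] = 0.0; h0 = h_fun(m, re, i0, len, mode); }
  if (!std::isfinite(h0)) return false;
  double g[2], v[2];
  for (int iter = 0; iter < 60; ++iter) {
    // gradient and Hessian by central differences
    for (int i = 0; i < d; ++i) {
      v[0] = mode[0]; v[1] = mode[1];
      v[i] = mode[i] + eps; double hp = h_fun(m, re, i0, len, v);
      v[i] = mode[i] - eps; double hm = h_fun(m, re, i0, len, v);
      g[i] = (hp - hm) / (2.0 * eps);
      A[i * d + i] = -(hp - 2.0 * h0 + hm) / (eps * eps);
    }
    if (d == 2) {
      double vpp[2] = { mode[0] + eps, mode[1] + eps };
      double vpm[2] = { mode[0] + eps, mode[1] - eps };
      double vmp[2] = { mode[0] - eps, mode[1] + eps };
      double vmm[2] = { mode[0] - eps, mode[1] - eps };
      double off = -(h_fun(m, re, i0, len, vpp) - h_fun(m, re, i0, len, vpm)
                   - h_fun(m, re, i0, len, vmp) + h_fun(m, re, i0, len, vmm))
                   / (4.0 * eps * eps);
      A[1] = A[2] = off;
    }
    double gnorm = std::fabs(g[0]) + (d == 2 ? std::fabs(g[1]) : 0.0);
    if (gnorm < tol) break;
    // Newton step on A s = g (A is neg-Hessian, expected PD near mode)
    double s[2];
    if (d == 1) {
      double a = A[0] > 1e-10 ? A[0] : 1.0;
      s[0] = g[0] / a;
    } else {
      double det = A[0] * A[3] - A[1] * A[1];
      if (A[0] <= 1e-10 || det <= 1e-12) {      // not PD: gradient step
        s[0] = g[0]; s[1] = g[1];
      } else {
        s[0] = ( A[3] * g[0] - A[1] * g[1]) / det;
        s[1] = (-A[1] * g[0] + A[0] * g[1]) / det;
      }
    }
    // damped step
    double step = 1.0, hn = -HUGE_VAL;
    for (int half = 0; half < 12; ++half) {
      v[0] = mode[0] + step * s[0];
      v[1] = (d == 2) ? mode[1] + step * s[1] : mode[1];
      hn = h_fun(m, re, i0, len, v);
      if (std::isfinite(hn) && hn >= h0 - 1e-12) break;
      step *= 0.5;
    }
    if (!std::isfinite(hn) || hn < h0 - 1e-8) return false;
    mode[0] = v[0]; if (d == 2) mode[1] = v[1];
    if (hn - h0 < 1e-12 && iter > 0) { h0 = hn; break; }
    h0 = hn;
  }
  // final neg-Hessian at the mode
  for (int i = 0; i < d; ++i) {
    v[0] = mode[0]; v[1] = mode[1];
    v[i] = mode[i] + eps; double hp = h_fun(m, re, i0, len, v);
    v[i] = mode[i] - eps; double hm = h_fun(m, re, i0, len, v);
    A[i * d + i] = -(hp - 2.0 * h0 + hm) / (eps * eps);
  }
  if (d == 2) {
    double vpp[2] = { mode[0] + eps, mode[1] + eps };
    double vpm[2] = { mode[0] + eps, mode[1] - eps };
    double vmp[2] = { mode[0] - eps, mode[1] + eps };
    double vmm[2] = { mode[0] - eps, mode[1] - eps };
    double off = -(h_fun(m, re, i0, len, vpp) - h_fun(m, re, i0, len, vpm)
                 - h_fun(m, re, i0, len, vmp) + h_fun(m, re, i0, len, vmm))
                 / (4.0 * eps * eps);
    A[1] = A[2] = off;
  }
  if (d == 1) return A[0] > 1e-10;
  return A[0] > 1e-10 && (A[0] * A[3] - A[1] * A[1]) > 1e-12;
}

// [[Rcpp::export]]
List agq_loglik_cpp(NumericVector y, NumericMatrix Z, NumericMatrix X,
                    IntegerVector subj_start, IntegerVector subj_len,
                    NumericVector alpha, NumericVector coef,
                    double k, double sigma, int family,
                    double sd1, double sd2, double rho,
                    double zero_threshold,
                    NumericVector gh_x, NumericVector gh_w,
                    bool adaptive, double mode_tol,
                    NumericMatrix start_modes) {
  int ns = subj_start.size();
  int nq = gh_x.size();
  int n = y.size();
  Model m;
  m.family = family;
  m.set_dist(k, sigma);
  m.lpz.assign(n, 0.0); m.lpx.assign(n, 0.0);
  m.ly.resize(n); m.pos.resize(n);
  for (int j = 0; j < n; ++j) {
    m.ly[j] = (y[j] > 0) ? std::log(y[j]) : 0.0;
    m.pos[j] = y[j] > zero_threshold;
  }
  for (int p = 0; p < alpha.size(); ++p)
    for (int j = 0; j < n; ++j) m.lpz[j] += Z(j, p) * alpha[p];
  for (int p = 0; p < coef.size(); ++p)
    for (int j = 0; j < n; ++j) m.lpx[j] += X(j, p) * coef[p];

  REStruct re;
  bool want1 = (family == 0 || family >= 2);
  bool want2 = (family == 1 || family >= 2);
  re.use1 = want1 && sd1 > SD_TOL;
  re.use2 = want2 && sd2 > SD_TOL;
  re.dim = (re.use1 ? 1 : 0) + (re.use2 ? 1 : 0);
  re.sd1 = sd1; re.sd2 = sd2;
  re.rho = (re.dim == 2) ? rho : 0.0;
  if (re.rho > 0.999) re.rho = 0.999;
  if (re.rho < -0.999) re.rho = -0.999;

  NumericVector ll(ns);
  NumericMatrix modes(ns, 2);
  IntegerVector adapted(ns);
  std::vector<double> lw(nq);
  for (int i = 0; i < nq; ++i)
    lw[i] = std::log(gh_w[i]) + gh_x[i] * gh_x[i];

  for (int s = 0; s < ns; ++s) {
    int i0 = subj_start[s], len = subj_len[s];
    if (re.dim == 0) {
      ll[s] = cond_ll(m, i0, len, 0.0, 0.0);
      continue;
    }
    // mode and curvature (adaptive) or prior center/scale (non-adaptive)
    double mode[2] = { 0.0, 0.0 };
    double Sig[4];        // covariance of the proposal, active coords
    bool ok = false;
    if (adaptive) {
      double mstart[2] = { start_modes(s, 0), start_modes(s, 1) };
      double mact[2];
      if (re.dim == 2) { mact[0] = mstart[0]; mact[1] = mstart[1]; }
      else mact[0] = re.use1 ? mstart[0] : mstart[1];
      mact[1] = (re.dim == 2) ? mact[1] : 0.0;
      double A[4];
      ok = find_mode(m, re, i0, len, mact, A, mode_tol);
      if (ok) {
        mode[0] = mact[0]; mode[1] = (re.dim == 2) ? mact[1] : 0.0;
        if (re.dim == 1) {
          Sig[0] = 1.0 / A[0];
        } else {
          double det = A[0] * A[3] - A[1] * A[1];
          Sig[0] =  A[3] / det; Sig[1] = -A[1] / det;
          Sig[2] = -A[1] / det; Sig[3] =  A[0] / det;
        }
      }
    }
    if (!ok) {            // non-adaptive rule centered at the prior
      mode[0] = mode[1] = 0.0;
      if (re.dim == 1) {
        double sd = re.use1 ? re.sd1 : re.sd2;
        Sig[0] = sd * sd;
      } else {
        Sig[0] = re.sd1 * re.sd1;
        Sig[1] = Sig[2] = re.rho * re.sd1 * re.sd2;
        Sig[3] = re.sd2 * re.sd2;
      }
    }
    adapted[s] = ok ? 1 : 0;

    if (re.dim == 1) {
      double L = std::sqrt(Sig[0]);
      double acc = -HUGE_VAL;
      for (int i = 0; i < nq; ++i) {
        double v = mode[0] + M_SQRT2 * L * gh_x[i];
        double t = lw[i] + h_fun(m, re, i0, len, &v);
        if (t > acc) acc = t + log1p(std::exp(acc - t));
        else if (std::isfinite(t)) acc = acc + log1p(std::exp(t - acc));
      }
      ll[s] = 0.5 * std::log(2.0) + std::log(L) + acc;
      if (re.use1) modes(s, 0) = mode[0]; else modes(s, 1) = mode[0];
    } else {
      // Cholesky of Sig
      double l11 = std::sqrt(Sig[0]);
      double l21 = Sig[1] / l11;
      double d22 = Sig[3] - l21 * l21;
      if (d22 < 1e-12) d22 = 1e-12;
      double l22 = std::sqrt(d22);
      double acc = -HUGE_VAL;
      for (int i = 0; i < nq; ++i) {
        for (int j = 0; j < nq; ++j) {
          double v[2];
          v[0] = mode[0] + M_SQRT2 * l11 * gh_x[i];
          v[1] = mode[1] + M_SQRT2 * (l21 * gh_x[i] + l22 * gh_x[j]);
          double t = lw[i] + lw[j] + h_fun(m, re, i0, len, v);
          if (!std::isfinite(t)) continue;
          if (acc == -HUGE_VAL) acc = t;
          else if (t > acc) acc = t + log1p(std::exp(acc - t));
          else acc = acc + log1p(std::exp(t - acc));
        }
      }
      ll[s] = std::log(2.0) + std::log(l11) + std::log(l22) + acc;
      modes(s, 0) = mode[0]; modes(s, 1) = mode[1];
    }
  }

  double total = 0.0;
  for (int s = 0; s < ns; ++s) total += ll[s];
  return List::create(_["total"] = total, _["subject"] = ll,
                      _["modes"] = modes, _["adapted"] = adapted);
}
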