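// Marginal log-likelihood of a logistic mixed model with nested random
// intercepts (individual within cohort), integrated by nested adaptive
// Gauss-Hermite quadrature. One quadrature point per level collapses to
// the Laplace approximation.
//
// Random effects are parameterised as sigma * z with z ~ N(0, 1), so the
// linear predictor of row r in individual i of cohort c is
//   eta_r + sigma_c * u_c + sigma_i * v_i.
// The gradient uses the fixed-node chain rule (posterior-weighted score);
// the dependence of the adapted node positions on the parameters is
// ignored, which vanishes as the quadrature error does.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double log1p_exp(double x) {
  if (x > 33.0) return x;
  if (x < -33.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double logsumexp_vec(const std::vector<double>& t) {
  double m = t[0];
  for (size_t i = 1; i < t.size(); ++i) m = std::max(m, t[i]);
  double s = 0.0;
  for (size_t i = 0; i < t.size(); ++i) s += std::exp(t[i] - m);
  return m + std::log(s);
}

struct InnerState {
  double vhat;   // conditional mode of the standardised individual effect
  double s;      // adaptive scale 1/sqrt(sigma_i^2 W + 1)
};

// Bernoulli log-likelihood of individual i's rows at offset u + sigma_i*v,
// plus the N(0,1) log-prior kernel of v (without the normalising constant).
static double q_individual(const double* eta, const double* y,
                           int lo, int hi, double off, double v) {
  double q = -0.5 * v * v;
  for (int r = lo; r < hi; ++r) {
    double e = eta[r] + off;
    q += y[r] * e - log1p_exp(e);
  }
  return q;
}

// Newton search for the conditional mode of v for one individual.
static InnerState inner_mode(const double* eta, const double* y,
                             int lo, int hi, double u, double sigma_i) {
  InnerState st;
  double v = 0.0;
  double W = 0.0;
  for (int it = 0; it < 60; ++it) {
    double g = -v, h = -1.0;
    W = 0.0;
    for (int r = lo; r < hi; ++r) {
      double e = eta[r] + u + sigma_i * v;
      double mu = 1.0 / (1.0 + std::exp(-e));
      g += sigma_i * (y[r] - mu);
      W += mu * (1.0 - mu);
    }
    h -= sigma_i * sigma_i * W;
    double step = -g / h;
    if (step > 5.0) step = 5.0;
    if (step < -5.0) step = -5.0;
    v += step;
    if (std::fabs(step) < 1e-11) break;
  }
  st.vhat = v;
  st.s = 1.0 / std::sqrt(sigma_i * sigma_i * W + 1.0);
  return st;
}

static const double HALF_LOG_2PI = 0.9189385332046727;

// [[Rcpp::export]]
List glmm_nested_loglik_cpp(NumericVector beta, double sigma_c, double sigma_i,
                            NumericMatrix X, NumericVector y,
                            IntegerVector ind_ptr, IntegerVector coh_ptr,
                            NumericVector z1, NumericVector logw1,
                            NumericVector z2, NumericVector logw2,
                            bool grad_flag) {
  const int n = X.nrow(), p = X.ncol();
  const int m = ind_ptr.size() - 1;
  const int C = coh_ptr.size() - 1;
  const int K1 = z1.size(), K2 = z2.size();
  const double sqrt2 = std::sqrt(2.0);
  const bool has_ind = sigma_i > 0.0;
  const bool has_coh = sigma_c > 0.0;

  std::vector<double> eta(n);
  for (int r = 0; r < n; ++r) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(r, j) * beta[j];
    eta[r] = e;
  }
  const double* etap = eta.data();
  const double* yp = REAL(y);

  // log g_i(u) and, optionally, the inner state for reuse
  std::vector<double> tl(K2);
  auto log_g = [&](int i, double u, InnerState* keep) -> double {
    int lo = ind_ptr[i], hi = ind_ptr[i + 1];
    if (!has_ind) {
      double q = 0.0;
      for (int r = lo; r < hi; ++r) {
        double e = etap[r] + u;
        q += yp[r] * e - log1p_exp(e);
      }
      if (keep) { keep->vhat = 0.0; keep->s = 1.0; }
      return q;
    }
    InnerState st = inner_mode(etap, yp, lo, hi, u, sigma_i);
    if (keep) *keep = st;
    for (int l = 0; l < K2; ++l) {
      double v = st.vhat + sqrt2 * st.s * z2[l];
      tl[l] = q_individual(etap, yp, lo, hi, u + sigma_i * v, v) +
        z2[l] * z2[l] + logw2[l];
    }
    return std::log(sqrt2 * st.s) - HALF_LOG_2PI + logsumexp_vec(tl);
  };

  // profile gradient/curvature of the cohort-level integrand at u, using
  // the inner Laplace modes (used only to centre the outer quadrature)
  auto outer_GH = [&](int c, double u, double* G, double* H) {
    double g = -u / (sigma_c * sigma_c);
    double h = -1.0 / (sigma_c * sigma_c);
    for (int i = coh_ptr[c]; i < coh_ptr[c + 1]; ++i) {
      int lo = ind_ptr[i], hi = ind_ptr[i + 1];
      double vhat = 0.0, W = 0.0;
      if (has_ind) {
        InnerState st = inner_mode(etap, yp, lo, hi, u, sigma_i);
        vhat = st.vhat;
      }
      double score = 0.0;
      W = 0.0;
      for (int r = lo; r < hi; ++r) {
        double e = etap[r] + u + sigma_i * vhat;
        double mu = 1.0 / (1.0 + std::exp(-e));
        score += yp[r] - mu;
        W += mu * (1.0 - mu);
      }
      g += score;
      h -= has_ind ? W / (1.0 + sigma_i * sigma_i * W) : W;
    }
    *G = g;
    *H = h;
  };

  double loglik = 0.0;
  std::vector<double> grad(p + 2, 0.0);
  std::vector<double> resid_w(n, 0.0);  // posterior-weighted residuals
  std::vector<double> Ak(K1), Tk(K1), uk(K1);
  std::vector<InnerState> states;       // per (i - coh offset, k)
  std::vector<double> tll(K2);

  for (int c = 0; c < C; ++c) {
    int i0 = coh_ptr[c], i1 = coh_ptr[c + 1];
    int mc = i1 - i0;

    double uhat = 0.0, hout = 1.0;
    int nK1 = has_coh ? K1 : 1;
    if (has_coh) {
      for (int it = 0; it < 50; ++it) {
        double G, H;
        outer_GH(c, uhat, &G, &H);
        double step = -G / H;
        if (step > 10.0) step = 10.0;
        if (step < -10.0) step = -10.0;
        uhat += step;
        hout = -H;
        if (std::fabs(step) < 1e-10) break;
      }
    }
    double sout = has_coh ? 1.0 / std::sqrt(hout) : 1.0;

    states.assign((size_t)mc * nK1, InnerState());
    for (int k = 0; k < nK1; ++k) {
      double u = has_coh ? uhat + sqrt2 * sout * z1[k] : 0.0;
      uk[k] = u;
      double A = 0.0;
      if (has_coh) {
        // N(0, sigma_c^2) log-density of the raw cohort offset u
        A += -HALF_LOG_2PI - std::log(sigma_c) -
          0.5 * u * u / (sigma_c * sigma_c);
      }
      for (int i = i0; i < i1; ++i) {
        A += log_g(i, u, &states[(size_t)(i - i0) * nK1 + k]);
      }
      Ak[k] = A;
      Tk[k] = has_coh ? A + z1[k] * z1[k] + logw1[k] : A;
    }
    double lc;
    if (has_coh) {
      std::vector<double> tk(Tk.begin(), Tk.begin() + nK1);
      lc = std::log(sqrt2 * sout) + logsumexp_vec(tk);
    } else {
      lc = Tk[0];
    }
    loglik += lc;

    if (grad_flag) {
      std::vector<double> Wk(nK1);
      if (has_coh) {
        double mx = Tk[0];
        for (int k = 1; k < nK1; ++k) mx = std::max(mx, Tk[k]);
        double s = 0.0;
        for (int k = 0; k < nK1; ++k) { Wk[k] = std::exp(Tk[k] - mx); s += Wk[k]; }
        for (int k = 0; k < nK1; ++k) Wk[k] /= s;
      } else {
        Wk[0] = 1.0;
      }
      for (int k = 0; k < nK1; ++k) {
        double u = uk[k];
        if (has_coh) {
          // prior score wrt sigma_c at the (fixed) node u
          grad[p] += Wk[k] *
            (u * u / (sigma_c * sigma_c * sigma_c) - 1.0 / sigma_c);
        }
        for (int i = i0; i < i1; ++i) {
          int lo = ind_ptr[i], hi = ind_ptr[i + 1];
          const InnerState& st = states[(size_t)(i - i0) * nK1 + k];
          if (!has_ind) {
            for (int r = lo; r < hi; ++r) {
              double e = etap[r] + u;
              double mu = 1.0 / (1.0 + std::exp(-e));
              resid_w[r] += Wk[k] * (yp[r] - mu);
            }
          } else {
            // recompute inner node weights
            for (int l = 0; l < K2; ++l) {
              double v = st.vhat + sqrt2 * st.s * z2[l];
              tll[l] = q_individual(etap, yp, lo, hi, u + sigma_i * v, v) +
                z2[l] * z2[l] + logw2[l];
            }
            double mx = tll[0];
            for (int l = 1; l < K2; ++l) mx = std::max(mx, tll[l]);
            double s = 0.0;
            std::vector<double> om(K2);
            for (int l = 0; l < K2; ++l) { om[l] = std::exp(tll[l] - mx); s += om[l]; }
            for (int l = 0; l < K2; ++l) om[l] /= s;
            for (int l = 0; l < K2; ++l) {
              double v = st.vhat + sqrt2 * st.s * z2[l];
              double wt = Wk[k] * om[l];
              for (int r = lo; r < hi; ++r) {
                double e = etap[r] + u + sigma_i * v;
                double mu = 1.0 / (1.0 + std::exp(-e));
                double res = wt * (yp[r] - mu);
                resid_w[r] += res;
                grad[p + 1] += res * v;
              }
            }
          }
        }
      }
    }
  }

  List out;
  out["loglik"] = loglik;
  if (grad_flag) {
    for (int r = 0; r < n; ++r) {
      for (int j = 0; j < p; ++j) grad[j] += resid_w[r] * X(r, j);
    }
    out["gradient"] = NumericVector(grad.begin(), grad.end());
  }
  return out;
}
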