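// Likelihood kernels for joint longitudinal-survival models with a
// current-value association and a piecewise-constant baseline hazard.
//
// With a subject's (summed, scaled) current value linear in time,
// m(t) = A + B t, every hazard integral over a baseline segment has the
// closed form  lambda_j * exp(A) * I0(B; u, v)  with
//   I0 = int_u^v exp(B t) dt,  I1 = int t exp(B t) dt,  I2 = int t^2 exp(B t) dt.
// These power the marginal likelihood (adaptive Gauss-Hermite over the
// subject random effects), the MCMC backend's complete-data likelihood,
// and the Gibbs exposures for the baseline-hazard update.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void seg_ints(double c, double u, double v,
                            double &I0, double &I1, double &I2) {
  // stable near c == 0 (second-order series)
  double span = std::max(std::fabs(u), std::fabs(v));
  if (std::fabs(c) * std::max(span, 1.0) < 1e-7) {
    double u2 = u * u, v2 = v * v, u3 = u2 * u, v3 = v2 * v;
    double u4 = u3 * u, v4 = v3 * v, u5 = u4 * u, v5 = v4 * v;
    I0 = (v - u) + c * (v2 - u2) / 2.0 + c * c * (v3 - u3) / 6.0;
    I1 = (v2 - u2) / 2.0 + c * (v3 - u3) / 3.0 + c * c * (v4 - u4) / 8.0;
    I2 = (v3 - u3) / 3.0 + c * (v4 - u4) / 4.0 + c * c * (v5 - u5) / 10.0;
  } else {
    double eu = std::exp(c * u), ev = std::exp(c * v);
    I0 = (ev - eu) / c;
    I1 = (ev * (c * v - 1.0) - eu * (c * u - 1.0)) / (c * c);
    I2 = (ev * (c * c * v * v - 2.0 * c * v + 2.0) -
          eu * (c * c * u * u - 2.0 * c * u + 2.0)) / (c * c * c);
  }
}

// Cumulative-hazard building blocks for one subject:
// S0 = sum_j lambda_j e^A I0_j, S1 = ... I1_j, S2 = ... I2_j over [0, Ti].
static inline void cumhaz_sums(double Ti, double A, double B,
                               const arma::vec &knots, const arma::vec &lam,
                               double &S0, double &S1, double &S2) {
  S0 = S1 = S2 = 0.0;
  double eA = std::exp(A);
  int K = lam.n_elem;
  for (int j = 0; j < K; ++j) {
    double u = knots[j];
    if (u >= Ti) break;
    double v = std::min(knots[j + 1], Ti);
    double I0, I1, I2;
    seg_ints(B, u, v, I0, I1, I2);
    S0 += lam[j] * eA * I0;
    S1 += lam[j] * eA * I1;
    S2 += lam[j] * eA * I2;
  }
}

static inline int seg_index(double t, const arma::vec &knots) {
  int K = knots.n_elem - 1;
  for (int j = K - 1; j >= 0; --j) if (t >= knots[j]) return j;
  return 0;
}

//' @noRd
// [[Rcpp::export(name = "cpp_pc_exposures")]]
arma::mat cpp_pc_exposures(const arma::vec &Ti, const arma::vec &A,
                           const arma::vec &B, const arma::vec &knots) {
  int n = Ti.n_elem, K = knots.n_elem - 1;
  arma::mat E(n, K, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    double eA = std::exp(A[i]);
    for (int j = 0; j < K; ++j) {
      double u = knots[j];
      if (u >= Ti[i]) break;
      double v = std::min(knots[j + 1], Ti[i]);
      double I0, I1, I2;
      seg_ints(B[i], u, v, I0, I1, I2);
      E(i, j) = eA * I0;
    }
  }
  return E;
}

//' @noRd
// [[Rcpp::export(name = "cpp_surv_loglik")]]
arma::vec cpp_surv_loglik(const arma::vec &Ti, const arma::vec &delta,
                          const arma::vec &A, const arma::vec &B,
                          const arma::vec &knots, const arma::vec &loglam) {
  int n = Ti.n_elem, K = loglam.n_elem;
  arma::vec lam = arma::exp(loglam);
  arma::vec out(n);
  for (int i = 0; i < n; ++i) {
    double H = 0.0, eA = std::exp(A[i]);
    for (int j = 0; j < K; ++j) {
      double u = knots[j];
      if (u >= Ti[i]) break;
      double v = std::min(knots[j + 1], Ti[i]);
      double I0, I1, I2;
      seg_ints(B[i], u, v, I0, I1, I2);
      H += lam[j] * eA * I0;
    }
    double ll = -H;
    if (delta[i] > 0.5)
      ll += loglam[seg_index(Ti[i], knots)] + A[i] + B[i] * Ti[i];
    out[i] = ll;
  }
  return out;
}

// Marginal log-likelihood of the univariate joint model by adaptive
// Gauss-Hermite quadrature over (b0, b1).  Observations are grouped by
// subject via 0-based offsets obs_off (length n+1).  The marker and its
// baseline covariate are assumed already on the association reporting
// scale.  Design X columns: 1, t, arm, arm*t, baseline.
//
// Returns a List: loglik, per-subject contributions, random-effect modes
// and the (negated) Hessian at the mode (for empirical-Bayes use).
//' @noRd
// [[Rcpp::export(name = "cpp_jm_marg_loglik")]]
List cpp_jm_marg_loglik(const arma::vec &y, const arma::mat &X,
                        const arma::vec &tobs, const arma::ivec &obs_off,
                        const arma::mat &W, const arma::vec &arm,
                        const arma::vec &base,
                        const arma::vec &Ti, const arma::vec &delta,
                        const arma::vec &beta, double log_sigma,
                        double log_sd0, double log_sd1, double atanh_rho,
                        const arma::vec &gamma, double alpha,
                        const arma::vec &loglam, const arma::vec &knots,
                        const arma::vec &gh_x, const arma::vec &gh_w,
                        bool want_modes, const arma::mat &b_init) {
  int n = Ti.n_elem;
  int Q = gh_x.n_elem;
  double sigma = std::exp(log_sigma);
  double sd0 = std::exp(log_sd0), sd1 = std::exp(log_sd1);
  double rho = std::tanh(atanh_rho);
  arma::mat D(2, 2);
  D(0, 0) = sd0 * sd0; D(1, 1) = sd1 * sd1;
  D(0, 1) = D(1, 0) = rho * sd0 * sd1;
  double detD = D(0, 0) * D(1, 1) - D(0, 1) * D(0, 1);
  if (!(detD > 0.0) || !std::isfinite(detD))
    return List::create(_["loglik"] = NA_REAL);
  arma::mat Dinv(2, 2);
  Dinv(0, 0) = D(1, 1) / detD; Dinv(1, 1) = D(0, 0) / detD;
  Dinv(0, 1) = Dinv(1, 0) = -D(0, 1) / detD;

  arma::vec lam = arma::exp(loglam);
  arma::vec r = y - X * beta;
  arma::vec eta_w = W * gamma;
  double sig2 = sigma * sigma;
  const double l2pi = std::log(2.0 * M_PI);

  arma::vec lli(n, arma::fill::zeros);
  arma::mat modes(n, 2, arma::fill::zeros);
  arma::mat Mout(n, 3, arma::fill::zeros);
  bool bad = false;

  for (int i = 0; i < n && !bad; ++i) {
    int o0 = obs_off[i], o1 = obs_off[i + 1];
    double ni = o1 - o0, St = 0, Stt = 0, Sr = 0, Srt = 0, Srr = 0;
    for (int o = o0; o < o1; ++o) {
      double tt = tobs[o], rr = r[o];
      St += tt; Stt += tt * tt; Sr += rr; Srt += rr * tt; Srr += rr * rr;
    }
    // fixed parts of the current value: m(t) = Am + b0 + (Bm + b1) t
    double Am = beta[0] + beta[2] * arm[i] + beta[4] * base[i];
    double Bm = beta[1] + beta[3] * arm[i];
    double dseg = (delta[i] > 0.5) ? loglam[seg_index(Ti[i], knots)] : 0.0;

    // log integrand f(b), gradient, Hessian
    auto fval = [&](double b0, double b1, bool grad,
                    arma::vec &g, arma::mat &Hm) -> double {
      double A = eta_w[i] + alpha * (Am + b0);
      double B = alpha * (Bm + b1);
      if (A + std::max(0.0, B) * Ti[i] > 60.0) return -1e300;  // runaway hazard
      double S0, S1, S2;
      cumhaz_sums(Ti[i], A, B, knots, lam, S0, S1, S2);
      double SSR = Srr - 2.0 * (b0 * Sr + b1 * Srt) +
        b0 * b0 * ni + 2.0 * b0 * b1 * St + b1 * b1 * Stt;
      double qb = Dinv(0, 0) * b0 * b0 + 2.0 * Dinv(0, 1) * b0 * b1 +
        Dinv(1, 1) * b1 * b1;
      double f = -ni * (std::log(sigma) + 0.5 * l2pi) - SSR / (2.0 * sig2)
        - l2pi - 0.5 * std::log(detD) - 0.5 * qb - S0;
      if (delta[i] > 0.5) f += dseg + A + B * Ti[i];
      if (grad) {
        g[0] = (Sr - ni * b0 - St * b1) / sig2
          - (Dinv(0, 0) * b0 + Dinv(0, 1) * b1) - alpha * S0;
        g[1] = (Srt - St * b0 - Stt * b1) / sig2
          - (Dinv(0, 1) * b0 + Dinv(1, 1) * b1) - alpha * S1;
        if (delta[i] > 0.5) { g[0] += alpha; g[1] += alpha * Ti[i]; }
        Hm(0, 0) = -ni / sig2 - Dinv(0, 0) - alpha * alpha * S0;
        Hm(0, 1) = Hm(1, 0) = -St / sig2 - Dinv(0, 1) - alpha * alpha * S1;
        Hm(1, 1) = -Stt / sig2 - Dinv(1, 1) - alpha * alpha * S2;
      }
      return f;
    };

    // Newton with step halving (f is concave in b); warm start if given
    double b0 = 0.0, b1 = 0.0;
    if ((int)b_init.n_rows == n) { b0 = b_init(i, 0); b1 = b_init(i, 1); }
    arma::vec g(2); arma::mat Hm(2, 2);
    double f0 = fval(b0, b1, true, g, Hm);
    for (int it = 0; it < 50; ++it) {
      double det = Hm(0, 0) * Hm(1, 1) - Hm(0, 1) * Hm(0, 1);
      if (!(std::fabs(det) > 1e-300)) break;
      double s0 = -( Hm(1, 1) * g[0] - Hm(0, 1) * g[1]) / det;
      double s1 = -(-Hm(0, 1) * g[0] + Hm(0, 0) * g[1]) / det;
      double step = 1.0, fnew = -1e308; double nb0 = b0, nb1 = b1;
      for (int h = 0; h < 30; ++h) {
        nb0 = b0 + step * s0; nb1 = b1 + step * s1;
        arma::vec gtmp(2); arma::mat Htmp(2, 2);
        fnew = fval(nb0, nb1, false, gtmp, Htmp);
        if (fnew >= f0 - 1e-12) break;
        step *= 0.5;
      }
      double move = std::fabs(nb0 - b0) + std::fabs(nb1 - b1);
      b0 = nb0; b1 = nb1;
      f0 = fval(b0, b1, true, g, Hm);
      if (move < 1e-10) break;
    }
    // curvature at mode
    arma::mat M = -Hm;
    double m11 = M(0, 0), m12 = M(0, 1), m22 = M(1, 1);
    if (!(m11 > 0.0)) { bad = true; break; }
    double r11 = std::sqrt(m11), r12 = m12 / r11;
    double d22 = m22 - r12 * r12;
    if (!(d22 > 0.0)) { bad = true; break; }
    double r22 = std::sqrt(d22);

    // AGH: b = bhat + sqrt(2) * Rinv * x
    double acc = 0.0;
    const double sq2 = std::sqrt(2.0);
    for (int q1 = 0; q1 < Q; ++q1) {
      double x1 = gh_x[q1];
      for (int q2 = 0; q2 < Q; ++q2) {
        double x2 = gh_x[q2];
        // solve upper-triangular R z = sqrt(2) x
        double z2 = sq2 * x2 / r22;
        double z1 = (sq2 * x1 - r12 * z2) / r11;
        arma::vec gtmp(2); arma::mat Htmp(2, 2);
        double fq = fval(b0 + z1, b1 + z2, false, gtmp, Htmp);
        acc += gh_w[q1] * gh_w[q2] *
          std::exp(fq - f0 + x1 * x1 + x2 * x2);
      }
    }
    if (!(acc > 0.0) || !std::isfinite(acc)) { bad = true; break; }
    lli[i] = f0 + std::log(2.0 / (r11 * r22)) + std::log(acc);
    modes(i, 0) = b0; modes(i, 1) = b1;
    if (want_modes) {
      Mout(i, 0) = m11; Mout(i, 1) = m12; Mout(i, 2) = m22;
    }
  }
  if (bad) return List::create(_["loglik"] = NA_REAL);
  List out = List::create(_["loglik"] = arma::accu(lli), _["lli"] = lli,
                          _["modes"] = modes);
  if (want_modes) out["curv"] = Mout;
  return out;
}
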