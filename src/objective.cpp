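// Fast negative log posterior and full analytic gradient.
// Mirrors the TMB model in modvelo.cpp exactly (same priors, same closed
// forms); the two implementations cross-validate each other in the tests.
//
// Gradient structure exploits two identities:
//   * time derivatives of the module solutions are the ODE right-hand sides
//     (d u/d t = alpha - beta u, d s/d t = beta u - gamma s), so cell-time
//     and switch-time gradients come for free;
//   * the derivative of a divided difference of exp(-x tau) with respect to
//     a node is the next-order divided difference with that node repeated,
//     so rate gradients are third divided differences (dd3).
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

static inline double phi1d(double x) {
  if (x < 1e-5) return 1.0 - x / 2 + x * x / 6 - x * x * x / 24;
  return -std::expm1(-x) / x;
}

// (exp(-r1 t)-exp(-r2 t))/(r2-r1), symmetric, stable
static inline double dexp2d(double r1, double r2, double tau) {
  double rmin = std::min(r1, r2), dr = std::fabs(r1 - r2);
  return tau * std::exp(-rmin * tau) * phi1d(dr * tau);
}

// second divided difference of exp(-x tau); positive
static inline double dd2d(double a, double b, double c, double tau) {
  double x1 = std::min(a, std::min(b, c));
  double x3 = std::max(a, std::max(b, c));
  double x2 = a + b + c - x1 - x3;
  double spread = (x3 - x1) * tau;
  if (spread < 1e-3) {
    double d1 = (x2 - x1) * tau, d2 = (x3 - x1) * tau;
    return tau * tau * std::exp(-x1 * tau) *
           (0.5 - (d1 + d2) / 6 + (d1 * d1 + d2 * d2 + d1 * d2) / 24 -
            (d1 * d1 * d1 + d2 * d2 * d2 + d1 * d1 * d2 + d1 * d2 * d2) / 120);
  }
  return (dexp2d(x1, x2, tau) - dexp2d(x2, x3, tau)) / (x3 - x1);
}

// third divided difference of exp(-x tau); negative
static inline double dd3d(double a, double b, double c, double d, double tau) {
  double x[4] = {a, b, c, d};
  std::sort(x, x + 4);
  double spread = (x[3] - x[0]) * tau;
  if (spread < 1e-3) {
    double d1 = (x[1] - x[0]) * tau, d2 = (x[2] - x[0]) * tau,
           d3 = (x[3] - x[0]) * tau;
    double s1 = d1 + d2 + d3;
    double s2 = d1 * d1 + d2 * d2 + d3 * d3 + d1 * d2 + d1 * d3 + d2 * d3;
    double s3 = d1 * d1 * d1 + d2 * d2 * d2 + d3 * d3 * d3 +
                d1 * d1 * (d2 + d3) + d2 * d2 * (d1 + d3) +
                d3 * d3 * (d1 + d2) + d1 * d2 * d3;
    return -tau * tau * tau * std::exp(-x[0] * tau) *
           (1.0 / 6 - s1 / 24 + s2 / 120 - s3 / 720);
  }
  return (dd2d(x[1], x[2], x[3], tau) - dd2d(x[0], x[1], x[2], tau)) /
         (x[3] - x[0]);
}

static inline double nldens_norm(double x, double mu, double sig, double &g) {
  double z = (x - mu) / sig;
  g = z / sig;
  return 0.5 * LOG2PI + std::log(sig) + 0.5 * z * z;
}

static List mv_nll_impl(NumericMatrix U, NumericMatrix S, IntegerVector batch,
                double t_max, double tps, int use_soup,
                NumericVector z_t, NumericVector z_on, NumericVector log_dT,
                NumericVector log_lam_on, NumericVector log_lam_off,
                NumericVector log_beta, NumericVector log_gamma,
                NumericMatrix log_ahat, NumericVector log_l_c, double log_l_u,
                NumericMatrix log_a, NumericMatrix log_soup_u,
                NumericMatrix log_soup_s, NumericVector hyper) {
  const int C = U.nrow(), G = U.ncol(), M = z_on.size();
  const double floor_ = 1e-6;
  double nll = 0.0;

  // hyperparameters: mu_beta, log_sig_beta, mu_gamma, log_sig_gamma,
  // mu_ahat, log_sig_ahat, mu_a, log_sig_a, log_sig_lc
  const double mu_beta = hyper[0], sig_beta = std::exp(hyper[1]);
  const double mu_gamma = hyper[2], sig_gamma = std::exp(hyper[3]);
  const double mu_ahat = hyper[4], sig_ahat = std::exp(hyper[5]);
  const double mu_a = hyper[6], sig_a = std::exp(hyper[7]);
  const double sig_lc = std::exp(hyper[8]);

  // cell time: T_c = exp(z_t), log-normal prior with sd tps on the log
  // scale centred so the prior mean time is t_max / 2
  const double mu_t0 = std::log(t_max / 2) - 0.5 * tps * tps;
  std::vector<double> T_c(C), l_c(C);
  for (int c = 0; c < C; c++) {
    T_c[c] = std::exp(z_t[c]);
    l_c[c] = std::exp(log_l_c[c]);
  }
  std::vector<double> beta(G), gamma(G), a_u(G), a_s(G);
  for (int g = 0; g < G; g++) {
    beta[g] = std::exp(log_beta[g]);
    gamma[g] = std::exp(log_gamma[g]);
    a_u[g] = std::exp(log_a(g, 0));
    a_s[g] = std::exp(log_a(g, 1));
  }
  const double l_u = std::exp(log_l_u);
  std::vector<double> lam_n(M), lam_f(M), Ton(M), dTv(M), Toff(M), sig_on(M);
  for (int m = 0; m < M; m++) {
    lam_n[m] = std::exp(log_lam_on[m]);
    lam_f[m] = std::exp(log_lam_off[m]);
    double s = 1.0 / (1.0 + std::exp(-z_on[m]));
    sig_on[m] = s;
    Ton[m] = 2 * t_max * s;  // switch-on uniform over [0, 2 t_max]
    dTv[m] = std::exp(log_dT[m]);
    Toff[m] = Ton[m] + dTv[m];
  }

  // ---- forward pass: biological expectations -------------------------------
  std::vector<double> uB(C * (size_t)G, 0.0), sB(C * (size_t)G, 0.0);
  for (int m = 0; m < M; m++) {
    double ln = lam_n[m], lf = lam_f[m], dT = dTv[m];
    std::vector<double> u0(G), s0(G), alf0(G);
    double F = ln * dT * phi1d(ln * dT);
    for (int g = 0; g < G; g++) {
      double A = std::exp(log_ahat(m, g)), b = beta[g], gm = gamma[g];
      u0[g] = A * (dT * phi1d(b * dT) - dexp2d(ln, b, dT));
      s0[g] = A * (dT * phi1d(gm * dT) - dexp2d(b, gm, dT) -
                   b * dd2d(ln, b, gm, dT));
      alf0[g] = A * F;
    }
    for (int c = 0; c < C; c++) {
      double t = T_c[c];
      if (t <= Ton[m]) continue;
      if (t <= Toff[m]) {
        double tau = t - Ton[m];
        for (int g = 0; g < G; g++) {
          double A = std::exp(log_ahat(m, g)), b = beta[g], gm = gamma[g];
          uB[c + (size_t)C * g] +=
              A * (tau * phi1d(b * tau) - dexp2d(ln, b, tau));
          sB[c + (size_t)C * g] +=
              A * (tau * phi1d(gm * tau) - dexp2d(b, gm, tau) -
                   b * dd2d(ln, b, gm, tau));
        }
      } else {
        double tau2 = t - Toff[m];
        for (int g = 0; g < G; g++) {
          double b = beta[g], gm = gamma[g];
          uB[c + (size_t)C * g] +=
              u0[g] * std::exp(-b * tau2) + alf0[g] * dexp2d(lf, b, tau2);
          sB[c + (size_t)C * g] +=
              s0[g] * std::exp(-gm * tau2) +
              b * u0[g] * dexp2d(b, gm, tau2) +
              b * alf0[g] * dd2d(lf, b, gm, tau2);
        }
      }
    }
  }

  // ---- likelihood and measurement gradients --------------------------------
  double nll_kin_mark = nll;  // likelihood starts here
  std::vector<double> Wu(C * (size_t)G), Ws(C * (size_t)G);
  NumericVector g_z_t(C), g_log_l_c(C);
  NumericMatrix g_log_a(G, 2);
  NumericMatrix g_soup_u(log_soup_u.nrow(), use_soup ? G : 1);
  NumericMatrix g_soup_s(log_soup_s.nrow(), use_soup ? G : 1);
  double g_log_l_u = 0.0;
  std::vector<double> g_T(C, 0.0);
  for (int g = 0; g < G; g++) {
    double au = a_u[g], as_ = a_s[g];
    for (int c = 0; c < C; c++) {
      int e = batch[c];
      double su = use_soup ? std::exp(log_soup_u(e, g)) : 0.0;
      double ss = use_soup ? std::exp(log_soup_s(e, g)) : 0.0;
      double lcu = l_c[c] * l_u, lcs = l_c[c];
      double mu_u = lcu * (su + uB[c + (size_t)C * g]) + floor_;
      double mu_s = lcs * (ss + sB[c + (size_t)C * g]) + floor_;
      double xu = U(c, g), xs = S(c, g);
      nll -= R::lgammafn(xu + au) - R::lgammafn(au) - R::lgammafn(xu + 1) +
             au * (std::log(au) - std::log(au + mu_u)) +
             xu * (std::log(mu_u) - std::log(au + mu_u));
      nll -= R::lgammafn(xs + as_) - R::lgammafn(as_) - R::lgammafn(xs + 1) +
             as_ * (std::log(as_) - std::log(as_ + mu_s)) +
             xs * (std::log(mu_s) - std::log(as_ + mu_s));
      double wu = xu / mu_u - (au + xu) / (au + mu_u);
      double ws = xs / mu_s - (as_ + xs) / (as_ + mu_s);
      Wu[c + (size_t)C * g] = -wu * lcu;
      Ws[c + (size_t)C * g] = -ws * lcs;
      g_log_l_c[c] += -wu * (mu_u - floor_) - ws * (mu_s - floor_);
      g_log_l_u += -wu * (mu_u - floor_);
      g_log_a(g, 0) -= au * (R::digamma(xu + au) - R::digamma(au) +
                             std::log(au) + 1.0 - std::log(au + mu_u) -
                             (au + xu) / (au + mu_u));
      g_log_a(g, 1) -= as_ * (R::digamma(xs + as_) - R::digamma(as_) +
                              std::log(as_) + 1.0 - std::log(as_ + mu_s) -
                              (as_ + xs) / (as_ + mu_s));
      if (use_soup) {
        g_soup_u(e, g) += -wu * lcu * su;
        g_soup_s(e, g) += -ws * lcs * ss;
      }
    }
  }

  double nll_lik = nll - nll_kin_mark;

  // ---- backward pass through the kinetics ----------------------------------
  NumericVector g_z_on(M), g_log_dT(M), g_lam_on(M), g_lam_off(M);
  NumericVector g_log_beta(G), g_log_gamma(G);
  NumericMatrix g_log_ahat(M, G);
  std::vector<double> gTon(M, 0.0), gdT(M, 0.0), gln(M, 0.0), glf(M, 0.0);
  std::vector<double> gb(G, 0.0), gg(G, 0.0);

  for (int m = 0; m < M; m++) {
    double ln = lam_n[m], lf = lam_f[m], dT = dTv[m];
    double F = ln * dT * phi1d(ln * dT);
    double e_ln_dT = std::exp(-ln * dT);
    // per-gene quantities at the switch-off boundary
    std::vector<double> u0(G), s0(G), alf0(G), dRu0b(G), dRs0b(G), dRs0g(G),
        dRu0l(G), dRs0l(G), u0p(G), s0p(G);
    double alf0p_overA = ln * e_ln_dT, dalf0l_overA = dT * e_ln_dT;
    std::vector<double> Avec(G);
    for (int g = 0; g < G; g++) {
      double A = std::exp(log_ahat(m, g)), b = beta[g], gm = gamma[g];
      Avec[g] = A;
      double D_lb0 = dexp2d(ln, b, dT), D_bg0 = dexp2d(b, gm, dT);
      double DD2_lbg0 = dd2d(ln, b, gm, dT);
      double Ru0 = dT * phi1d(b * dT) - D_lb0;
      double Rs0 = dT * phi1d(gm * dT) - D_bg0 - b * DD2_lbg0;
      u0[g] = A * Ru0;
      s0[g] = A * Rs0;
      alf0[g] = A * F;
      dRu0b[g] = -dd2d(0, b, b, dT) + dd2d(ln, b, b, dT);
      dRs0b[g] = dd2d(b, b, gm, dT) - DD2_lbg0 - b * dd3d(ln, b, b, gm, dT);
      dRs0g[g] = -dd2d(0, gm, gm, dT) + dd2d(b, gm, gm, dT) -
                 b * dd3d(ln, b, gm, gm, dT);
      dRu0l[g] = dd2d(ln, ln, b, dT);
      dRs0l[g] = -b * dd3d(ln, ln, b, gm, dT);
      u0p[g] = A * F - b * u0[g];
      s0p[g] = b * u0[g] - gm * s0[g];
    }
    for (int c = 0; c < C; c++) {
      double t = T_c[c];
      if (t <= Ton[m]) continue;
      if (t <= Toff[m]) {
        double tau = t - Ton[m];
        double e_ln = std::exp(-ln * tau);
        for (int g = 0; g < G; g++) {
          double A = Avec[g], b = beta[g], gm = gamma[g];
          double gu = Wu[c + (size_t)C * g], gs = Ws[c + (size_t)C * g];
          double D_lb = dexp2d(ln, b, tau), D_bg = dexp2d(b, gm, tau);
          double DD2_lbg = dd2d(ln, b, gm, tau);
          double u = A * (tau * phi1d(b * tau) - D_lb);
          double s = A * (tau * phi1d(gm * tau) - D_bg - b * DD2_lbg);
          double alf = A * (1.0 - e_ln);
          double rtu = alf - b * u, rts = b * u - gm * s;
          g_log_ahat(m, g) += gu * u + gs * s;
          double gt = gu * rtu + gs * rts;
          g_T[c] += gt;
          gTon[m] -= gt;
          gln[m] += gu * A * dd2d(ln, ln, b, tau) -
                    gs * A * b * dd3d(ln, ln, b, gm, tau);
          gb[g] += gu * A * (-dd2d(0, b, b, tau) + dd2d(ln, b, b, tau)) +
                   gs * A * (dd2d(b, b, gm, tau) - DD2_lbg -
                             b * dd3d(ln, b, b, gm, tau));
          gg[g] += gs * A * (-dd2d(0, gm, gm, tau) + dd2d(b, gm, gm, tau) -
                             b * dd3d(ln, b, gm, gm, tau));
        }
      } else {
        double tau2 = t - Toff[m];
        double e_lf = std::exp(-lf * tau2);
        for (int g = 0; g < G; g++) {
          double A = Avec[g], b = beta[g], gm = gamma[g];
          double gu = Wu[c + (size_t)C * g], gs = Ws[c + (size_t)C * g];
          double e2b = std::exp(-b * tau2), e2g = std::exp(-gm * tau2);
          double D_fb = dexp2d(lf, b, tau2), D_bg2 = dexp2d(b, gm, tau2);
          double DD2_fbg = dd2d(lf, b, gm, tau2);
          double u = u0[g] * e2b + alf0[g] * D_fb;
          double s = s0[g] * e2g + b * u0[g] * D_bg2 + b * alf0[g] * DD2_fbg;
          double alf = alf0[g] * e_lf;
          double rtu = alf - b * u, rts = b * u - gm * s;
          g_log_ahat(m, g) += gu * u + gs * s;
          double gt = gu * rtu + gs * rts;
          g_T[c] += gt;
          gTon[m] -= gt;
          gdT[m] +=
              gu * (u0p[g] * e2b + Avec[g] * alf0p_overA * D_fb - rtu) +
              gs * (s0p[g] * e2g + b * u0p[g] * D_bg2 +
                    b * Avec[g] * alf0p_overA * DD2_fbg - rts);
          double du0l = A * dRu0l[g], dal = A * dalf0l_overA;
          gln[m] += gu * (du0l * e2b + dal * D_fb) +
                    gs * (A * dRs0l[g] * e2g + b * du0l * D_bg2 +
                          b * dal * DD2_fbg);
          glf[m] += -gu * alf0[g] * dd2d(lf, lf, b, tau2) +
                    gs * b * alf0[g] * dd3d(lf, lf, b, gm, tau2);
          gb[g] += gu * (A * dRu0b[g] * e2b - tau2 * u0[g] * e2b -
                         alf0[g] * dd2d(lf, b, b, tau2)) +
                   gs * (A * dRs0b[g] * e2g +
                         (u0[g] + b * A * dRu0b[g]) * D_bg2 -
                         b * u0[g] * dd2d(b, b, gm, tau2) +
                         alf0[g] * DD2_fbg +
                         b * alf0[g] * dd3d(lf, b, b, gm, tau2));
          gg[g] += gs * (A * dRs0g[g] * e2g - tau2 * s0[g] * e2g -
                         b * u0[g] * dd2d(b, gm, gm, tau2) +
                         b * alf0[g] * dd3d(lf, b, gm, gm, tau2));
        }
      }
    }
    // chain rules for module-level parameters
    g_z_on[m] = gTon[m] * 2 * t_max * sig_on[m] * (1.0 - sig_on[m]);
    g_log_dT[m] = gdT[m] * dT;
    g_lam_on[m] = gln[m] * ln;
    g_lam_off[m] = glf[m] * lf;
  }

  // ---- priors --------------------------------------------------------------
  double gdum;
  double h_mu_beta = 0, h_ls_beta = 0, h_mu_gamma = 0, h_ls_gamma = 0;
  double h_mu_ahat = 0, h_ls_ahat = 0, h_mu_a = 0, h_ls_a = 0, h_ls_lc = 0;
  for (int c = 0; c < C; c++) {
    double gprior;
    nll += nldens_norm(z_t[c], mu_t0, tps, gprior);
    g_z_t[c] = g_T[c] * T_c[c] + gprior;
    double gi;
    nll += nldens_norm(log_l_c[c], 0.0, sig_lc, gi);
    g_log_l_c[c] += gi;
    double zi = log_l_c[c] / sig_lc;
    h_ls_lc += 1.0 - zi * zi;
  }
  for (int m = 0; m < M; m++) {
    double z1 = z_on[m];
    nll += z1 + 2.0 * std::log1p(std::exp(-z1));
    g_z_on[m] += 2.0 / (1.0 + std::exp(-z1)) - 1.0;
    double gi;
    nll += nldens_norm(log_dT[m], std::log(0.45 * t_max), 1.0, gi);
    g_log_dT[m] += gi;
    nll += nldens_norm(log_lam_on[m], std::log(1.5), 0.7, gi);
    g_lam_on[m] += gi;
    nll += nldens_norm(log_lam_off[m], std::log(1.5), 0.7, gi);
    g_lam_off[m] += gi;
  }
  for (int g = 0; g < G; g++) {
    double gi, z;
    nll += nldens_norm(log_beta[g], mu_beta, sig_beta, gi);
    g_log_beta[g] = gb[g] * beta[g] + gi;
    h_mu_beta -= gi;
    z = (log_beta[g] - mu_beta) / sig_beta;
    h_ls_beta += 1.0 - z * z;
    nll += nldens_norm(log_gamma[g], mu_gamma, sig_gamma, gi);
    g_log_gamma[g] = gg[g] * gamma[g] + gi;
    h_mu_gamma -= gi;
    z = (log_gamma[g] - mu_gamma) / sig_gamma;
    h_ls_gamma += 1.0 - z * z;
    for (int m = 0; m < M; m++) {
      nll += nldens_norm(log_ahat(m, g), mu_ahat, sig_ahat, gi);
      g_log_ahat(m, g) += gi;
      h_mu_ahat -= gi;
      z = (log_ahat(m, g) - mu_ahat) / sig_ahat;
      h_ls_ahat += 1.0 - z * z;
    }
    for (int j = 0; j < 2; j++) {
      nll += nldens_norm(log_a(g, j), mu_a, sig_a, gi);
      g_log_a(g, j) += gi;
      h_mu_a -= gi;
      z = (log_a(g, j) - mu_a) / sig_a;
      h_ls_a += 1.0 - z * z;
    }
  }
  if (use_soup) {
    for (int e = 0; e < log_soup_u.nrow(); e++)
      for (int g = 0; g < G; g++) {
        double gi;
        nll += nldens_norm(log_soup_u(e, g), std::log(0.05), 1.5, gi);
        g_soup_u(e, g) += gi;
        nll += nldens_norm(log_soup_s(e, g), std::log(0.05), 1.5, gi);
        g_soup_s(e, g) += gi;
      }
  }
  double g_llu_prior;
  nll += nldens_norm(log_l_u, std::log(0.5), 1.0, g_llu_prior);
  g_log_l_u += g_llu_prior;
  // hyperpriors
  NumericVector g_hyper(9);
  double gi;
  nll += nldens_norm(mu_beta, std::log(0.5), 1.0, gi);
  g_hyper[0] = h_mu_beta + gi;
  nll += nldens_norm(hyper[1], std::log(0.7), 0.5, gi);
  g_hyper[1] = h_ls_beta + gi;
  nll += nldens_norm(mu_gamma, std::log(0.5), 1.0, gi);
  g_hyper[2] = h_mu_gamma + gi;
  nll += nldens_norm(hyper[3], std::log(0.7), 0.5, gi);
  g_hyper[3] = h_ls_gamma + gi;
  nll += nldens_norm(mu_ahat, 0.0, 2.0, gi);
  g_hyper[4] = h_mu_ahat + gi;
  nll += nldens_norm(hyper[5], std::log(1.5), 0.5, gi);
  g_hyper[5] = h_ls_ahat + gi;
  nll += nldens_norm(mu_a, std::log(5.0), 1.5, gi);
  g_hyper[6] = h_mu_a + gi;
  nll += nldens_norm(hyper[7], std::log(0.7), 0.5, gi);
  g_hyper[7] = h_ls_a + gi;
  nll += nldens_norm(hyper[8], std::log(0.3), 0.3, gi);
  g_hyper[8] = h_ls_lc + gi;
  (void)gdum;

  List grad = List::create(
      _["z_t"] = g_z_t, _["z_on"] = g_z_on, _["log_dT"] = g_log_dT,
      _["log_lam_on"] = g_lam_on, _["log_lam_off"] = g_lam_off,
      _["log_beta"] = g_log_beta, _["log_gamma"] = g_log_gamma,
      _["log_ahat"] = g_log_ahat, _["log_l_c"] = g_log_l_c,
      _["log_l_u"] = g_log_l_u, _["log_a"] = g_log_a,
      _["log_soup_u"] = g_soup_u, _["log_soup_s"] = g_soup_s,
      _["hyper"] = g_hyper);
  return List::create(_["value"] = nll, _["gradient"] = grad,
                      _["loglik"] = -nll_lik, _["uB"] = wrap(uB),
                      _["sB"] = wrap(sB));
}

// .Call entry (registered in modvelo.cpp alongside the TMB entry points):
// takes a list of data fields and a list of parameter blocks.
extern "C" SEXP mv_nll_call(SEXP data_, SEXP par_) {
BEGIN_RCPP
  List d(data_), p(par_);
  return wrap(mv_nll_impl(
      as<NumericMatrix>(d["U"]), as<NumericMatrix>(d["S"]),
      as<IntegerVector>(d["batch"]), as<double>(d["t_max"]),
      as<double>(d["time_prior_scale"]), as<int>(d["use_soup"]),
      as<NumericVector>(p["z_t"]), as<NumericVector>(p["z_on"]),
      as<NumericVector>(p["log_dT"]), as<NumericVector>(p["log_lam_on"]),
      as<NumericVector>(p["log_lam_off"]), as<NumericVector>(p["log_beta"]),
      as<NumericVector>(p["log_gamma"]), as<NumericMatrix>(p["log_ahat"]),
      as<NumericVector>(p["log_l_c"]), as<double>(p["log_l_u"]),
      as<NumericMatrix>(p["log_a"]), as<NumericMatrix>(p["log_soup_u"]),
      as<NumericMatrix>(p["log_soup_s"]), as<NumericVector>(p["hyper"])));
END_RCPP
}
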