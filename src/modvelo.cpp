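// Negative log posterior of the modular RNA-velocity model.
// Kinetics use stable divided-difference closed forms matching the R
// implementations in R/kinetics.R; all branches are CppAD-safe (CondExp with
// guarded denominators) so the tape stays valid as parameters move.
#include <TMB.hpp>

template <class Type>
Type clamp0(Type x) {
  return CppAD::CondExpGt(x, Type(0), x, Type(0));
}

// (1 - exp(-x))/x for x >= 0
template <class Type>
Type phi1(Type x) {
  Type xg = CppAD::CondExpLt(x, Type(1e-5), Type(1), x);
  Type big = (Type(1) - exp(-xg)) / xg;
  Type ser = Type(1) - x / Type(2) + x * x / Type(6) - x * x * x / Type(24);
  return CppAD::CondExpLt(x, Type(1e-5), ser, big);
}

// (exp(-r1 t) - exp(-r2 t)) / (r2 - r1), symmetric, stable
template <class Type>
Type dexp2(Type r1, Type r2, Type tau) {
  Type rmin = CppAD::CondExpLt(r1, r2, r1, r2);
  Type dr = CppAD::CondExpLt(r1, r2, r2 - r1, r1 - r2);
  return tau * exp(-rmin * tau) * phi1(dr * tau);
}

// second divided difference of x -> exp(-x tau) at nodes a, b, c
template <class Type>
Type dd2exp(Type a, Type b, Type c, Type tau) {
  Type x1 = CppAD::CondExpLt(a, b, a, b);
  x1 = CppAD::CondExpLt(x1, c, x1, c);
  Type x3 = CppAD::CondExpGt(a, b, a, b);
  x3 = CppAD::CondExpGt(x3, c, x3, c);
  Type x2 = a + b + c - x1 - x3;
  Type spread = (x3 - x1) * tau;
  Type d1 = (x2 - x1) * tau, d2 = (x3 - x1) * tau;
  Type ser = tau * tau * exp(-x1 * tau) *
             (Type(0.5) - (d1 + d2) / Type(6) +
              (d1 * d1 + d2 * d2 + d1 * d2) / Type(24) -
              (d1 * d1 * d1 + d2 * d2 * d2 + d1 * d1 * d2 + d1 * d2 * d2) /
                  Type(120));
  Type denom = CppAD::CondExpLt(spread, Type(1e-3), Type(1), x3 - x1);
  Type diff = (dexp2(x1, x2, tau) - dexp2(x2, x3, tau)) / denom;
  return CppAD::CondExpLt(spread, Type(1e-3), ser, diff);
}

template <class Type>
Type nldens_logistic(Type x, Type scale) {
  // -log density of logistic(0, scale)
  Type z = x / scale;
  return z + Type(2) * log(Type(1) + exp(-z)) + log(scale);
}

template <class Type>
Type objective_function<Type>::operator()() {
  DATA_MATRIX(U);          // cells x genes, unspliced
  DATA_MATRIX(S);          // cells x genes, spliced
  DATA_IVECTOR(batch);     // 0-based batch index per cell
  DATA_INTEGER(use_soup);  // 0/1
  DATA_SCALAR(t_max);
  DATA_SCALAR(time_prior_scale);  // logistic scale of the cell-time prior

  PARAMETER_VECTOR(z_t);        // C: cell times (logit scale)
  PARAMETER_VECTOR(z_on);       // M: switch-on times (logit scale)
  PARAMETER_VECTOR(log_dT);     // M: ON duration
  PARAMETER_VECTOR(log_lam_on);   // M
  PARAMETER_VECTOR(log_lam_off);  // M
  PARAMETER_VECTOR(log_beta);   // G
  PARAMETER_VECTOR(log_gamma);  // G
  PARAMETER_MATRIX(log_ahat);   // M x G
  PARAMETER_VECTOR(log_l_c);    // C: per-cell detection
  PARAMETER(log_l_u);           // unspliced-modality detection factor
  PARAMETER_MATRIX(log_a);      // G x 2 NB concentrations (u, s)
  PARAMETER_MATRIX(log_soup_u);  // E x G (mapped off when use_soup = 0)
  PARAMETER_MATRIX(log_soup_s);  // E x G
  // hierarchical hyperparameters
  PARAMETER(mu_beta);
  PARAMETER(log_sig_beta);
  PARAMETER(mu_gamma);
  PARAMETER(log_sig_gamma);
  PARAMETER(mu_ahat);
  PARAMETER(log_sig_ahat);
  PARAMETER(mu_a);
  PARAMETER(log_sig_a);
  PARAMETER(log_sig_lc);

  int C = U.rows(), G = U.cols(), M = z_on.size();
  Type nll = 0;

  vector<Type> T_c(C), l_c(C);
  for (int c = 0; c < C; c++) {
    T_c(c) = exp(z_t(c));  // log-normal cell time
    l_c(c) = exp(log_l_c(c));
  }
  vector<Type> beta = exp(log_beta), gamma = exp(log_gamma);
  Type l_u = exp(log_l_u);

  matrix<Type> uB(C, G), sB(C, G);
  uB.setZero();
  sB.setZero();

  for (int m = 0; m < M; m++) {
    Type lam_on = exp(log_lam_on(m)), lam_off = exp(log_lam_off(m));
    Type t_on = Type(2) * t_max * invlogit(z_on(m));
    Type dT = exp(log_dT(m));
    Type t_off = t_on + dT;
    // module state at switch-off (per gene), for the decay phase
    Type a0f = lam_on * dT * phi1(lam_on * dT);  // 1 - exp(-lam_on dT)
    vector<Type> u0(G), s0(G);
    for (int g = 0; g < G; g++) {
      Type ah = exp(log_ahat(m, g));
      u0(g) = ah * (dT * phi1(beta(g) * dT) - dexp2(lam_on, beta(g), dT));
      s0(g) = ah * (dT * phi1(gamma(g) * dT) - dexp2(beta(g), gamma(g), dT) -
                    beta(g) * dd2exp(lam_on, beta(g), gamma(g), dT));
    }
    for (int c = 0; c < C; c++) {
      Type tau = clamp0(CppAD::CondExpLt(T_c(c), t_off, T_c(c), t_off) - t_on);
      Type tau2 = clamp0(T_c(c) - t_off);
      Type isoff = CppAD::CondExpGt(T_c(c), t_off, Type(1), Type(0));
      Type e2lam = exp(-lam_off * tau2);
      for (int g = 0; g < G; g++) {
        Type ah = exp(log_ahat(m, g));
        Type b = beta(g), gm = gamma(g);
        // ON-phase response at tau
        Type u_on = ah * (tau * phi1(b * tau) - dexp2(lam_on, b, tau));
        Type s_on = ah * (tau * phi1(gm * tau) - dexp2(b, gm, tau) -
                          b * dd2exp(lam_on, b, gm, tau));
        // OFF-phase continuation at tau2
        Type a0 = ah * a0f;
        Type u_off = u0(g) * exp(-b * tau2) + a0 * dexp2(lam_off, b, tau2);
        Type s_off = s0(g) * exp(-gm * tau2) +
                     b * u0(g) * dexp2(b, gm, tau2) +
                     b * a0 * dd2exp(lam_off, b, gm, tau2);
        uB(c, g) += u_on + isoff * (u_off - u_on);
        sB(c, g) += s_on + isoff * (s_off - s_on);
      }
    }
  }

  REPORT(uB);
  REPORT(sB);

  // measurement expectations and NB likelihood
  Type floor_ = Type(1e-6);
  for (int c = 0; c < C; c++) {
    int e = batch(c);
    for (int g = 0; g < G; g++) {
      Type soup_u = use_soup ? exp(log_soup_u(e, g)) : Type(0);
      Type soup_s = use_soup ? exp(log_soup_s(e, g)) : Type(0);
      Type mu_u = l_c(c) * l_u * (soup_u + uB(c, g)) + floor_;
      Type mu_s = l_c(c) * (soup_s + sB(c, g)) + floor_;
      Type a_u = exp(log_a(g, 0)), a_s = exp(log_a(g, 1));
      nll -= dnbinom2(U(c, g), mu_u, mu_u + mu_u * mu_u / a_u, true);
      nll -= dnbinom2(S(c, g), mu_s, mu_s + mu_s * mu_s / a_s, true);
    }
  }

  // priors ------------------------------------------------------------------
  Type sig_beta = exp(log_sig_beta), sig_gamma = exp(log_sig_gamma);
  Type sig_ahat = exp(log_sig_ahat), sig_a = exp(log_sig_a);
  Type sig_lc = exp(log_sig_lc);
  Type mu_t0 = log(t_max / 2) - Type(0.5) * time_prior_scale * time_prior_scale;
  for (int c = 0; c < C; c++) {
    nll -= dnorm(z_t(c), mu_t0, time_prior_scale, true);
    nll -= dnorm(log_l_c(c), Type(0), sig_lc, true);
  }
  for (int m = 0; m < M; m++) {
    nll += nldens_logistic(z_on(m), Type(1));  // uniform switch-on time
    nll -= dnorm(log_dT(m), log(Type(0.45) * t_max), Type(1.0), true);
    nll -= dnorm(log_lam_on(m), log(Type(1.5)), Type(0.7), true);
    nll -= dnorm(log_lam_off(m), log(Type(1.5)), Type(0.7), true);
  }
  for (int g = 0; g < G; g++) {
    nll -= dnorm(log_beta(g), mu_beta, sig_beta, true);
    nll -= dnorm(log_gamma(g), mu_gamma, sig_gamma, true);
    for (int m = 0; m < M; m++)
      nll -= dnorm(log_ahat(m, g), mu_ahat, sig_ahat, true);
    nll -= dnorm(log_a(g, 0), mu_a, sig_a, true);
    nll -= dnorm(log_a(g, 1), mu_a, sig_a, true);
  }
  if (use_soup) {
    for (int e = 0; e < log_soup_u.rows(); e++)
      for (int g = 0; g < G; g++) {
        nll -= dnorm(log_soup_u(e, g), log(Type(0.05)), Type(1.5), true);
        nll -= dnorm(log_soup_s(e, g), log(Type(0.05)), Type(1.5), true);
      }
  }
  nll -= dnorm(log_l_u, log(Type(0.5)), Type(1), true);
  // hyperpriors
  nll -= dnorm(mu_beta, log(Type(0.5)), Type(1), true);
  nll -= dnorm(mu_gamma, log(Type(0.5)), Type(1), true);
  nll -= dnorm(mu_ahat, Type(0), Type(2), true);
  nll -= dnorm(mu_a, log(Type(5)), Type(1.5), true);
  nll -= dnorm(log_sig_beta, log(Type(0.7)), Type(0.5), true);
  nll -= dnorm(log_sig_gamma, log(Type(0.7)), Type(0.5), true);
  nll -= dnorm(log_sig_ahat, log(Type(1.5)), Type(0.5), true);
  nll -= dnorm(log_sig_a, log(Type(0.7)), Type(0.5), true);
  nll -= dnorm(log_sig_lc, log(Type(0.3)), Type(0.3), true);

  return nll;
}

// Combined registration: TMB entry points plus the fast objective in
// objective.cpp (dynamic lookup is disabled, so everything must be listed).
#include <R_ext/Rdynload.h>
extern "C" SEXP mv_nll_call(SEXP, SEXP);
extern "C" void R_init_modvelo(DllInfo *dll) {
  static const R_CallMethodDef CallEntries[] = {
      TMB_CALLDEFS,
      {"mv_nll_call", (DL_FUNC)&mv_nll_call, 2},
      {NULL, NULL, 0}};
  R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, (Rboolean)FALSE);
  TMB_CCALLABLES("modvelo");
}
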