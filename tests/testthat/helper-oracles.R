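# Shared fixtures and independent oracles, built in code at test time.

# numerical integration oracle for the module ODE system (one gene);
# integrates each phase separately with restarts at the exact switch times,
# so the adaptive solver never steps over a discontinuity
ode_module_oracle <- function(times, mk, beta, gamma) {
  f <- function(t, y, p) {
    list(c(p$lam * (p$ahat - y[1]),
           y[1] - beta * y[2],
           beta * y[2] - gamma * y[3]))
  }
  run <- function(y0, tt, lam, ahat) {
    deSolve::ode(y0, tt, f, list(lam = lam, ahat = ahat),
                 method = "lsoda", rtol = 1e-11,
                 atol = 1e-13)[, -1, drop = FALSE]
  }
  out <- matrix(0, length(times), 3)
  ton <- mk$t_on
  toff <- mk$t_off
  in_on <- times > ton & times <= toff
  on_times <- times[in_on]
  end_on <- if (is.finite(toff)) toff
            else if (length(on_times)) max(on_times) else ton
  tt_on <- sort(unique(c(ton, on_times, end_on)))
  sol_on <- if (length(tt_on) > 1)
    run(c(0, 0, 0), tt_on, mk$lambda_on, mk$target_rate[1])
  else matrix(0, 1, 3)
  out[in_on, ] <- sol_on[match(on_times, tt_on), , drop = FALSE]
  in_off <- times > toff
  if (any(in_off)) {
    y_off <- sol_on[match(toff, tt_on), ]
    tt_off <- sort(unique(c(toff, times[in_off])))
    sol_off <- run(y_off, tt_off, mk$lambda_off, 0)
    out[in_off, ] <- sol_off[match(times[in_off], tt_off), , drop = FALSE]
  }
  cbind(time = times, out)
}

# random single-gene module configuration; degenerate = NULL, "bg" (beta ==
# gamma) or "lb" (lambda_on == beta)
random_module_config <- function(degenerate = NULL) {
  beta <- exp(runif(1, log(0.1), log(2)))
  gamma <- exp(runif(1, log(0.1), log(2)))
  lam_on <- exp(runif(1, log(0.5), log(5)))
  if (identical(degenerate, "bg")) gamma <- beta
  if (identical(degenerate, "lb")) lam_on <- beta
  t_on <- runif(1, 0, 2)
  list(mk = module_kinetics(exp(runif(1, log(0.5), log(5))), lam_on,
                            exp(runif(1, log(0.5), log(5))), t_on,
                            t_on + runif(1, 2, 8)),
       gr = gene_rates(beta, gamma))
}

# one small fitted model shared across downstream tests (computed once)
cached_fit <- local({
  env <- new.env()
  function() {
    if (is.null(env$fit)) {
      env$sim <- simulate_counts(120, 40, 2, seed = 5)
      env$fit <- mv_fit(env$sim$data, n_modules = 2, n_samples = 10,
                        epochs = 250, seed = 1)
    }
    list(sim = env$sim, fit = env$fit)
  }
})
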