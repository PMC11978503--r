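# Inference: objective correctness (dual-route against the autodiff oracle),
# determinism, convergence contract, module-count heuristic and posterior
# time summaries.

make_small_problem <- function(seed = 3, C = 40, G = 12, M = 2) {
  sim <- simulate_counts(C, G, M, seed = seed)
  d <- sim$data
  init <- modvelo:::mv_init_params(d, M, 20)
  skel <- modvelo:::mv_pl_compact(init)
  ob <- modvelo:::mv_make_objective(d, 20, 0.85, FALSE, skel)
  list(sim = sim, d = d, init = init, skel = skel, ob = ob,
       par = modvelo:::mv_flatten(skel, FALSE))
}

test_that("analytic objective and gradient match the autodiff oracle", {
  p <- make_small_problem()
  tmb_data <- list(U = as.matrix(p$d$unspliced), S = as.matrix(p$d$spliced),
                   batch = p$d$batch - 1L, use_soup = 0L, t_max = 20,
                   time_prior_scale = 0.85)
  map <- list(log_soup_u = factor(rep(NA, length(p$init$log_soup_u))),
              log_soup_s = factor(rep(NA, length(p$init$log_soup_s))))
  obj <- TMB::MakeADFun(tmb_data, p$init, map = map, DLL = "modvelo",
                        silent = TRUE)
  set.seed(5)
  for (k in 1:3) {
    par <- p$par + rnorm(length(p$par), 0, 0.35)
    expect_equal(p$ob$fn(par), obj$fn(par), tolerance = 1e-7)
    g1 <- p$ob$gr(par)
    g2 <- as.vector(obj$gr(par))
    expect_lt(max(abs(g1 - g2) / pmax(abs(g2), 1)), 1e-7)
  }
})

test_that("analytic gradient matches central finite differences", {
  p <- make_small_problem(seed = 6)
  set.seed(2)
  par <- p$par + rnorm(length(p$par), 0, 0.2)
  g <- p$ob$gr(par)
  idx <- sample(length(par), 12)
  for (i in idx) {
    h <- 1e-5 * max(1, abs(par[i]))
    up <- par; up[i] <- par[i] + h
    dn <- par; dn[i] <- par[i] - h
    fd <- (p$ob$fn(up) - p$ob$fn(dn)) / (2 * h)
    expect_equal(g[i], fd, tolerance = 1e-4)
  }
})

test_that("fits are bitwise deterministic given seed and data", {
  sim <- simulate_counts(50, 15, 2, seed = 2)
  f1 <- mv_fit(sim$data, n_modules = 2, n_samples = 3, epochs = 60, seed = 7)
  f2 <- mv_fit(sim$data, n_modules = 2, n_samples = 3, epochs = 60, seed = 7)
  expect_identical(f1$elbo_trace, f2$elbo_trace)
  expect_identical(f1$posterior$beta, f2$posterior$beta)
  expect_identical(f1$posterior$t, f2$posterior$t)
  s1 <- mv_fit(sim$data, n_modules = 2, n_samples = 2, method = "svi",
               svi_steps = 150, seed = 7)
  s2 <- mv_fit(sim$data, n_modules = 2, n_samples = 2, method = "svi",
               svi_steps = 150, seed = 7)
  expect_identical(s1$elbo_trace, s2$elbo_trace)
  expect_identical(s1$posterior$t, s2$posterior$t)
})

test_that("optimization trace is non-decreasing after smoothing", {
  cf <- cached_fit()
  tr <- cf$fit$elbo_trace
  n <- length(tr)
  last <- tr[seq(floor(0.8 * n), n)]
  # running maximum of the tail should be flat-ish: no late collapse
  smooth <- stats::runmed(last, 21)
  expect_gt(utils::tail(smooth, 1), smooth[1] - 1e-6 * abs(smooth[1]))
  # posterior samples respect ordering and positivity constraints
  expect_true(all(cf$fit$posterior$t_on < cf$fit$posterior$t_off))
  expect_true(all(cf$fit$posterior$beta > 0))
  expect_true(all(cf$fit$posterior$gamma > 0))
  expect_true(all(cf$fit$posterior$lambda_on > 0))
})

test_that("permutation-invariant summaries are stable across SVI seeds", {
  # needs a dataset with real dynamic signal and enough posterior draws that
  # the posterior-mean times are not dominated by Monte-Carlo error
  sim <- simulate_counts(150, 60, 2, seed = 12)
  f1 <- mv_fit(sim$data, n_modules = 2, n_samples = 200, method = "svi",
               svi_steps = 3000, seed = 1)
  f2 <- mv_fit(sim$data, n_modules = 2, n_samples = 200, method = "svi",
               svi_steps = 3000, seed = 2)
  expect_gte(cor(f1$posterior_mean$t, f2$posterior_mean$t,
                 method = "spearman"), 0.9)
  expect_gte(cor(f1$posterior_mean$beta, f2$posterior_mean$beta,
                 method = "spearman"), 0.9)
  tot1 <- colSums(f1$posterior_mean$alpha_hat)
  tot2 <- colSums(f2$posterior_mean$alpha_hat)
  expect_gte(cor(tot1, tot2, method = "spearman"), 0.9)
})

test_that("fit configuration errors are caught", {
  sim <- simulate_counts(12, 8, 1, seed = 1)
  expect_error(mv_fit(sim$data, n_modules = 50), "more modules than cells")
})

test_that("module-count heuristic honors overrides and tracks structure", {
  sim <- simulate_counts(60, 20, 2, seed = 3)
  expect_identical(select_num_modules(sim$data, n_modules = 7), 7L)
  # well-separated programs: within +-2 of the true module count
  for (k in c(2, 3)) {
    s <- simulate_counts(250, 80, k, seed = 40 + k,
                         cell_times = "clustered")
    expect_lte(abs(select_num_modules(s$data) - k), 2)
  }
  # steady-state single-cluster data: small M
  ss <- simulate_counts(200, 80, 2, seed = 9, cell_times = "steady_state")
  expect_lte(select_num_modules(ss$data), 3)
})

test_that("posterior time CV summarizes sample dispersion", {
  fake <- structure(list(
    posterior = list(t = rbind(c(1, 2, 5), c(3, 2, 5))),
    n_samples = 2L,
    data = list(spliced = matrix(0, 3, 1,
                                 dimnames = list(paste0("c", 1:3), "g")))),
    class = "mv_fit")
  cv <- posterior_time_cv(fake)
  expect_equal(cv$cv[1], sd(c(1, 3)) / 2)   # sample sd, n-1 divisor
  expect_equal(cv$cv[1], 0.70710678, tolerance = 1e-7)
  expect_equal(cv$cv[2:3], c(0, 0))
  fake$posterior$t[, 1] <- c(-1, 1)
  expect_true(is.na(posterior_time_cv(fake)$cv[1]))
})

test_that("tidy and glance summarize a fit", {
  cf <- cached_fit()
  td <- generics::tidy(cf$fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  expect_identical(sum(td$term == "beta"), 40L)
  gl <- generics::glance(cf$fit)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_modules, 2L)
  expect_s3_class(ggplot2::autoplot(cf$fit), "ggplot")
})
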