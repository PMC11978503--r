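# Closed-form module kinetics against frozen values and the numerical
# integration oracle.

test_that("transcription rate follows the relaxation closed form", {
  mk <- module_kinetics(2, lambda_on = 1, lambda_off = 1, t_on = 0)
  expect_equal(module_alpha(1, mk)[1, 1], 2 * (1 - exp(-1)),
               tolerance = 1e-12)
  # inactive before switch-on
  mk2 <- module_kinetics(2, 1, 1, t_on = 3, t_off = 10)
  expect_equal(module_alpha(c(0, 1, 2.999), mk2)[, 1], rep(0, 3))
  # relaxes to the target rate when ON forever
  expect_equal(module_alpha(100, mk)[1, 1], 2, tolerance = 1e-9)
})

test_that("unspliced and spliced solutions match frozen special cases", {
  step <- module_kinetics(1, 1e8, 1, t_on = 0)  # near-instant activation
  gr <- gene_rates(1, 1)
  expect_equal(module_unspliced(1, step, gr)[1, 1], 1 - exp(-1),
               tolerance = 1e-7)
  # repeated eigenvalue beta == gamma: s(t) = 1 - e^-t - t e^-t
  expect_equal(module_spliced(1, step, gr)[1, 1], 1 - 2 * exp(-1),
               tolerance = 1e-7)
  expect_equal(module_unspliced(c(-5, 0), step, gr)[, 1], c(0, 0))
  # ODE fixed points
  mk <- module_kinetics(2, 1, 1, t_on = 0)
  gr2 <- gene_rates(0.5, 0.25)
  t_inf <- 50 / 0.25
  expect_equal(module_unspliced(t_inf, mk, gr2)[1, 1], 2 / 0.5,
               tolerance = 1e-9)
  expect_equal(module_spliced(t_inf, mk, gr2)[1, 1], 2 / 0.25,
               tolerance = 1e-9)
})

test_that("velocity equals beta*u - gamma*s and vanishes at steady state", {
  step <- module_kinetics(1, 1e8, 1, t_on = 0)
  gr <- gene_rates(1, 1)
  expect_equal(velocity(1, step, gr)[1, 1], exp(-1), tolerance = 1e-7)
  mk <- module_kinetics(2, 1, 1, t_on = 0)
  gr2 <- gene_rates(0.5, 0.25)
  expect_lt(abs(velocity(50 / 0.25, mk, gr2)[1, 1]), 1e-9)
  # central finite difference of the spliced solution
  set.seed(42)
  for (i in 1:10) {
    cfg <- random_module_config()
    t0 <- runif(1, cfg$mk$t_on + 0.2, cfg$mk$t_off + 3)
    h <- 1e-5
    fd <- (module_spliced(t0 + h, cfg$mk, cfg$gr)[1, 1] -
             module_spliced(t0 - h, cfg$mk, cfg$gr)[1, 1]) / (2 * h)
    expect_equal(velocity(t0, list(cfg$mk), cfg$gr)[1, 1], fd,
                 tolerance = 1e-6)
  }
})

test_that("closed forms agree with numerical ODE integration", {
  skip_if_not_installed("deSolve")
  set.seed(1)
  for (i in 1:25) {
    deg <- if (i %% 5 == 0) "bg" else if (i %% 7 == 0) "lb" else NULL
    cfg <- random_module_config(deg)
    times <- sort(c(0, runif(15, 0, 3 * cfg$mk$t_off)))
    num <- ode_module_oracle(times, cfg$mk, cfg$gr$beta, cfg$gr$gamma)
    scale <- pmax(abs(num[, 2:4]), 1e-4)
    got <- cbind(module_alpha(times, cfg$mk)[, 1],
                 module_unspliced(times, cfg$mk, cfg$gr)[, 1],
                 module_spliced(times, cfg$mk, cfg$gr)[, 1])
    expect_lt(max(abs(got - num[, 2:4]) / scale), 1e-6)
  }
})

test_that("near-degenerate rate gaps stay numerically stable", {
  skip_if_not_installed("deSolve")
  set.seed(3)
  for (gap in c(1e-3, 1e-6, 0)) {
    beta <- 0.8
    gamma <- beta * (1 + gap)
    mk <- module_kinetics(1.5, 2.5, 1.2, t_on = 0.5, t_off = 6)
    gr <- gene_rates(beta, gamma)
    times <- seq(0.6, 15, length.out = 20)
    num <- ode_module_oracle(times, mk, beta, gamma)
    got <- module_spliced(times, mk, gr)[, 1]
    expect_lt(max(abs(got - num[, 4]) / pmax(abs(num[, 4]), 1e-4)), 1e-6)
  }
})

test_that("solutions are continuous across both switch times", {
  set.seed(7)
  for (i in 1:5) {
    cfg <- random_module_config()
    eps <- 1e-9
    for (tc in c(cfg$mk$t_on, cfg$mk$t_off)) {
      lo <- c(module_alpha(tc - eps, cfg$mk)[1, 1],
              module_unspliced(tc - eps, cfg$mk, cfg$gr)[1, 1],
              module_spliced(tc - eps, cfg$mk, cfg$gr)[1, 1])
      hi <- c(module_alpha(tc + eps, cfg$mk)[1, 1],
              module_unspliced(tc + eps, cfg$mk, cfg$gr)[1, 1],
              module_spliced(tc + eps, cfg$mk, cfg$gr)[1, 1])
      expect_lt(max(abs(hi - lo)), 1e-7)
    }
  }
})

test_that("fast activation converges to the classical two-state solution", {
  # lambda -> Inf limit of the classical induction solutions:
  # u = a/b (1 - e^-bt); s = a/g (1 - e^-gt) + a (e^-bt - e^-gt)/(b - g)
  a <- 1.7; b <- 0.9; g <- 0.4; t <- 2.3
  u_cl <- a / b * (1 - exp(-b * t))
  s_cl <- a / g * (1 - exp(-g * t)) + a * (exp(-b * t) - exp(-g * t)) / (b - g)
  mk <- module_kinetics(a, 1e7, 1, t_on = 0)
  gr <- gene_rates(b, g)
  expect_equal(module_unspliced(t, mk, gr)[1, 1], u_cl, tolerance = 1e-6)
  expect_equal(module_spliced(t, mk, gr)[1, 1], s_cl, tolerance = 1e-6)
})

test_that("expected_counts superposes modules linearly", {
  set.seed(11)
  cfg <- random_module_config()
  gr <- cfg$gr
  one <- expected_counts(c(1, 3, 7), list(cfg$mk), gr)
  two <- expected_counts(c(1, 3, 7), list(cfg$mk, cfg$mk), gr)
  expect_equal(two$u, 2 * one$u, tolerance = 1e-12)
  expect_equal(two$s, 2 * one$s, tolerance = 1e-12)
  expect_equal(as.vector(one$u), as.vector(one$u_m[, , 1]))
  # totals equal sums over per-module components
  m2 <- module_kinetics(0.7, 2, 1, t_on = 2, t_off = 9)
  both <- expected_counts(c(1, 3, 7), list(cfg$mk, m2), gr)
  expect_equal(as.vector(both$s),
               as.vector(both$s_m[, , 1] + both$s_m[, , 2]))
})

test_that("multi-module superposition matches joint numerical integration", {
  skip_if_not_installed("deSolve")
  set.seed(19)
  for (rep in 1:3) {
    M <- sample(2:3, 1)
    cfgs <- lapply(seq_len(M), function(i) random_module_config())
    gr <- cfgs[[1]]$gr
    mods <- lapply(cfgs, `[[`, "mk")
    times <- sort(runif(10, 0, 20))
    num <- Reduce(`+`, lapply(mods, function(mk)
      ode_module_oracle(times, mk, gr$beta, gr$gamma)[, 2:4]))
    ec <- expected_counts(times, mods, gr)
    expect_lt(max(abs(ec$u - num[, 2]) / pmax(abs(num[, 2]), 1e-4)), 1e-6)
    expect_lt(max(abs(ec$s - num[, 3]) / pmax(abs(num[, 3]), 1e-4)), 1e-6)
  }
})

test_that("invalid kinetics inputs are rejected", {
  expect_error(module_kinetics(-1, 1, 1), "target_rate")
  expect_error(module_kinetics(1, 1, 1, t_on = 5, t_off = 2), "t_on")
  mk <- module_kinetics(1, 1, 1)
  expect_error(module_alpha(NA, mk), "finite")
  expect_error(module_alpha(Inf, mk), "finite")
  expect_error(expected_counts(1, list(), gene_rates(1, 1)), "non-empty")
})
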