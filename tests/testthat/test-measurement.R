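# Measurement transformation and the NB observation model.

test_that("measurement expectation applies detection, soup and batches", {
  xB <- list(u = matrix(10, 1, 1), s = matrix(10, 1, 1))
  mp <- measurement_params(detect_cell = 0.5, detect_mod = c(1, 1),
                           soup_u = matrix(2, 1, 1), soup_s = matrix(2, 1, 1),
                           overdispersion = cbind(1, 1))
  xM <- measurement_expectation(xB, mp)
  expect_equal(xM$mu_u[1, 1], 0.5 * (2 + 10))
  expect_equal(xM$mu_s[1, 1], 6)
  # identity when l = 1, soup = 0
  mp0 <- measurement_params(detect_cell = 1, overdispersion = cbind(1, 1))
  expect_equal(measurement_expectation(xB, mp0)$mu_u, xB$u)
  # one-hot batch selection picks the cell's own batch soup
  xB2 <- list(u = matrix(1, 2, 1), s = matrix(1, 2, 1))
  mp2 <- measurement_params(detect_cell = c(1, 1),
                            soup_u = matrix(c(5, 50), 2, 1),
                            soup_s = matrix(c(7, 70), 2, 1),
                            overdispersion = cbind(1, 1))
  xM2 <- measurement_expectation(xB2, mp2, batch = c(1L, 2L))
  expect_equal(xM2$mu_u[, 1], c(6, 51))
  expect_equal(xM2$mu_s[, 1], c(8, 71))
  expect_error(measurement_expectation(xB2, mp2, batch = c(1L, NA)), "batch")
})

test_that("algebraic identity holds elementwise for random inputs", {
  set.seed(2)
  C <- 7; G <- 5
  xB <- list(u = matrix(rexp(C * G), C, G), s = matrix(rexp(C * G), C, G))
  lc <- rexp(C) + 0.1
  sU <- matrix(rexp(G), 1)
  sS <- matrix(rexp(G), 1)
  mp <- measurement_params(lc, detect_mod = c(0.4, 1.1), soup_u = sU,
                           soup_s = sS, overdispersion = cbind(rep(1, G),
                                                               rep(1, G)))
  xM <- measurement_expectation(xB, mp)
  manual <- outer(lc * 0.4, rep(1, G)) * (matrix(sU, C, G, byrow = TRUE) +
                                            xB$u)
  expect_equal(xM$mu_u, manual, tolerance = 1e-12)
})

test_that("NB log-likelihood uses the mean-concentration convention", {
  # geometric special case: mu = 1, a = 1 -> P(0) = 1/2
  expect_equal(nb_loglik(0, 1, 1), log(0.5), tolerance = 1e-12)
  # truncated pmf mass sums to ~1
  for (pars in list(c(2.5, 0.7), c(30, 5), c(0.3, 12))) {
    hi <- qnbinom(1 - 1e-10, size = pars[2], mu = pars[1])
    mass <- sum(exp(nb_loglik(0:hi, pars[1], pars[2])))
    expect_gt(mass, 1 - 1e-8)
  }
  # Poisson limit as a -> Inf
  x <- 0:30
  expect_lt(max(abs(nb_loglik(x, 4.2, 1e8) - dpois(x, 4.2, log = TRUE))),
            1e-5)
  # variance identity via moments of the pmf
  mu <- 5; a <- 3
  x <- 0:500
  p <- exp(nb_loglik(x, mu, a))
  expect_equal(sum(p * x), mu, tolerance = 1e-8)
  expect_equal(sum(p * (x - mu)^2), mu + mu^2 / a, tolerance = 1e-6)
  expect_error(nb_loglik(-1, 1, 1), "non-negative")
  expect_error(nb_loglik(1.5, 1, 1), "integer")
})

test_that("NB log-likelihood is concave in the log mean", {
  # concavity holds on the log-mean scale (the scale the model optimizes,
  # since means are exp-transformed parameters); in mu itself the x = 0
  # branch is convex
  eta <- seq(log(0.2), log(30), length.out = 300)
  for (x in c(0, 3, 17)) {
    ll <- nb_loglik(rep(x, length(eta)), exp(eta), 2.5)
    expect_lt(max(diff(ll, differences = 2)), 1e-8)
  }
})

test_that("joint model log-likelihood composes and separates truth", {
  sim <- simulate_counts(80, 25, 2, seed = 13)
  tr <- sim$truth
  ll_true <- model_loglik(sim$data, tr$times, tr$modules, tr$rates,
                          tr$measurement)
  swapped <- gene_rates(tr$rates$gamma, tr$rates$beta)
  ll_swap <- model_loglik(sim$data, tr$times, tr$modules, swapped,
                          tr$measurement)
  expect_gt(ll_true, ll_swap)
  # empty gene set gives zero
  empty <- count_data(Matrix::Matrix(0, 3, 0, sparse = TRUE),
                      Matrix::Matrix(0, 3, 0, sparse = TRUE))
  expect_identical(model_loglik(empty, 1:3, tr$modules,
                                gene_rates(numeric(0) + 1, numeric(0) + 1),
                                tr$measurement), 0)
})

test_that("detection rescaling invariance documents the identifiability gap", {
  # doubling detection while halving soup + biological signal leaves the
  # measurement expectation (hence the likelihood) unchanged
  xB <- list(u = matrix(rexp(12), 3, 4), s = matrix(rexp(12), 3, 4))
  sU <- matrix(rexp(4), 1); sS <- matrix(rexp(4), 1)
  ov <- cbind(rep(2, 4), rep(2, 4))
  mp1 <- measurement_params(rep(1, 3), soup_u = sU, soup_s = sS,
                            overdispersion = ov)
  mp2 <- measurement_params(rep(2, 3), soup_u = sU / 2, soup_s = sS / 2,
                            overdispersion = ov)
  xB2 <- list(u = xB$u / 2, s = xB$s / 2)
  m1 <- measurement_expectation(xB, mp1)
  m2 <- measurement_expectation(xB2, mp2)
  expect_equal(m1$mu_u, m2$mu_u, tolerance = 1e-12)
  expect_equal(m1$mu_s, m2$mu_s, tolerance = 1e-12)
})
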