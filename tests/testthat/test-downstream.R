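# Module analytics: activation, normalized activation, states, markers,
# steady-state reference, transition confidence, velocity graph.

test_that("module activation matches the kinetics closed forms", {
  cf <- cached_fit()
  fit <- cf$fit
  act <- module_activation(fit, samples = TRUE)
  # draw 1, module 2: recompute from the posterior draw directly
  mks <- modvelo:::mv_fit_modules(fit, draw = 1)
  gr <- modvelo:::mv_fit_rates(fit, draw = 1)
  expected <- rowSums(module_spliced(fit$posterior$t[1, ], mks[[2]], gr))
  got <- act$activation[act$draw == 1 & act$module == 2]
  expect_equal(got, unname(expected), tolerance = 1e-10)
  expect_true(all(act$activation >= 0))
  expect_error(module_activation(fit, modules = 99), "unknown module")
})

test_that("normalized activation is a monotone fraction of steady state", {
  # property on raw kinetics: s_m(t)/s_m(Inf) is nondecreasing on the ON
  # window and lies in [0, 1] up to numerical tolerance
  set.seed(14)
  for (i in 1:8) {
    cfg <- random_module_config()
    mk <- cfg$mk; gr <- cfg$gr
    ss <- mk$target_rate / gr$gamma
    grid <- seq(mk$t_on, mk$t_off, length.out = 60)
    norm <- module_spliced(grid, mk, gr)[, 1] / ss
    expect_true(all(diff(norm) >= -1e-9))
    expect_true(all(norm >= -1e-9 & norm <= 1 + 1e-9))
  }
  cf <- cached_fit()
  na_tbl <- normalized_activation(cf$fit)
  expect_true(all(is.finite(na_tbl$normalized)))
  expect_gt(max(na_tbl$normalized), 0.2)
})

test_that("module state rule reproduces the threshold classification", {
  expect_identical(as.character(module_state(0.01, t = 5, t_on = 1,
                                             t_off = 10)), "OFF")
  expect_identical(as.character(module_state(0.5, t = 0.5, t_on = 1,
                                             t_off = 10)), "OFF")
  expect_identical(as.character(module_state(0.96, t = 5, t_on = 1,
                                             t_off = 10)), "ON")
  expect_identical(as.character(module_state(0.5, t = 5, t_on = 1,
                                             t_off = 10)), "induction")
  expect_identical(as.character(module_state(0.5, t = 12, t_on = 1,
                                             t_off = 10)), "repression")
  # exhaustive and exclusive over a random grid
  set.seed(1)
  st <- module_state(runif(500), runif(500, 0, 20), t_on = 4, t_off = 12)
  expect_true(!anyNA(st))
  expect_true(all(levels(st) == c("OFF", "induction", "ON", "repression")))
})

test_that("marker ranking follows the explained-rate fraction", {
  fake <- structure(list(
    n_modules = 2L,
    posterior_mean = list(
      alpha_hat = rbind(c(3, 1, 0, 0), c(0, 1, 2, 0)),
      gamma = c(1, 2, 4, 1)),
    data = list(spliced = matrix(0, 2, 4, dimnames = list(
      NULL, c("gA", "gB", "gC", "gD"))))),
    class = "mv_fit")
  mk <- module_markers(fake, k = 3)
  m1 <- mk[mk$module == 1, ]
  expect_identical(m1$gene[1], "gA")          # exclusively module 1
  expect_equal(m1$fraction[1], 1)
  expect_equal(mk$fraction[mk$gene == "gB"], c(0.5, 0.5))  # shared equally
  expect_false("gD" %in% mk$gene)             # all-zero gene excluded
  # fractions per gene sum to one across modules
  full <- module_markers(fake, k = 4)
  sums <- tapply(full$fraction, full$gene, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("markers recover the simulated module structure", {
  cf <- cached_fit()
  truth_primary <- apply(cf$sim$truth$alpha_hat, 2, which.max)
  mk <- module_markers(cf$fit, k = 12)
  # modules are identifiable only up to permutation: match by overlap
  ov <- sapply(1:2, function(m) sapply(1:2, function(tm)
    mean(mk$gene[mk$module == m] %in%
           colnames(cf$sim$data$spliced)[truth_primary == tm])))
  expect_gt(max(ov[, 1]), 0.7)
  expect_gt(max(ov[, 2]), 0.7)
})

test_that("steady-state reference implements alpha_hat / gamma", {
  fake <- structure(list(
    n_modules = 2L,
    posterior_mean = list(alpha_hat = rbind(c(2, 1), c(0, 4)),
                          gamma = c(0.5, 2)),
    data = list(spliced = matrix(0, 1, 2,
                                 dimnames = list(NULL, c("g1", "g2"))))),
    class = "mv_fit")
  ref <- steady_state_reference(fake)
  expect_equal(ref$module1, c(4, 0.5))
  expect_equal(ref$module2, c(0, 2))
  # an OFF-only module gives an all-zero column
  expect_equal(ref$module2[ref$gene == "g1"], 0)
  # CSV round trip at stated precision
  td <- withr::local_tempdir()
  p <- file.path(td, "ref.csv")
  utils::write.csv(ref, p, row.names = FALSE)
  back <- utils::read.csv(p)
  expect_equal(back$module1, ref$module1, tolerance = 1e-12)
})

test_that("transition confidence scores separation correctly", {
  expect_equal(transition_confidence(1:100, 201:300), 1)
  expect_equal(transition_confidence(201:300, 1:100), 0)
  # identical distributions: P(X > q90) = 0.10
  set.seed(31)
  anc <- rnorm(1e5); desc <- rnorm(1e5)
  score <- transition_confidence(anc, desc)
  se <- sqrt(0.1 * 0.9 / 1e5)
  expect_lt(abs(score - 0.10), 3 * se)
  expect_error(transition_confidence(numeric(0), 1:5), "non-empty")
  cf <- cached_fit()
  s13 <- transition_confidence(cf$fit, "stage1", "stage3")
  s31 <- transition_confidence(cf$fit, "stage3", "stage1")
  expect_gt(s13, s31)
  expect_error(transition_confidence(cf$fit, "nope", "stage1"), "cluster")
})

test_that("velocity graph core matches a brute-force implementation", {
  set.seed(12)
  C <- 5; G <- 4; kk <- 2
  expr <- matrix(rnorm(C * G), C, G)
  knn <- t(sapply(1:C, function(c) setdiff(sample(1:C), c)[1:kk]))
  v_draws <- lapply(1:3, function(i) matrix(rnorm(C * G), C, G))
  got <- modvelo:::mv_velocity_graph_core(v_draws, expr, knn, 0.25)
  # independent naive computation
  brute <- matrix(0, C, C)
  for (v in v_draws) {
    P <- matrix(0, C, C)
    for (c in 1:C) {
      w <- numeric(kk)
      for (j in 1:kk) {
        d <- expr[knn[c, j], ] - expr[c, ]
        w[j] <- exp(sum(v[c, ] * d) / sqrt(sum(v[c, ]^2) * sum(d^2)) / 0.25)
      }
      P[c, knn[c, ]] <- w / sum(w)
    }
    brute <- brute + P / length(v_draws)
  }
  expect_equal(as.matrix(got), brute, tolerance = 1e-12)
  expect_equal(unname(Matrix::rowSums(got)), rep(1, C), tolerance = 1e-12)
  # single draw reproduces the single-sample graph exactly
  g1 <- modvelo:::mv_velocity_graph_core(v_draws[1], expr, knn, 0.25)
  g1b <- modvelo:::mv_velocity_graph_core(v_draws[1], expr, knn, 0.25)
  expect_identical(as.matrix(g1), as.matrix(g1b))
})

test_that("velocity aligned with one neighbor maximizes its probability", {
  expr <- rbind(c(0, 0), c(1, 0), c(0, 1))
  knn <- rbind(c(2, 3), c(1, 3), c(1, 2))
  v <- rbind(c(1, 0), c(0, 0), c(0, 0))   # cell 1 points exactly at cell 2
  P <- modvelo:::mv_velocity_graph_core(list(v), expr, knn, 0.25)
  expect_gt(P[1, 2], P[1, 3])
  expect_equal(which.max(as.matrix(P)[1, ]), 2L)
})

test_that("fitted velocity graph rows are probability vectors", {
  cf <- cached_fit()
  vg <- velocity_graph(cf$fit, n_samples = 5, k = 10)
  expect_equal(unname(Matrix::rowSums(vg)), rep(1, nrow(vg)),
               tolerance = 1e-10)
  ve <- embed_velocity(vg, cf$sim$data$embedding)
  expect_identical(dim(ve), c(120L, 2L))
  expect_true(all(is.finite(ve)))
  expect_s3_class(plot_module_activation(cf$fit), "ggplot")
})
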