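# Model fitting: MAP optimization of the joint posterior using the compiled
# analytic-gradient objective, followed by a Laplace (Gaussian) approximation
# on the unconstrained scale from which joint posterior samples are drawn.
# An independent TMB (autodiff) implementation of the same objective lives in
# src/modvelo.cpp and cross-validates the analytic gradients in the tests.

#' @importFrom Rcpp evalCpp
NULL

mv_hyper_names <- c("mu_beta", "log_sig_beta", "mu_gamma", "log_sig_gamma",
                    "mu_ahat", "log_sig_ahat", "mu_a", "log_sig_a",
                    "log_sig_lc")

# parameter list <-> flat vector (order fixed; soup blocks only when used)
mv_par_groups <- function(use_soup) {
  g <- c("z_t", "z_on", "log_dT", "log_lam_on", "log_lam_off", "log_beta",
         "log_gamma", "log_ahat", "log_l_c", "log_l_u", "log_a")
  if (use_soup) g <- c(g, "log_soup_u", "log_soup_s")
  c(g, "hyper")
}

mv_flatten <- function(pl, use_soup) {
  unlist(pl[mv_par_groups(use_soup)], use.names = FALSE)
}

mv_unflatten <- function(par, skel, use_soup) {
  out <- skel
  pos <- 0L
  for (nm in mv_par_groups(use_soup)) {
    n <- length(skel[[nm]])
    v <- par[pos + seq_len(n)]
    if (is.matrix(skel[[nm]])) dim(v) <- dim(skel[[nm]])
    out[[nm]] <- v
    pos <- pos + n
  }
  out
}

# init list (separate hyper fields) -> objective parameter list ($hyper vector)
mv_pl_compact <- function(init) {
  pl <- init[c("z_t", "z_on", "log_dT", "log_lam_on", "log_lam_off",
               "log_beta", "log_gamma", "log_ahat", "log_l_c", "log_l_u",
               "log_a", "log_soup_u", "log_soup_s")]
  pl$hyper <- unlist(init[mv_hyper_names], use.names = FALSE)
  pl
}

# objective closure with value/gradient caching (one C++ call serves both)
mv_make_objective <- function(data, t_max, time_prior_scale, use_soup, skel) {
  dat <- list(U = as.matrix(data$unspliced), S = as.matrix(data$spliced),
              batch = data$batch - 1L, t_max = t_max,
              time_prior_scale = time_prior_scale,
              use_soup = as.integer(use_soup))
  cache <- new.env()
  cache$par <- NULL
  eval_at <- function(par) {
    if (!identical(par, cache$par)) {
      pl <- mv_unflatten(par, skel, use_soup)
      res <- .Call("mv_nll_call", dat, pl, PACKAGE = "modvelo")
      cache$par <- par
      cache$value <- res$value
      gr <- res$gradient
      if (!use_soup) gr$log_soup_u <- gr$log_soup_s <- NULL
      cache$grad <- unlist(gr, use.names = FALSE)
    }
    list(value = cache$value, grad = cache$grad)
  }
  list(fn = function(par) eval_at(par)$value,
       gr = function(par) eval_at(par)$grad)
}

mv_init_params <- function(data, M, t_max, tps = 0.85) {
  S <- as.matrix(data$spliced)
  U <- as.matrix(data$unspliced)
  C <- nrow(S); G <- ncol(S)
  depth <- pmax(Matrix::rowSums(S), 1)
  log_l_c <- pmin(pmax(log(depth / median(depth)), -2), 2)

  # crude pseudotime: first PC of depth-normalized log counts, oriented so the
  # unspliced/spliced ratio decreases along time (repression dominates late)
  norm <- log1p(1e4 * S / depth)
  pc1 <- tryCatch(stats::prcomp(norm, rank. = 1, center = TRUE)$x[, 1],
                  error = function(e) seq_len(C))
  us_ratio <- (Matrix::rowSums(U) + 1) / (depth + 1)
  if (isTRUE(cor(pc1, us_ratio, method = "spearman") > 0)) pc1 <- -pc1
  # map pseudotime ranks onto the log-normal time prior quantiles
  z_t <- stats::qnorm((rank(pc1, ties.method = "first") - 0.5) / C,
                      mean = log(t_max / 2) - tps^2 / 2, sd = 0.8 * tps)

  log_l_u <- min(max(log(sum(U) / max(sum(S), 1) + 1e-8), -3), 1)
  # steady state implies u/s = l_u * gamma/beta per gene; split the observed
  # ratio evenly between beta and gamma so neither group starts uninformed
  q <- pmin(pmax((Matrix::colMeans(U) + 1e-3) /
                   (Matrix::colMeans(S) + 1e-3) / exp(log_l_u), 0.04), 25)
  log_gamma <- 0.5 * log(q)
  log_beta <- -0.5 * log(q)
  gm <- exp(log_gamma)
  sbar <- Matrix::colMeans(S) / mean(exp(log_l_c))
  log_ahat <- matrix(rep(log(pmax(sbar * gm / M, 1e-3)), each = M), M, G)

  f_on <- (seq_len(M) - 0.5) / (M + 1)   # staggered onsets within [0, t_max]
  z_on <- stats::qlogis(f_on / 2)
  log_dT <- rep(log(0.45 * t_max), M)

  mom_a <- function(X) {
    mu <- Matrix::colMeans(X)
    v <- apply(X, 2, stats::var)
    a <- mu^2 / pmax(v - mu, mu * 0.05)
    log(pmin(pmax(a, 0.5), 50))
  }
  log_a <- cbind(mom_a(U), mom_a(S))

  # start in the fast-relaxation regime: slow-lambda basins are degenerate
  # (module forcing mimics gene kinetics and scrambles beta/gamma)
  list(z_t = z_t, z_on = z_on, log_dT = log_dT,
       log_lam_on = rep(log(3), M), log_lam_off = rep(log(3), M),
       log_beta = log_beta, log_gamma = log_gamma, log_ahat = log_ahat,
       log_l_c = log_l_c, log_l_u = log_l_u, log_a = log_a,
       log_soup_u = matrix(log(0.05), max(data$batch), G),
       log_soup_s = matrix(log(0.05), max(data$batch), G),
       mu_beta = log(0.5), log_sig_beta = log(0.7),
       mu_gamma = mean(log_gamma), log_sig_gamma = log(0.7),
       mu_ahat = mean(log_ahat), log_sig_ahat = log(1.5),
       mu_a = mean(log_a), log_sig_a = log(0.7), log_sig_lc = log(0.3))
}

mv_natural <- function(pl, t_max) {
  list(t = exp(pl$z_t),
       t_on = 2 * t_max * stats::plogis(pl$z_on),
       t_off = 2 * t_max * stats::plogis(pl$z_on) + exp(pl$log_dT),
       lambda_on = exp(pl$log_lam_on),
       lambda_off = exp(pl$log_lam_off),
       beta = exp(pl$log_beta), gamma = exp(pl$log_gamma),
       alpha_hat = exp(pl$log_ahat),
       l_c = exp(pl$log_l_c), l_u = exp(pl$log_l_u),
       a = exp(pl$log_a))
}

#' Heuristic default for the number of modules
#'
#' Community detection (Louvain) on a k-nearest-neighbor graph of cells in
#' PCA space of log-normalized spliced counts; the default number of modules
#' is the number of communities plus one, capped at 20. A cheap proxy for the
#' number of distinct expression programs; a user-supplied value is always
#' returned unchanged.
#'
#' @param data An [count_data()] object.
#' @param n_modules Optional user override, returned as-is.
#' @param k Neighbors for the kNN graph (default 15).
#' @param resolution Louvain resolution (default 0.3).
#' @return A positive integer number of modules.
#' @export
select_num_modules <- function(data, n_modules = NULL, k = 15,
                               resolution = 0.3) {
  if (!is.null(n_modules)) return(as.integer(n_modules))
  S <- as.matrix(data$spliced)
  depth <- pmax(rowSums(S), 1)
  norm <- log1p(1e4 * S / depth)
  npc <- min(30, ncol(norm) - 1, nrow(norm) - 1)
  pc <- stats::prcomp(norm, rank. = npc, center = TRUE)$x
  nn <- mv_knn(pc, k = min(k, nrow(pc) - 1))
  edges <- cbind(rep(seq_len(nrow(nn)), ncol(nn)), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  as.integer(max(1, min(20, length(unique(igraph::membership(comm))) + 1)))
}

# k nearest neighbors by euclidean distance; rows = cells, returns n x k index
# matrix (self excluded). O(n^2), adequate at desk scale.
mv_knn <- function(x, k) {
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  t(apply(d, 1, function(r) order(r)[seq_len(k)]))
}

#' Fit the modular velocity model
#'
#' Maximum a posteriori estimation of all latent parameters (cell times,
#' switch times, relaxation rates, target transcription rates, splicing and
#' degradation rates, detection efficiencies, NB overdispersions and their
#' hierarchical hyperparameters) by gradient-based optimization, with
#' gradients from automatic differentiation (TMB). Joint posterior samples
#' are then drawn from a Laplace (Gaussian) approximation at the mode on the
#' unconstrained scale, so every sample satisfies the positivity and
#' `t_on < t_off` constraints by construction.
#'
#' @param data An [count_data()] object (already gene-filtered).
#' @param n_modules Number of modules; default [select_num_modules()].
#' @param t_max Trajectory timescale length (arbitrary units, default 20).
#' @param n_samples Posterior samples S to draw (default 30; 1 keeps just the
#'   MAP and skips the Hessian).
#' @param epochs Maximum optimizer iterations (default 400).
#' @param seed Integer seed; fixed seed and data give an identical fit.
#' @param time_prior_scale Standard deviation (log scale) of the log-normal
#'   prior on cell times (default 0.85, giving a prior coefficient of
#'   variation close to 1, so an uninformed time posterior reports CV near 1).
#' @param use_soup Model ambient RNA per batch? Default: only when the data
#'   has more than one batch.
#' @param method `"laplace"` (default): MAP optimization followed by a
#'   Laplace Gaussian approximation — fast, good point estimates.
#'   `"svi"`: stochastic variational inference with a mean-field Gaussian
#'   family on the unconstrained scale (reparameterization gradients, Adam);
#'   slower, but the entropy term keeps the posterior honestly broad when
#'   the data carry little dynamic information, so uncertainty statistics
#'   (e.g. the posterior-time CV) are calibrated. Use `"svi"` for
#'   uncertainty-focused analyses.
#' @param svi_steps,learning_rate SVI iteration count and Adam step size.
#' @param verbose Print optimizer progress.
#' @return An object of class `mv_fit`; see Details.
#' @details The returned object contains `posterior` (arrays of S joint
#'   samples per parameter group), `posterior_mean`, `map` (natural-scale
#'   point estimates), `elbo_trace` (the negated objective at each function
#'   evaluation), `opt` (optimizer diagnostics) and the input data.
#' @export
mv_fit <- function(data, n_modules = NULL, t_max = 20, n_samples = 30,
                   epochs = 400, seed = 1, time_prior_scale = 0.85,
                   use_soup = NULL, method = c("laplace", "svi"),
                   svi_steps = 3000, learning_rate = 0.02, verbose = FALSE) {
  stopifnot(inherits(data, "mv_data"))
  method <- match.arg(method)
  C <- nrow(data$spliced)
  M <- select_num_modules(data, n_modules)
  if (M > C) stop("invalid config: more modules than cells")
  if (is.null(use_soup)) use_soup <- max(data$batch) > 1
  set.seed(as.integer(seed))

  init <- mv_init_params(data, M, t_max)
  skel <- mv_pl_compact(init)
  ob <- mv_make_objective(data, t_max, time_prior_scale, use_soup, skel)
  par0 <- mv_flatten(skel, use_soup)
  S_n <- max(1L, as.integer(n_samples))

  if (method == "svi") {
    # start the cell-time variational factors near the prior (broad) so that
    # narrow time posteriors must be earned by dynamic signal in the data;
    # global parameter factors start narrow around their initialization
    log_s0 <- rep(log(0.1), length(par0))
    log_s0[seq_len(C)] <- log(time_prior_scale)
    # warm-up: freeze the cell-time factors at the prior while the global
    # parameters adapt to the time-marginalized data, so time posteriors only
    # narrow if dynamic signal supports it after the warm-up
    sv <- mv_svi(ob, par0, steps = svi_steps, lr = learning_rate,
                 log_s0 = log_s0, freeze = seq_len(C),
                 warmup = min(1500, svi_steps %/% 3), verbose = verbose)
    trace <- sv$elbo_trace
    opt <- list(convergence = 0L, objective = -utils::tail(trace, 1),
                message = "SVI step budget reached", method = "svi")
    par_hat <- sv$m
    draws <- matrix(rnorm(S_n * length(par_hat)), S_n, length(par_hat),
                    byrow = TRUE)
    draws <- sweep(sweep(draws, 2, exp(sv$log_s), "*"), 2, sv$m, "+")
    if (S_n == 1) draws <- matrix(par_hat, 1, length(par_hat))
  } else {
    trace_env <- new.env()
    trace_env$tr <- numeric(0)
    fn <- function(p) {
      v <- ob$fn(p)
      if (!is.finite(v)) v <- 1e12
      trace_env$tr <- c(trace_env$tr, -v)
      v
    }
    gr <- function(p) {
      g <- ob$gr(p)
      g[!is.finite(g)] <- 0
      g
    }
    opt <- stats::nlminb(par0, fn, gr,
                         control = list(iter.max = epochs,
                                        eval.max = 3 * epochs,
                                        trace = if (verbose) 10 else 0))
    if (!is.finite(opt$objective) || opt$objective >= 1e12)
      stop("fit divergence: non-finite objective; inspect data scaling/epochs")
    opt$method <- "laplace"
    trace <- trace_env$tr
    par_hat <- opt$par
    draws <- matrix(par_hat, nrow = S_n, ncol = length(par_hat), byrow = TRUE)
    if (S_n > 1) {
      H <- mv_hessian_fd(ob$gr, par_hat)
      L <- mv_chol_ridge(H)
      z <- matrix(rnorm(S_n * length(par_hat)), length(par_hat), S_n)
      draws <- t(par_hat + backsolve(L, z))
    }
  }
  nat_map <- mv_natural(mv_unflatten(par_hat, skel, use_soup), t_max)
  nats <- lapply(seq_len(S_n), function(i)
    mv_natural(mv_unflatten(draws[i, ], skel, use_soup), t_max))

  G <- ncol(data$spliced)
  post <- list(
    t = do.call(rbind, lapply(nats, `[[`, "t")),
    t_on = do.call(rbind, lapply(nats, `[[`, "t_on")),
    t_off = do.call(rbind, lapply(nats, `[[`, "t_off")),
    lambda_on = do.call(rbind, lapply(nats, `[[`, "lambda_on")),
    lambda_off = do.call(rbind, lapply(nats, `[[`, "lambda_off")),
    beta = do.call(rbind, lapply(nats, `[[`, "beta")),
    gamma = do.call(rbind, lapply(nats, `[[`, "gamma")),
    alpha_hat = aperm(array(unlist(lapply(nats, `[[`, "alpha_hat")),
                            c(M, G, S_n)), c(3, 1, 2)),
    l_c = do.call(rbind, lapply(nats, `[[`, "l_c")),
    l_u = vapply(nats, `[[`, 0, "l_u"),
    a = aperm(array(unlist(lapply(nats, `[[`, "a")), c(G, 2, S_n)),
              c(3, 1, 2)))
  pm <- list(t = colMeans(post$t), t_on = colMeans(post$t_on),
             t_off = colMeans(post$t_off),
             lambda_on = colMeans(post$lambda_on),
             lambda_off = colMeans(post$lambda_off),
             beta = colMeans(post$beta), gamma = colMeans(post$gamma),
             alpha_hat = apply(post$alpha_hat, c(2, 3), mean),
             l_c = colMeans(post$l_c), l_u = mean(post$l_u),
             a = apply(post$a, c(2, 3), mean))

  structure(list(posterior = post, posterior_mean = pm, map = nat_map,
                 elbo_trace = trace, opt = opt, data = data,
                 n_modules = M, n_samples = S_n, t_max = t_max, seed = seed,
                 time_prior_scale = time_prior_scale),
            class = "mv_fit")
}

# Mean-field Gaussian SVI on the unconstrained scale: one-sample
# reparameterization gradients, Adam updates, analytic entropy. Maximizes
# ELBO(m, s) = E_{z~N(m,s)}[log p(theta(z), data)] + sum(log s) + const.
mv_svi <- function(ob, par0, steps = 3000, lr = 0.02, log_s0 = log(0.1),
                   freeze = integer(0), warmup = 0, verbose = FALSE) {
  n <- length(par0)
  m <- par0
  log_s <- rep_len(log_s0, n)
  mm1 <- vm1 <- mm2 <- vm2 <- numeric(n)  # Adam moments
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  trace <- numeric(steps)
  for (it in seq_len(steps)) {
    s <- exp(log_s)
    z <- rnorm(n)
    theta <- m + s * z
    v <- ob$fn(theta)
    g <- ob$gr(theta)
    if (!all(is.finite(g)) || !is.finite(v)) {
      g[!is.finite(g)] <- 0
      v <- if (is.finite(v)) v else 1e12
    }
    trace[it] <- -v + sum(log_s)
    g_m <- g                      # d(-ELBO)/dm
    g_ls <- g * s * z - 1         # d(-ELBO)/dlog_s (entropy term: -1)
    mm1 <- b1 * mm1 + (1 - b1) * g_m
    vm1 <- b2 * vm1 + (1 - b2) * g_m^2
    mm2 <- b1 * mm2 + (1 - b1) * g_ls
    vm2 <- b2 * vm2 + (1 - b2) * g_ls^2
    # step-size decay over the last half of training stabilizes the fit
    lr_t <- lr * if (it > steps / 2) 0.3 else 1
    corr <- sqrt(1 - b2^it) / (1 - b1^it)
    dm <- lr_t * corr * mm1 / (sqrt(vm1) + eps)
    dls <- lr_t * corr * mm2 / (sqrt(vm2) + eps)
    if (it <= warmup && length(freeze)) {
      dm[freeze] <- 0
      dls[freeze] <- 0
    }
    m <- m - dm
    log_s <- log_s - dls
    if (verbose && it %% 500 == 0)
      message("step ", it, " ELBO ", round(trace[it], 1))
  }
  list(m = m, log_s = log_s, elbo_trace = trace)
}

# Hessian by central differences of the analytic gradient
mv_hessian_fd <- function(gr, par, h = 1e-4) {
  n <- length(par)
  H <- matrix(0, n, n)
  for (i in seq_len(n)) {
    step <- h * max(1, abs(par[i]))
    pp <- par; pp[i] <- par[i] + step
    pm <- par; pm[i] <- par[i] - step
    H[i, ] <- (gr(pp) - gr(pm)) / (2 * step)
  }
  (H + t(H)) / 2
}

# upper Cholesky factor of H with escalating ridge for non-PD modes
mv_chol_ridge <- function(H) {
  ridge <- 1e-6 * max(1, max(abs(diag(H))))
  for (i in 1:12) {
    L <- tryCatch(chol(H + diag(ridge * (i > 1) * 10^(i - 2), nrow(H))),
                  error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop("posterior Hessian could not be factorized")
}

#' @export
print.mv_fit <- function(x, ...) {
  cat("<mv_fit> ", length(x$posterior_mean$l_c), " cells x ",
      length(x$posterior_mean$beta), " genes, ", x$n_modules, " modules, ",
      x$n_samples, " posterior samples\n", sep = "")
  cat("  final log posterior: ", round(max(x$elbo_trace), 2),
      " (", length(x$elbo_trace), " evaluations)\n", sep = "")
  invisible(x)
}

# rebuild module_kinetics/gene_rates objects from one posterior draw or the
# posterior mean
mv_fit_modules <- function(fit, draw = NULL) {
  p <- if (is.null(draw)) fit$posterior_mean else
    list(t_on = fit$posterior$t_on[draw, ],
         t_off = fit$posterior$t_off[draw, ],
         lambda_on = fit$posterior$lambda_on[draw, ],
         lambda_off = fit$posterior$lambda_off[draw, ],
         alpha_hat = matrix(fit$posterior$alpha_hat[draw, , ],
                            fit$n_modules, ncol(fit$data$spliced)))
  lapply(seq_len(fit$n_modules), function(m)
    module_kinetics(p$alpha_hat[m, ], p$lambda_on[m], p$lambda_off[m],
                    p$t_on[m], p$t_off[m]))
}

mv_fit_rates <- function(fit, draw = NULL) {
  if (is.null(draw)) gene_rates(fit$posterior_mean$beta, fit$posterior_mean$gamma)
  else gene_rates(fit$posterior$beta[draw, ], fit$posterior$gamma[draw, ])
}

#' Coefficient of variation of the posterior cell times
#'
#' Per-cell sd/mean of the posterior time samples (sample sd, n-1 divisor).
#' Values near 0 indicate confident time estimates; values near 1 indicate an
#' uninformative posterior, as expected for steady-state data without
#' transcriptional dynamics. A zero-mean cell is reported as `NA` rather than
#' raising an error.
#'
#' @param fit An `mv_fit` with at least 2 posterior samples.
#' @return A tibble with columns `cell`, `mean_t`, `sd_t`, `cv`.
#' @export
posterior_time_cv <- function(fit) {
  stopifnot(inherits(fit, "mv_fit"))
  if (fit$n_samples < 2) stop("at least 2 posterior samples required")
  tt <- fit$posterior$t
  m <- colMeans(tt)
  s <- apply(tt, 2, sd)
  tibble::tibble(cell = rownames(fit$data$spliced), mean_t = m, sd_t = s,
                 cv = ifelse(m == 0, NA_real_, s / m))
}

#' Orient the fitted timescale
#'
#' The likelihood is nearly invariant to time reversal; this diagnostic
#' reports whether the fitted direction is consistent with unspliced counts
#' leading spliced counts (the unspliced fraction should rise before it
#' falls along time). Returns `1` if consistent, `-1` if reversed-looking.
#'
#' @param fit An `mv_fit`.
#' @return `1` or `-1`.
#' @export
time_orientation <- function(fit) {
  t <- fit$posterior_mean$t
  uf <- Matrix::rowSums(fit$data$unspliced) /
    pmax(Matrix::rowSums(fit$data$unspliced) +
           Matrix::rowSums(fit$data$spliced), 1)
  early <- t <= median(t)
  slope_early <- cor(t[early], uf[early], method = "spearman")
  slope_late <- cor(t[!early], uf[!early], method = "spearman")
  if (isTRUE(slope_early >= slope_late)) 1 else -1
}

# ---- broom-style methods ----------------------------------------------------

#' Tidy a fitted modular velocity model
#'
#' @param x An `mv_fit`.
#' @param parameters Which parameter groups to return (default the gene-level
#'   rates and module parameters).
#' @param ... Unused.
#' @return A tibble with columns `term`, `gene`/`module`/`cell` (as
#'   applicable), `estimate` (posterior mean) and `std.error` (posterior sd).
#' @export
tidy.mv_fit <- function(x, parameters = c("beta", "gamma", "alpha_hat",
                                          "t_on", "t_off", "lambda_on",
                                          "lambda_off"), ...) {
  genes <- colnames(x$data$spliced)
  out <- list()
  psd <- function(m) apply(m, 2, sd)
  for (p in parameters) {
    if (p %in% c("beta", "gamma")) {
      out[[p]] <- tibble::tibble(term = p, gene = genes,
                                 estimate = x$posterior_mean[[p]],
                                 std.error = psd(x$posterior[[p]]))
    } else if (p == "alpha_hat") {
      est <- x$posterior_mean$alpha_hat
      sdv <- apply(x$posterior$alpha_hat, c(2, 3), sd)
      out[[p]] <- tibble::tibble(
        term = "alpha_hat",
        module = rep(seq_len(x$n_modules), times = length(genes)),
        gene = rep(genes, each = x$n_modules),
        estimate = as.vector(est), std.error = as.vector(sdv))
    } else if (p %in% c("t_on", "t_off", "lambda_on", "lambda_off")) {
      out[[p]] <- tibble::tibble(term = p, module = seq_len(x$n_modules),
                                 estimate = x$posterior_mean[[p]],
                                 std.error = psd(x$posterior[[p]]))
    } else if (p == "t") {
      out[[p]] <- tibble::tibble(term = "t", cell = rownames(x$data$spliced),
                                 estimate = x$posterior_mean$t,
                                 std.error = psd(x$posterior$t))
    }
  }
  dplyr::bind_rows(out)
}

#' Glance at a fitted modular velocity model
#'
#' @param x An `mv_fit`.
#' @param ... Unused.
#' @return A one-row tibble with fit-level summaries.
#' @export
glance.mv_fit <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x$data$spliced),
                 n_genes = ncol(x$data$spliced),
                 n_modules = x$n_modules,
                 n_samples = x$n_samples,
                 log_posterior = max(x$elbo_trace),
                 n_evaluations = length(x$elbo_trace),
                 convergence = x$opt$convergence,
                 seed = x$seed)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Optimization trace plot
#'
#' @param object An `mv_fit`.
#' @param ... Unused.
#' @return A ggplot of the log-posterior trace over function evaluations.
#' @export
autoplot.mv_fit <- function(object, ...) {
  df <- tibble::tibble(evaluation = seq_along(object$elbo_trace),
                       log_posterior = object$elbo_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$evaluation, .data$log_posterior)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "function evaluation", y = "log posterior") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
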