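#' @useDynLib modvelo
#' @importFrom stats sd var rnorm runif quantile setNames median cor
#' @importFrom rlang .data
NULL

# ---- stable exponential primitives ------------------------------------------

# (1 - exp(-x)) / x, accurate for all x >= 0 (series near 0)
mv_phi1 <- function(x) {
  out <- x
  small <- abs(x) < 1e-5
  xs <- x[small]
  out[small] <- 1 - xs / 2 + xs^2 / 6 - xs^3 / 24
  xl <- x[!small]
  out[!small] <- -expm1(-xl) / xl
  out
}

# D(r1, r2, tau) = (exp(-r1 tau) - exp(-r2 tau)) / (r2 - r1), symmetric in r1, r2.
# Response at time tau of dy/dt = exp(-r1 t) - r2 y, y(0) = 0.
# Computed as exp(-rmin tau) * (1 - exp(-|dr| tau)) / |dr|, which has no
# cancellation; the |dr| -> 0 limit is tau * exp(-rmin tau).
mv_dexp <- function(r1, r2, tau) {
  rmin <- pmin(r1, r2)
  dr <- abs(r2 - r1)
  e <- exp(-rmin * tau)
  small <- dr * pmax(tau, 1) < 1e-12
  out <- e
  out[small] <- (tau * e)[small]
  big <- !small
  out[big] <- (e * -expm1(-dr * tau) / dr)[big]
  out
}

# Second divided difference of x -> exp(-x * tau) at nodes (a, b, c); symmetric,
# strictly positive, equal to the response of a rate-c linear system to the
# forcing D(a, b, tau). Near-coincident nodes use a simplex (Hermite-Genocchi)
# series; otherwise a difference of stable first divided differences.
mv_dd2exp <- function(a, b, c, tau) {
  n <- max(length(a), length(b), length(c), length(tau))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n)
  tau <- rep_len(tau, n)
  x1 <- pmin(a, b, c)
  x3 <- pmax(a, b, c)
  x2 <- a + b + c - x1 - x3
  spread <- (x3 - x1) * tau
  out <- numeric(n)
  ser <- spread < 1e-3
  if (any(ser)) {
    d1 <- ((x2 - x1) * tau)[ser]
    d2 <- ((x3 - x1) * tau)[ser]
    out[ser] <- (tau[ser]^2 * exp(-x1[ser] * tau[ser])) *
      (1 / 2 - (d1 + d2) / 6 + (d1^2 + d2^2 + d1 * d2) / 24 -
         (d1^3 + d2^3 + d1^2 * d2 + d1 * d2^2) / 120)
  }
  if (any(!ser)) {
    i <- !ser
    out[i] <- (mv_dexp(x2[i], x3[i], tau[i]) - mv_dexp(x1[i], x2[i], tau[i])) /
      (x1[i] - x3[i])
  }
  out
}

# ---- parameter containers ---------------------------------------------------

#' Kinetic parameters of one transcriptional module
#'
#' A module is an independently switching component of the transcription-rate
#' expansion: while ON (between its switch-on and switch-off times) the
#' module's transcription rate relaxes toward a gene-specific target rate
#' `target_rate` at rate `lambda_on`; after switch-off it decays back to zero
#' at rate `lambda_off`. Target rates are zero in the OFF state by definition.
#'
#' @param target_rate Numeric vector of per-gene target transcription rates
#'   (counts per unit time) in the ON state; must be non-negative.
#' @param lambda_on,lambda_off Positive scalars; relaxation rates (1/time)
#'   toward the ON target and back to zero, shared across genes.
#' @param t_on,t_off Switch-on/off times on the shared trajectory timescale;
#'   `t_on < t_off`, `t_off = Inf` keeps the module ON forever.
#' @return An object of class `mv_module`.
#' @examples
#' mk <- module_kinetics(c(2, 0.5), lambda_on = 1, lambda_off = 2,
#'                       t_on = 0, t_off = 10)
#' @export
module_kinetics <- function(target_rate, lambda_on, lambda_off = lambda_on,
                            t_on = 0, t_off = Inf) {
  stopifnot(is.numeric(target_rate), all(is.finite(target_rate)),
            all(target_rate >= 0))
  stopifnot(length(lambda_on) == 1, lambda_on > 0, is.finite(lambda_on),
            length(lambda_off) == 1, lambda_off > 0, is.finite(lambda_off))
  stopifnot(length(t_on) == 1, is.finite(t_on), length(t_off) == 1)
  if (!(t_on < t_off)) stop("`t_on` must be strictly smaller than `t_off`")
  structure(list(target_rate = as.numeric(target_rate),
                 lambda_on = lambda_on, lambda_off = lambda_off,
                 t_on = t_on, t_off = t_off),
            class = "mv_module")
}

#' Gene-level splicing and degradation rates
#'
#' @param beta Positive numeric vector of per-gene splicing rates (1/time).
#' @param gamma Positive numeric vector of per-gene degradation rates (1/time).
#' @return An object of class `mv_rates`.
#' @export
gene_rates <- function(beta, gamma) {
  stopifnot(is.numeric(beta), is.numeric(gamma),
            length(beta) == length(gamma),
            all(is.finite(beta)), all(is.finite(gamma)),
            all(beta > 0), all(gamma > 0))
  structure(list(beta = as.numeric(beta), gamma = as.numeric(gamma)),
            class = "mv_rates")
}

mv_check_time <- function(t) {
  if (!is.numeric(t) || length(t) == 0 || any(!is.finite(t)))
    stop("`t` must be a finite numeric vector")
  as.numeric(t)
}

# ---- closed-form module solutions -------------------------------------------

# Evaluate alpha, u and s of one module for all genes at times t.
# Returns list of length(t) x G matrices. Closed forms:
#   ON  (tau = t - t_on in [0, dT]):
#     alpha = ahat (1 - e^{-lam_on tau})
#     u     = ahat [ (1 - e^{-beta tau})/beta - D(lam_on, beta, tau) ]
#     s     = ahat [ (1 - e^{-gamma tau})/gamma - D(beta, gamma, tau)
#                    - beta DD2(lam_on, beta, gamma, tau) ]
#   OFF (tau2 = t - t_off >= 0), continuing from the ON values at t_off:
#     alpha = alpha0 e^{-lam_off tau2}
#     u     = u0 e^{-beta tau2} + alpha0 D(lam_off, beta, tau2)
#     s     = s0 e^{-gamma tau2} + beta u0 D(beta, gamma, tau2)
#             + beta alpha0 DD2(lam_off, beta, gamma, tau2)
# D and DD2 are stable first/second divided differences of exp(-x tau), so the
# degenerate cases lambda ~ beta, beta ~ gamma, lambda ~ gamma need no special
# branches at the call site.
mv_module_eval <- function(t, mk, gr) {
  t <- mv_check_time(t)
  beta <- gr$beta
  gamma <- gr$gamma
  ahat <- mk$target_rate
  stopifnot(length(ahat) == length(beta))
  C <- length(t)
  G <- length(beta)
  ahat_m <- matrix(ahat, C, G, byrow = TRUE)
  beta_m <- matrix(beta, C, G, byrow = TRUE)
  gamma_m <- matrix(gamma, C, G, byrow = TRUE)

  tau_on <- pmax(pmin(t, mk$t_off) - mk$t_on, 0)
  on_frac <- -expm1(-mk$lambda_on * tau_on)

  TB <- outer(tau_on, beta)
  TG <- outer(tau_on, gamma)
  u_resp <- -expm1(-TB) / beta_m -
    matrix(mv_dexp(mk$lambda_on, beta_m, tau_on), C, G)
  s_resp <- -expm1(-TG) / gamma_m -
    matrix(mv_dexp(beta_m, gamma_m, tau_on), C, G) -
    beta_m * matrix(mv_dd2exp(mk$lambda_on, beta_m, gamma_m, tau_on), C, G)

  alpha <- on_frac * ahat_m
  u <- ahat_m * u_resp
  s <- ahat_m * s_resp

  off <- t > mk$t_off
  if (any(off)) {
    dT <- mk$t_off - mk$t_on
    a0_frac <- -expm1(-mk$lambda_on * dT)
    u0 <- ahat * (-expm1(-beta * dT) / beta - mv_dexp(mk$lambda_on, beta, dT))
    s0 <- ahat * (-expm1(-gamma * dT) / gamma - mv_dexp(beta, gamma, dT) -
                    beta * mv_dd2exp(mk$lambda_on, beta, gamma, dT))
    tau2 <- t[off] - mk$t_off
    Co <- length(tau2)
    beta_o <- matrix(beta, Co, G, byrow = TRUE)
    gamma_o <- matrix(gamma, Co, G, byrow = TRUE)
    u0_o <- matrix(u0, Co, G, byrow = TRUE)
    s0_o <- matrix(s0, Co, G, byrow = TRUE)
    a0_o <- matrix(ahat * a0_frac, Co, G, byrow = TRUE)
    alpha[off, ] <- a0_o * exp(-mk$lambda_off * tau2)
    u[off, ] <- u0_o * exp(-outer(tau2, beta)) +
      a0_o * matrix(mv_dexp(mk$lambda_off, beta_o, tau2), Co, G)
    s[off, ] <- s0_o * exp(-outer(tau2, gamma)) +
      beta_o * u0_o * matrix(mv_dexp(beta_o, gamma_o, tau2), Co, G) +
      beta_o * a0_o * matrix(mv_dd2exp(mk$lambda_off, beta_o, gamma_o, tau2),
                             Co, G)
  }
  list(alpha = alpha, u = u, s = s)
}

mv_subset_genes <- function(m, genes) {
  if (is.null(genes)) m else m[, genes, drop = FALSE]
}

#' Module transcription rate at given times
#'
#' Closed-form solution of the module transcription-rate ODE
#' `d(alpha)/dt = lambda * (ahat * 1\[ON\] - alpha)` with `alpha(t_on) = 0`.
#'
#' @param t Finite numeric vector of times.
#' @param mk A [module_kinetics()] object.
#' @param gr A [gene_rates()] object (used only for gene count/validation by
#'   the companion functions; may be omitted here).
#' @param genes Optional gene index vector; default all genes.
#' @return A `length(t) x genes` matrix of transcription rates.
#' @export
module_alpha <- function(t, mk, genes = NULL) {
  t <- mv_check_time(t)
  tau_on <- pmax(pmin(t, mk$t_off) - mk$t_on, 0)
  frac <- -expm1(-mk$lambda_on * tau_on)
  off <- t > mk$t_off
  if (any(off)) {
    dT <- mk$t_off - mk$t_on
    frac[off] <- -expm1(-mk$lambda_on * dT) * exp(-mk$lambda_off * (t[off] - mk$t_off))
  }
  out <- outer(frac, mk$target_rate)
  mv_subset_genes(out, genes)
}

#' Expected unspliced counts contributed by one module
#'
#' Closed-form solution of `du/dt = alpha_m(t) - beta * u` with `u(t_on) = 0`.
#'
#' @inheritParams module_alpha
#' @param gr A [gene_rates()] object.
#' @return A `length(t) x genes` matrix.
#' @export
module_unspliced <- function(t, mk, gr, genes = NULL) {
  mv_subset_genes(mv_module_eval(t, mk, gr)$u, genes)
}

#' Expected spliced counts contributed by one module
#'
#' Closed-form solution of `ds/dt = beta * u_m(t) - gamma * s` with
#' `s(t_on) = 0`, stable in the repeated-eigenvalue cases (`beta ~ gamma`,
#' `lambda ~ beta`, `lambda ~ gamma`).
#'
#' @inheritParams module_unspliced
#' @return A `length(t) x genes` matrix.
#' @export
module_spliced <- function(t, mk, gr, genes = NULL) {
  mv_subset_genes(mv_module_eval(t, mk, gr)$s, genes)
}

#' Biological expectation values for all modules
#'
#' Superposes the closed-form module solutions into expected unspliced and
#' spliced counts per cell and gene (the "biological" expectations, before
#' detection efficiency, ambient RNA and batch effects are applied).
#'
#' @param t Finite numeric vector of cell times.
#' @param modules A list of [module_kinetics()] objects (at least one).
#' @param gr A [gene_rates()] object.
#' @return An object of class `mv_expectation`: a list with `u` and `s`
#'   (`length(t) x G` matrices, sums over modules), `alpha` (total
#'   transcription rate), and `u_m`, `s_m` (`C x G x M` arrays of per-module
#'   components).
#' @export
expected_counts <- function(t, modules, gr) {
  if (inherits(modules, "mv_module")) modules <- list(modules)
  if (!is.list(modules) || length(modules) == 0)
    stop("`modules` must be a non-empty list of module_kinetics objects")
  t <- mv_check_time(t)
  C <- length(t)
  G <- length(gr$beta)
  M <- length(modules)
  u_m <- array(0, c(C, G, M))
  s_m <- array(0, c(C, G, M))
  alpha <- matrix(0, C, G)
  for (m in seq_len(M)) {
    ev <- mv_module_eval(t, modules[[m]], gr)
    u_m[, , m] <- ev$u
    s_m[, , m] <- ev$s
    alpha <- alpha + ev$alpha
  }
  structure(list(t = t,
                 u = apply(u_m, c(1, 2), sum),
                 s = apply(s_m, c(1, 2), sum),
                 alpha = alpha, u_m = u_m, s_m = s_m,
                 beta = gr$beta, gamma = gr$gamma),
            class = "mv_expectation")
}

#' RNA velocity at given cell times
#'
#' The time derivative of the expected spliced counts,
#' `v_g = sum_m (beta_g u_mg - gamma_g s_mg)`.
#'
#' @inheritParams expected_counts
#' @return A `length(t) x G` matrix of per-gene velocities.
#' @export
velocity <- function(t, modules, gr) {
  ec <- expected_counts(t, modules, gr)
  beta_m <- matrix(gr$beta, length(t), length(gr$beta), byrow = TRUE)
  gamma_m <- matrix(gr$gamma, length(t), length(gr$gamma), byrow = TRUE)
  beta_m * ec$u - gamma_m * ec$s
}
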