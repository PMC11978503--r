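# Module-level downstream analytics on a fitted model: activation, states,
# markers, steady-state reference signatures, transition confidence and the
# posterior-averaged velocity graph.

mv_check_fit <- function(fit) stopifnot(inherits(fit, "mv_fit"))

mv_check_modules <- function(fit, modules) {
  if (is.null(modules)) return(seq_len(fit$n_modules))
  if (any(!modules %in% seq_len(fit$n_modules)))
    stop("unknown module id; available: 1..", fit$n_modules)
  as.integer(modules)
}

# per-draw spliced counts produced by each module, summed over genes (or per
# gene); returns array draws x cells x modules (or list of C x G per module)
mv_activation_draws <- function(fit, modules, per_gene = FALSE) {
  S_n <- fit$n_samples
  C <- nrow(fit$data$spliced)
  out <- array(0, c(S_n, C, length(modules)))
  pg <- if (per_gene)
    array(0, c(C, ncol(fit$data$spliced), length(modules))) else NULL
  for (i in seq_len(S_n)) {
    mks <- mv_fit_modules(fit, draw = i)
    gr <- mv_fit_rates(fit, draw = i)
    t_i <- fit$posterior$t[i, ]
    for (j in seq_along(modules)) {
      s_m <- mv_module_eval(t_i, mks[[modules[j]]], gr)$s
      out[i, , j] <- rowSums(s_m)
      if (per_gene) pg[, , j] <- pg[, , j] + s_m / S_n
    }
  }
  list(total = out, per_gene = pg)
}

#' Module activation: spliced counts produced by each module per cell
#'
#' Substitutes posterior parameter draws into the closed-form time evolution
#' of spliced counts and sums over genes, giving the total spliced counts a
#' module has produced in each cell at its inferred time.
#'
#' @param fit An `mv_fit`.
#' @param modules Module ids (default all).
#' @param per_gene Also return the posterior-mean per-gene activation matrix?
#' @param samples Return one row per posterior draw instead of the
#'   posterior-mean summary?
#' @return A tibble with columns `cell`, `module`, `t` (posterior-mean cell
#'   time), `activation` and `sd` (posterior sd); with `samples = TRUE`, one
#'   row per draw with a `draw` column. With `per_gene = TRUE` the per-gene
#'   array is attached as attribute `"per_gene"` (cells x genes x modules).
#' @export
module_activation <- function(fit, modules = NULL, per_gene = FALSE,
                              samples = FALSE) {
  mv_check_fit(fit)
  modules <- mv_check_modules(fit, modules)
  ad <- mv_activation_draws(fit, modules, per_gene = per_gene)
  cells <- rownames(fit$data$spliced)
  if (samples) {
    # rows ordered by draw, then module, then cell
    out <- tidyr::expand_grid(draw = seq_len(fit$n_samples),
                              module = modules,
                              cell = factor(cells, levels = cells))
    out$activation <- as.vector(aperm(ad$total, c(2, 3, 1)))
    out$cell <- as.character(out$cell)
  } else {
    m_act <- apply(ad$total, c(2, 3), mean)                 # C x M
    s_act <- if (fit$n_samples > 1) apply(ad$total, c(2, 3), sd) else
      m_act * 0
    out <- tidyr::expand_grid(module = modules,
                              cell = factor(cells, levels = cells))
    out$cell <- as.character(out$cell)
    out$t <- rep(fit$posterior_mean$t, times = length(modules))
    out$activation <- unlist(lapply(seq_along(modules),
                                    function(j) m_act[, j]))
    out$sd <- unlist(lapply(seq_along(modules), function(j) s_act[, j]))
  }
  if (per_gene) attr(out, "per_gene") <- ad$per_gene
  out
}

# posterior draws of module steady-state total spliced counts
mv_steady_draws <- function(fit, modules) {
  ss <- vapply(seq_len(fit$n_samples), function(i) {
    ah <- matrix(fit$posterior$alpha_hat[i, , ], fit$n_modules,
                 ncol(fit$data$spliced))
    gm <- fit$posterior$gamma[i, ]
    vapply(modules, function(m) sum(ah[m, ] / gm), 0)
  }, numeric(length(modules)))
  matrix(ss, nrow = length(modules))  # modules x draws
}

#' Normalized module activation
#'
#' Activation divided by the module's steady-state spliced counts (the
#' time-to-infinity limit of the spliced-count equations with the module held
#' ON). Lies in \[0, 1\] during induction up to numerical tolerance; a module
#' with zero steady state is flagged undefined (`NA`).
#'
#' @inheritParams module_activation
#' @return A tibble `cell`, `module`, `t`, `activation`, `steady_state`,
#'   `normalized` (`NA` where undefined).
#' @export
normalized_activation <- function(fit, modules = NULL) {
  mv_check_fit(fit)
  modules <- mv_check_modules(fit, modules)
  ad <- mv_activation_draws(fit, modules)$total    # S x C x M
  ss <- mv_steady_draws(fit, modules)              # M x S
  S_n <- fit$n_samples
  norm <- array(0, dim(ad))
  for (i in seq_len(S_n)) for (j in seq_along(modules)) {
    s0 <- ss[j, i]
    norm[i, , j] <- if (s0 > 0) ad[i, , j] / s0 else NA_real_
  }
  cmean <- function(a, j) if (S_n == 1) a[1, , j] else colMeans(a[, , j])
  out <- tidyr::expand_grid(module = modules, cell = rownames(fit$data$spliced))
  out$t <- rep(fit$posterior_mean$t, times = length(modules))
  out$activation <- unlist(lapply(seq_along(modules), function(j) cmean(ad, j)))
  out$steady_state <- rep(rowMeans(ss)[seq_along(modules)],
                          each = nrow(fit$data$spliced))
  out$normalized <- unlist(lapply(seq_along(modules),
                                  function(j) cmean(norm, j)))
  out
}

#' Classify module state in a cell
#'
#' A module is OFF if the cell time is below the module's switch-on time or
#' its normalized activation is below 0.05; ON if normalized activation is
#' above 0.95; otherwise in induction or repression depending on whether the
#' cell time is below or above the switch-off time.
#'
#' @param normalized Normalized activation values.
#' @param t Cell times (same length or scalar).
#' @param t_on,t_off Module switch times (scalar).
#' @param off_threshold,on_threshold State thresholds (defaults 0.05, 0.95).
#' @return A factor with levels OFF, induction, ON, repression.
#' @export
module_state <- function(normalized, t, t_on, t_off,
                         off_threshold = 0.05, on_threshold = 0.95) {
  stopifnot(all(is.finite(t)), is.finite(t_on))
  n <- max(length(normalized), length(t))
  normalized <- rep_len(normalized, n)
  t <- rep_len(t, n)
  state <- ifelse(t < t_on | normalized < off_threshold, "OFF",
           ifelse(normalized > on_threshold, "ON",
           ifelse(t < t_off, "induction", "repression")))
  factor(state, levels = c("OFF", "induction", "ON", "repression"))
}

#' Module states for all cells of a fitted model
#'
#' @inheritParams module_activation
#' @param ... Passed to [module_state()] (thresholds).
#' @return The [normalized_activation()] tibble with an added `state` column.
#' @export
module_states <- function(fit, modules = NULL, ...) {
  na_tbl <- normalized_activation(fit, modules)
  t_on <- fit$posterior_mean$t_on
  t_off <- fit$posterior_mean$t_off
  na_tbl$state <- factor(NA, levels = c("OFF", "induction", "ON", "repression"))
  for (m in unique(na_tbl$module)) {
    i <- na_tbl$module == m
    na_tbl$state[i] <- module_state(na_tbl$normalized[i], na_tbl$t[i],
                                    t_on[m], t_off[m], ...)
  }
  na_tbl
}

#' Rank module marker genes
#'
#' Genes are ranked by the fraction of their total target transcription rate
#' explained by the module (posterior mean), with ties broken by the absolute
#' target rate and then gene id. Genes with an all-zero rate are excluded.
#'
#' @param fit An `mv_fit`.
#' @param modules Module ids (default all).
#' @param k Top genes per module to return (default 10).
#' @return A tibble `module`, `gene`, `rank`, `fraction`, `target_rate`.
#' @export
module_markers <- function(fit, modules = NULL, k = 10) {
  mv_check_fit(fit)
  modules <- mv_check_modules(fit, modules)
  ah <- fit$posterior_mean$alpha_hat            # M x G
  genes <- colnames(fit$data$spliced)
  tot <- colSums(ah)
  keep <- tot > 0
  frac <- sweep(ah[, keep, drop = FALSE], 2, tot[keep], "/")
  gk <- genes[keep]
  purrr::map_dfr(modules, function(m) {
    ord <- order(-frac[m, ], -abs(ah[m, keep]), gk)
    top <- utils::head(ord, k)
    tibble::tibble(module = m, gene = gk[top], rank = seq_along(top),
                   fraction = frac[m, top], target_rate = ah[m, keep][top])
  })
}

#' Steady-state reference expression of each module
#'
#' The steady-state spliced counts per module and gene,
#' `g_mg = alpha_hat_mg / gamma_g` (posterior mean): the expression signature
#' a module converges to if held ON, suitable as a reference profile for
#' spatial deconvolution tools.
#'
#' Values are exported on the biological (detection-free) scale, since the
#' fitted detection model is cell-level and cancels in reference profiles.
#'
#' @param fit An `mv_fit`.
#' @return A tibble with a `gene` column and one column per module
#'   (`module1`, `module2`, ...).
#' @export
steady_state_reference <- function(fit) {
  mv_check_fit(fit)
  ah <- fit$posterior_mean$alpha_hat
  gmg <- t(ah) / fit$posterior_mean$gamma       # G x M
  colnames(gmg) <- paste0("module", seq_len(fit$n_modules))
  dplyr::bind_cols(tibble::tibble(gene = colnames(fit$data$spliced)),
                   tibble::as_tibble(gmg))
}

#' Confidence score for a cluster-to-cluster transition
#'
#' The fraction of pooled posterior cell-time samples in the putative
#' descendant cluster that exceed the 90th percentile of the pooled samples
#' of the putative ancestor cluster. Near 1 for a confidently ordered
#' transition, near 0 for a reversed one, and 0.10 in expectation when the
#' two clusters' time posteriors are identical.
#'
#' @param x An `mv_fit` (with `source` and `target` cluster names), or a
#'   numeric vector of ancestor time samples (with `source` a numeric vector
#'   of descendant samples).
#' @param source,target Cluster names (fit method) or sample vectors
#'   (default method).
#' @param ... Unused.
#' @return A single numeric score in \[0, 1\].
#' @export
transition_confidence <- function(x, source, target, ...) {
  UseMethod("transition_confidence")
}

#' @rdname transition_confidence
#' @export
transition_confidence.default <- function(x, source, target, ...) {
  ancestor <- x
  descendant <- source
  if (length(ancestor) == 0 || length(descendant) == 0)
    stop("both clusters must be non-empty")
  q90 <- stats::quantile(ancestor, 0.9, names = FALSE)
  mean(descendant > q90)
}

#' @rdname transition_confidence
#' @export
transition_confidence.mv_fit <- function(x, source, target, ...) {
  cl <- x$data$clusters
  if (is.null(cl)) stop("fit data has no cluster labels")
  is_src <- cl == source
  is_tgt <- cl == target
  if (!any(is_src) || !any(is_tgt))
    stop("empty cluster; available: ", paste(unique(cl), collapse = ", "))
  transition_confidence(as.vector(x$posterior$t[, is_src, drop = FALSE]),
                        as.vector(x$posterior$t[, is_tgt, drop = FALSE]))
}

# kNN-smoothed log expression used for displacement vectors
mv_smoothed_expression <- function(data, k = 30, n_pcs = 30) {
  S <- as.matrix(data$spliced)
  depth <- pmax(rowSums(S), 1)
  norm <- log1p(1e4 * S / depth)
  npc <- min(n_pcs, ncol(norm) - 1, nrow(norm) - 1)
  pc <- stats::prcomp(norm, rank. = npc, center = TRUE)$x
  nn <- mv_knn(pc, k = min(k, nrow(norm) - 1))
  sm <- norm
  for (c in seq_len(nrow(norm)))
    sm[c, ] <- colMeans(norm[c(c, nn[c, ]), , drop = FALSE])
  list(expr = sm, knn = nn, pca = pc)
}

#' Posterior-averaged RNA velocity graph
#'
#' For each posterior sample, computes the cosine similarity between a cell's
#' velocity vector and the displacement (in kNN-smoothed log expression
#' space) toward each of its k nearest neighbors, passes it through an
#' exponential kernel and row-normalizes to transition probabilities; the
#' graph is then averaged over posterior samples so genes with uncertain
#' velocities carry less weight. Velocities are mapped to log-expression
#' scale as `v / (1 + s)`.
#'
#' @param fit An `mv_fit`.
#' @param n_samples Posterior samples to average over (default 100, capped at
#'   the number of samples in the fit).
#' @param k Nearest neighbors (default 30).
#' @param n_pcs PCA components for the neighbor search (default 30).
#' @param kernel_scale Scale of the exponential kernel on cosine similarities
#'   (default 0.25).
#' @return A sparse cell x cell transition-probability matrix (rows sum to 1
#'   over neighbors); cells with no neighbors have zero rows and are listed
#'   in the `"isolated"` attribute.
#' @export
velocity_graph <- function(fit, n_samples = 100, k = 30, n_pcs = 30,
                           kernel_scale = 0.25) {
  mv_check_fit(fit)
  C <- nrow(fit$data$spliced)
  G <- ncol(fit$data$spliced)
  sm <- mv_smoothed_expression(fit$data, k = k, n_pcs = n_pcs)
  S_n <- min(n_samples, fit$n_samples)
  v_draws <- lapply(seq_len(S_n), function(i) {
    gr <- mv_fit_rates(fit, draw = i)
    ec <- expected_counts(fit$posterior$t[i, ], mv_fit_modules(fit, draw = i),
                          gr)
    (matrix(gr$beta, C, G, byrow = TRUE) * ec$u -
        matrix(gr$gamma, C, G, byrow = TRUE) * ec$s) / (1 + ec$s)
  })
  out <- mv_velocity_graph_core(v_draws, sm$expr, sm$knn, kernel_scale)
  rownames(out) <- colnames(out) <- rownames(fit$data$spliced)
  out
}

# core of the velocity graph: expression-space displacements to kNN
# neighbors, cosine similarity with each velocity draw, exponential kernel,
# row normalization, average over draws
mv_velocity_graph_core <- function(v_draws, expr, knn, kernel_scale = 0.25) {
  C <- nrow(expr)
  kk <- ncol(knn)
  src <- rep(seq_len(C), each = kk)
  dst <- as.vector(t(knn))
  disp <- expr[dst, , drop = FALSE] - expr[src, , drop = FALSE]
  dnorm_ <- sqrt(rowSums(disp^2))
  P <- matrix(0, C, kk)
  for (v in v_draws) {
    vnorm <- sqrt(rowSums(v^2))
    num <- rowSums(v[src, , drop = FALSE] * disp)
    cosv <- num / pmax(vnorm[src] * dnorm_, 1e-12)
    cosv[vnorm[src] == 0 | dnorm_ == 0] <- 0
    W <- matrix(exp(cosv / kernel_scale), C, kk, byrow = TRUE)
    P <- P + W / rowSums(W)
  }
  P <- P / length(v_draws)
  out <- Matrix::sparseMatrix(i = src, j = dst, x = as.vector(t(P)),
                              dims = c(C, C))
  attr(out, "isolated") <- integer(0)
  attr(out, "knn") <- knn
  out
}

#' Project velocities into a 2-D embedding
#'
#' Expected displacement under the velocity-graph transition probabilities,
#' relative to a uniform baseline over the same neighbors (the standard
#' embedding projection of velocity graphs).
#'
#' @param graph A [velocity_graph()] result.
#' @param embedding A cells x 2 matrix of embedding coordinates.
#' @return A cells x 2 matrix of embedded velocity vectors.
#' @export
embed_velocity <- function(graph, embedding) {
  nn <- attr(graph, "knn")
  C <- nrow(graph)
  stopifnot(nrow(embedding) == C)
  V <- matrix(0, C, 2)
  for (c in seq_len(C)) {
    nbr <- nn[c, ]
    d <- embedding[nbr, , drop = FALSE] -
      matrix(embedding[c, ], length(nbr), 2, byrow = TRUE)
    len <- sqrt(rowSums(d^2))
    ok <- len > 0
    if (!any(ok)) next
    e <- d[ok, , drop = FALSE] / len[ok]
    p <- graph[c, nbr][ok]
    V[c, ] <- colSums(p * e) - colMeans(e)
  }
  V
}

#' Plot module activation over inferred time
#'
#' @param fit An `mv_fit`.
#' @param modules Module ids (default all).
#' @return A ggplot: activation versus posterior-mean cell time, one colored
#'   series per module.
#' @export
plot_module_activation <- function(fit, modules = NULL) {
  act <- module_activation(fit, modules)
  ggplot2::ggplot(act, ggplot2::aes(.data$t, .data$activation,
                                    color = factor(.data$module))) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(x = "inferred cell time", y = "module activation
(spliced counts)", color = "module") +
    ggplot2::theme_minimal()
}
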