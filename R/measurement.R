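# Measurement model: detection efficiency, ambient RNA, batches, and the
# negative-binomial observation model.

#' Measurement parameters
#'
#' The detection efficiency `l_cgj` is factorized as a per-cell factor times a
#' per-modality factor times an optional per-gene-and-modality factor (a free
#' cell x gene matrix would be unidentifiable; depth and quantification
#' effects are low-rank). Ambient RNA ("soup") is a per-batch, per-gene,
#' per-modality mean count added before detection scaling.
#'
#' @param detect_cell Positive per-cell detection factors (length C).
#' @param detect_mod Positive length-2 vector, detection factors for the
#'   unspliced and spliced modality (in that order).
#' @param detect_gene Optional G x 2 matrix of per-gene modality factors
#'   (default all 1).
#' @param soup_u,soup_s Optional E x G matrices of ambient counts per batch
#'   and gene for the unspliced/spliced modality (default 0).
#' @param overdispersion G x 2 matrix (or length-2 list of vectors) of
#'   negative-binomial concentrations `a_gj` (columns: unspliced, spliced).
#' @return An object of class `mv_measurement`.
#' @export
measurement_params <- function(detect_cell, detect_mod = c(1, 1),
                               detect_gene = NULL, soup_u = NULL,
                               soup_s = NULL, overdispersion) {
  stopifnot(all(detect_cell > 0), length(detect_mod) == 2, all(detect_mod > 0))
  if (is.list(overdispersion))
    overdispersion <- cbind(overdispersion[[1]], overdispersion[[2]])
  overdispersion <- as.matrix(overdispersion)
  stopifnot(ncol(overdispersion) == 2, all(overdispersion > 0))
  if (!is.null(detect_gene)) {
    detect_gene <- as.matrix(detect_gene)
    stopifnot(nrow(detect_gene) == nrow(overdispersion),
              ncol(detect_gene) == 2, all(detect_gene > 0))
  }
  for (sp in list(soup_u, soup_s))
    if (!is.null(sp)) stopifnot(all(sp >= 0))
  structure(list(detect_cell = detect_cell, detect_mod = detect_mod,
                 detect_gene = detect_gene, soup_u = soup_u, soup_s = soup_s,
                 overdispersion = overdispersion),
            class = "mv_measurement")
}

mv_soup_for <- function(soup, batch, C, G) {
  if (is.null(soup)) return(matrix(0, C, G))
  soup <- as.matrix(soup)
  stopifnot(ncol(soup) == G, max(batch) <= nrow(soup))
  soup[batch, , drop = FALSE]
}

#' Measurement expectation values
#'
#' Transforms biological expectations into expected observed counts:
#' `x^M_cgj = l_cgj * (soup_{e(c),gj} + x^B_cgj)`, where `e(c)` is the batch
#' of cell `c` (one-hot batch selection).
#'
#' @param xB An [expected_counts()] result, or a list with `u` and `s`
#'   cell x gene matrices of biological expectations.
#' @param mp A [measurement_params()] object.
#' @param batch Integer per-cell batch assignment (default: single batch).
#' @return A list with matrices `mu_u` and `mu_s` of expected observed counts.
#' @export
measurement_expectation <- function(xB, mp, batch = NULL) {
  u <- xB$u; s <- xB$s
  C <- nrow(u); G <- ncol(u)
  if (is.null(batch)) batch <- rep(1L, C)
  if (length(batch) != C || any(is.na(batch)))
    stop("every cell must have a batch assignment")
  batch <- as.integer(batch)
  stopifnot(length(mp$detect_cell) == C)
  dg <- if (is.null(mp$detect_gene)) matrix(1, G, 2) else mp$detect_gene
  l_u <- mp$detect_cell * mp$detect_mod[1] *
    matrix(dg[, 1], C, G, byrow = TRUE)
  l_s <- mp$detect_cell * mp$detect_mod[2] *
    matrix(dg[, 2], C, G, byrow = TRUE)
  list(mu_u = l_u * (mv_soup_for(mp$soup_u, batch, C, G) + u),
       mu_s = l_s * (mv_soup_for(mp$soup_s, batch, C, G) + s))
}

#' Negative-binomial log-likelihood of observed counts
#'
#' Log pmf of `X ~ NB(mu, a)` in the mean-concentration (Gamma-Poisson)
#' convention, `Var = mu + mu^2 / a`; larger `a` means less overdispersion
#' and the Poisson limit as `a -> Inf`.
#'
#' @param x Non-negative integer counts (vector or matrix).
#' @param mu Positive means, recycled/conformable with `x`.
#' @param a Positive concentrations, conformable with `x`.
#' @return Per-entry log-likelihoods with the shape of `x`.
#' @export
nb_loglik <- function(x, mu, a) {
  if (any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers")
  stopifnot(all(mu > 0), all(a > 0))
  out <- stats::dnbinom(as.vector(x), size = as.vector(a + x * 0),
                        mu = as.vector(mu + x * 0), log = TRUE)
  if (is.matrix(x)) out <- matrix(out, nrow(x), ncol(x))
  out
}

#' Joint model log-likelihood of a dataset
#'
#' Composes the kinetic expectations, the measurement transformation and the
#' NB observation model into the total data log-likelihood.
#'
#' @param data An [count_data()] object.
#' @param t Per-cell times.
#' @param modules List of [module_kinetics()] objects.
#' @param gr A [gene_rates()] object.
#' @param mp A [measurement_params()] object.
#' @param mu_floor Small positive floor added to the NB means so zero
#'   expectations stay in the support (default 1e-8).
#' @return Scalar total log-likelihood (0 for an empty gene set).
#' @export
model_loglik <- function(data, t, modules, gr, mp, mu_floor = 1e-8) {
  G <- ncol(data$spliced)
  if (G == 0) return(0)
  xB <- expected_counts(t, modules, gr)
  xM <- measurement_expectation(xB, mp, batch = data$batch)
  a_u <- matrix(mp$overdispersion[, 1], nrow(xM$mu_u), G, byrow = TRUE)
  a_s <- matrix(mp$overdispersion[, 2], nrow(xM$mu_s), G, byrow = TRUE)
  sum(nb_loglik(as.matrix(data$unspliced), xM$mu_u + mu_floor, a_u)) +
    sum(nb_loglik(as.matrix(data$spliced), xM$mu_s + mu_floor, a_s))
}
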