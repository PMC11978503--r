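# Count-data container and gene filtering.

#' Raw spliced/unspliced count data
#'
#' Bundles cell x gene matrices of raw unspliced and spliced UMI counts with
#' optional per-cell metadata (cluster labels, batch labels, 2-D embedding).
#' Matrices are stored sparse; genes are columns.
#'
#' @param spliced,unspliced Cell x gene matrices of non-negative integer
#'   counts with identical dimensions (and dimnames, if any).
#' @param clusters Optional per-cell cluster labels (character or factor).
#' @param batch Optional per-cell batch labels; defaults to a single batch.
#' @param embedding Optional cells x 2 matrix of embedding coordinates.
#' @return An object of class `mv_data`.
#' @export
count_data <- function(spliced, unspliced, clusters = NULL, batch = NULL,
                       embedding = NULL) {
  to_sparse <- function(m) {
    m <- Matrix::Matrix(m, sparse = TRUE)
    methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                "CsparseMatrix")
  }
  spliced <- to_sparse(spliced)
  unspliced <- to_sparse(unspliced)
  if (!identical(dim(spliced), dim(unspliced)))
    stop("spliced and unspliced matrices must have identical dimensions")
  for (m in list(spliced, unspliced)) {
    x <- m@x
    if (length(x) && (any(x < 0) || any(x != round(x))))
      stop("counts must be non-negative integers")
  }
  n <- nrow(spliced)
  if (is.null(rownames(spliced)) && n > 0)
    rownames(spliced) <- rownames(unspliced) <- paste0("cell", seq_len(n))
  if (is.null(colnames(spliced)) && ncol(spliced) > 0)
    colnames(spliced) <- colnames(unspliced) <-
      paste0("gene", seq_len(ncol(spliced)))
  if (!is.null(clusters)) {
    stopifnot(length(clusters) == n)
    clusters <- as.character(clusters)
  }
  if (is.null(batch)) batch <- rep(1L, n)
  stopifnot(length(batch) == n)
  batch <- as.integer(factor(batch))
  if (!is.null(embedding)) {
    embedding <- as.matrix(embedding)
    stopifnot(nrow(embedding) == n, ncol(embedding) >= 2)
  }
  structure(list(spliced = spliced, unspliced = unspliced,
                 clusters = clusters, batch = batch, embedding = embedding),
            class = "mv_data")
}

#' @export
print.mv_data <- function(x, ...) {
  cat("<mv_data> ", nrow(x$spliced), " cells x ", ncol(x$spliced), " genes; ",
      max(x$batch), " batch(es)",
      if (!is.null(x$clusters)) paste0("; ", length(unique(x$clusters)), " clusters"),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.mv_data <- function(x) dim(x$spliced)

#' Filter genes by detected counts and variability
#'
#' Removes genes whose total detected counts (spliced + unspliced, summed over
#' cells) fall below `min_counts`, then keeps the `n_top` most variable of the
#' survivors. Variability is scored as the variance of
#' `log1p(1e4 * (s + u) / cell_total)` (log-normalized combined counts), a
#' standard highly-variable-gene score; ties are broken by original gene
#' order, and the returned data keeps genes in their original relative order.
#'
#' @param data An [count_data()] object.
#' @param n_top Number of most-variable genes to keep (default 3000).
#' @param min_counts Minimum total detected counts per gene (default 20).
#' @return A filtered `mv_data` object.
#' @export
filter_genes <- function(data, n_top = 3000, min_counts = 20) {
  stopifnot(inherits(data, "mv_data"))
  tot <- Matrix::colSums(data$spliced) + Matrix::colSums(data$unspliced)
  keep <- which(tot >= min_counts)
  if (length(keep) < 2)
    stop("fewer than 2 genes pass the min_counts filter")
  if (length(keep) > n_top) {
    comb <- data$spliced[, keep, drop = FALSE] + data$unspliced[, keep, drop = FALSE]
    depth <- pmax(Matrix::rowSums(comb), 1)
    norm <- log1p(1e4 * comb / depth)
    score <- apply(as.matrix(norm), 2, stats::var)
    ord <- order(-score, seq_along(score))
    keep <- sort(keep[ord[seq_len(n_top)]])
  }
  count_data(data$spliced[, keep, drop = FALSE],
             data$unspliced[, keep, drop = FALSE],
             clusters = data$clusters, batch = data$batch,
             embedding = data$embedding)
}
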