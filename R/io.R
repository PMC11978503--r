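# Readers/writers: MatrixMarket + TSV/CSV interchange for spliced/unspliced
# counts, metadata and ground truth. Genes are columns; indices in MTX files
# are 1-based (MatrixMarket convention).

#' Write a count dataset (and simulation ground truth) to a directory
#'
#' Writes `spliced.mtx`, `unspliced.mtx`, `barcodes.tsv`, `genes.tsv` and
#' `cells.csv` (cluster, batch, embedding). For a simulation, ground-truth
#' tables `truth_genes.csv`, `truth_cells.csv` and `truth_modules.csv` are
#' written as well.
#'
#' @param x An [count_data()] or [simulate_counts()] object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_counts <- function(x, dir) {
  truth <- NULL
  if (inherits(x, "mv_sim")) {
    truth <- x$truth
    x <- x$data
  }
  stopifnot(inherits(x, "mv_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(x$spliced, file.path(dir, "spliced.mtx"))
  Matrix::writeMM(x$unspliced, file.path(dir, "unspliced.mtx"))
  writeLines(rownames(x$spliced), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(x$spliced), file.path(dir, "genes.tsv"))
  meta <- tibble::tibble(cell = rownames(x$spliced), batch = x$batch)
  if (!is.null(x$clusters)) meta$cluster <- x$clusters
  if (!is.null(x$embedding)) {
    meta$embedding1 <- x$embedding[, 1]
    meta$embedding2 <- x$embedding[, 2]
  }
  utils::write.csv(meta, file.path(dir, "cells.csv"), row.names = FALSE)
  if (!is.null(truth)) {
    utils::write.csv(truth$genes, file.path(dir, "truth_genes.csv"),
                     row.names = FALSE)
    utils::write.csv(truth$cells, file.path(dir, "truth_cells.csv"),
                     row.names = FALSE)
    utils::write.csv(truth$modules_tbl, file.path(dir, "truth_modules.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a count dataset from MTX + TSV/CSV files
#'
#' Loads paired spliced/unspliced MatrixMarket matrices with barcode and
#' gene tables (the layout written by [write_counts()], or CellRanger-style
#' triplets). H5AD input is not supported by this package; export the two
#' layers to MTX instead.
#'
#' @param dir Directory containing the files.
#' @param spliced,unspliced,barcodes,genes,cells File names within `dir`.
#' @param round_policy What to do with non-integer matrix entries:
#'   `"round"` (warn and round, default) or `"error"`.
#' @return An [count_data()] object.
#' @export
read_counts <- function(dir, spliced = "spliced.mtx",
                        unspliced = "unspliced.mtx",
                        barcodes = "barcodes.tsv", genes = "genes.tsv",
                        cells = "cells.csv",
                        round_policy = c("round", "error")) {
  round_policy <- match.arg(round_policy)
  if (grepl("\\.h5ad$", dir, ignore.case = TRUE))
    stop("H5AD input is not supported; export the 'spliced' and 'unspliced'",
         " layers to MatrixMarket (.mtx) and load the directory instead")
  need <- c(spliced, unspliced)
  have <- list.files(dir)
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("missing layer file '", f, "'; directory contains: ",
           paste(have, collapse = ", "))
  rd <- function(f) {
    m <- methods::as(Matrix::readMM(file.path(dir, f)), "CsparseMatrix")
    if (length(m@x) && any(m@x != round(m@x))) {
      if (round_policy == "error") stop("non-integer counts in ", f)
      warning("non-integer counts in ", f, "; rounding to integers")
      m@x <- round(m@x)
    }
    m
  }
  S <- rd(spliced)
  U <- rd(unspliced)
  if (!identical(dim(S), dim(U)))
    stop("layer shapes differ: spliced ", paste(dim(S), collapse = "x"),
         ", unspliced ", paste(dim(U), collapse = "x"))
  bc <- if (file.exists(file.path(dir, barcodes)))
    readLines(file.path(dir, barcodes)) else NULL
  gn <- if (file.exists(file.path(dir, genes))) {
    g <- utils::read.delim(file.path(dir, genes), header = FALSE)
    as.character(g[[1]])
  } else NULL
  if (!is.null(bc)) rownames(S) <- rownames(U) <- bc
  if (!is.null(gn)) colnames(S) <- colnames(U) <- gn
  clusters <- batch <- embedding <- NULL
  if (file.exists(file.path(dir, cells))) {
    meta <- utils::read.csv(file.path(dir, cells))
    if (nrow(meta) != nrow(S))
      stop("cells metadata has ", nrow(meta), " rows for ", nrow(S), " cells")
    if ("cluster" %in% names(meta)) clusters <- meta$cluster
    if ("batch" %in% names(meta)) batch <- meta$batch
    if (all(c("embedding1", "embedding2") %in% names(meta)))
      embedding <- cbind(meta$embedding1, meta$embedding2)
  }
  count_data(S, U, clusters = clusters, batch = batch, embedding = embedding)
}

#' Save / load a fitted model
#'
#' Thin RDS wrappers, so scripted workflows read naturally.
#'
#' @param fit An `mv_fit`.
#' @param path File path (`.rds`).
#' @return `read_fit` returns the `mv_fit`; `write_fit` returns `path`
#'   invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "mv_fit"))
  saveRDS(fit, path)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  fit <- readRDS(path)
  stopifnot(inherits(fit, "mv_fit"))
  fit
}
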