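# Trajectory-direction evaluation: cross-boundary directional correctness
# (CBDir) over ground-truth cluster transitions, plus cluster time
# concordance.

#' k-nearest-neighbor index matrix
#'
#' Euclidean kNN by exhaustive search (adequate at desk scale).
#'
#' @param x A cells x d coordinate matrix.
#' @param k Number of neighbors (self excluded).
#' @return A cells x k integer index matrix.
#' @export
knn_neighbors <- function(x, k = 30) {
  x <- as.matrix(x)
  mv_knn(x, k = min(k, nrow(x) - 1))
}

#' Boundary cells between two clusters
#'
#' Cells of the source cluster with at least one kNN neighbor in the target
#' cluster (and the symmetric set).
#'
#' @param clusters Per-cell cluster labels.
#' @param knn A cells x k neighbor index matrix ([knn_neighbors()]).
#' @param source,target Cluster names.
#' @return A list with integer cell indices `source_boundary` and
#'   `target_boundary`.
#' @export
boundary_cells <- function(clusters, knn, source, target) {
  clusters <- as.character(clusters)
  for (cl in c(source, target))
    if (!cl %in% clusters) stop("unknown cluster: ", cl)
  in_src <- which(clusters == source)
  in_tgt <- which(clusters == target)
  touches <- function(cells, other) {
    cells[vapply(cells, function(c)
      any(clusters[knn[c, ]] %in% other), logical(1))]
  }
  list(source_boundary = touches(in_src, target),
       target_boundary = touches(in_tgt, source))
}

# CBDir for one cell: mean cosine between its velocity and displacement to
# its neighbors inside the target cluster; zero-norm terms contribute 0 and
# reduce the normalizer
mv_cbdir_cell <- function(c, positions, velocities, knn, clusters, target) {
  nbr <- knn[c, ][clusters[knn[c, ]] == target]
  if (length(nbr) == 0) return(NA_real_)
  v <- velocities[c, ]
  vn <- sqrt(sum(v^2))
  tot <- 0
  used <- 0L
  for (cc in nbr) {
    d <- positions[cc, ] - positions[c, ]
    dn <- sqrt(sum(d^2))
    if (vn == 0 || dn == 0) next
    tot <- tot + sum(v * d) / (vn * dn)
    used <- used + 1L
  }
  if (used == 0) return(0)
  tot / used
}

#' Cross-boundary directional correctness (CBDir)
#'
#' For each boundary cell of a ground-truth transition, the mean cosine
#' between its low-dimensional velocity vector and the displacement vectors
#' toward its target-cluster neighbors; the transition score is the mean
#' over boundary cells of the source cluster. Scores lie in \[-1, 1\] and
#' are positive when the flow points from source to target.
#'
#' @param positions Cells x d embedding coordinates.
#' @param velocities Cells x d embedded velocity vectors (e.g. from
#'   [embed_velocity()]).
#' @param clusters Per-cell cluster labels.
#' @param transitions A data frame with columns `source` and `target`.
#' @param k Neighbors for boundary detection (default 30); ignored when
#'   `knn` is given.
#' @param knn Optional precomputed neighbor index matrix.
#' @return A tibble `source`, `target`, `n_boundary`, `cbdir`; transitions
#'   with an empty boundary get `NA` with a warning and are excluded from
#'   the `"mean_cbdir"` attribute (equal weighting over transitions).
#' @export
cbdir <- function(positions, velocities, clusters, transitions, k = 30,
                  knn = NULL) {
  positions <- as.matrix(positions)
  velocities <- as.matrix(velocities)
  stopifnot(nrow(positions) == nrow(velocities),
            ncol(positions) == ncol(velocities))
  clusters <- as.character(clusters)
  if (is.null(knn)) knn <- knn_neighbors(positions, k)
  out <- purrr::pmap_dfr(
    list(transitions$source, transitions$target),
    function(src, tgt) {
      b <- boundary_cells(clusters, knn, src, tgt)
      cells <- b$source_boundary
      if (length(cells) == 0) {
        warning("transition ", src, " -> ", tgt,
                " has no boundary cells; not evaluable")
        return(tibble::tibble(source = src, target = tgt, n_boundary = 0L,
                              cbdir = NA_real_))
      }
      sc <- vapply(cells, mv_cbdir_cell, 0, positions, velocities, knn,
                   clusters, tgt)
      tibble::tibble(source = src, target = tgt,
                     n_boundary = length(cells),
                     cbdir = mean(sc, na.rm = TRUE))
    })
  attr(out, "mean_cbdir") <- mean(out$cbdir, na.rm = TRUE)
  out
}

#' Concordance of estimated cluster times with known transitions
#'
#' For each ground-truth transition, reports +1 if the mean posterior time
#' of the target cluster exceeds that of the source cluster, -1 if it is
#' lower, and 0 (with a tie flag) if equal.
#'
#' @param times Per-cell time estimates (posterior means), or an `mv_fit`.
#' @param clusters Per-cell cluster labels (taken from the fit if omitted).
#' @param transitions A data frame with columns `source` and `target`.
#' @return A tibble `source`, `target`, `dt` (mean time difference),
#'   `direction` (+1/-1/0), `concordant`, `tie`; the fraction of concordant
#'   transitions is attached as attribute `"fraction_concordant"`.
#' @export
time_concordance <- function(times, clusters = NULL, transitions) {
  if (inherits(times, "mv_fit")) {
    if (is.null(clusters)) clusters <- times$data$clusters
    times <- times$posterior_mean$t
  }
  clusters <- as.character(clusters)
  stopifnot(length(times) == length(clusters))
  out <- purrr::pmap_dfr(
    list(transitions$source, transitions$target),
    function(src, tgt) {
      for (cl in c(src, tgt))
        if (!cl %in% clusters) stop("unknown cluster: ", cl)
      dt <- mean(times[clusters == tgt]) - mean(times[clusters == src])
      dir <- sign(dt)
      tibble::tibble(source = src, target = tgt, dt = dt, direction = dir,
                     concordant = dir > 0, tie = dir == 0)
    })
  attr(out, "fraction_concordant") <- mean(out$concordant)
  out
}
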