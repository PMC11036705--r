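# Tumor cell-state lineage scoring and per-cluster state assignment.
#
# The lineage score of a cell for a state is the mean expression over that
# state's signature genes divided by the mean expression over all genes in
# the cell; each cluster is assigned the state with the highest mean score.

#' Per-cell lineage scores for each tumor cell state
#'
#' `score(cell, state) = mean(expr over the state's signature genes) /
#' mean(expr over all genes in the cell)`. The denominator uses all genes in
#' the supplied (post-QC) matrix by default; set `detected_only = TRUE` to
#' restrict it to genes detected in the cell.
#'
#' @param expr A `normalized_matrix` over cells (non-negative values, i.e.
#'   lognorm).
#' @param signatures Named list state -> gene vector; states keep their list
#'   order (it breaks assignment ties).
#' @param detected_only If `TRUE`, the all-gene mean only averages genes
#'   with nonzero expression in that cell.
#' @return A `lineage_scores` object: list with `scores` (cells x states
#'   matrix) and `signatures` (the gene lists after intersecting with the
#'   matrix, sizes logged via message).
#' @export
lineage_score <- function(expr, signatures, detected_only = FALSE) {
  v <- expr$values
  sig_used <- lapply(signatures, function(g) g[g %in% rownames(v)])
  empty <- names(sig_used)[lengths(sig_used) == 0]
  if (length(empty)) {
    stop("signature state(s) with no genes in the matrix: ",
         paste(empty, collapse = ", "))
  }
  message("signature overlap with matrix: ",
          paste(sprintf("%s=%d/%d", names(sig_used), lengths(sig_used),
                        lengths(signatures)), collapse = ", "))
  denom <- if (detected_only) {
    colSums(v) / pmax(colSums(v > 0), 1)
  } else {
    colMeans(v)
  }
  zero_denom <- denom == 0
  if (any(zero_denom)) {
    warning(sum(zero_denom), " cell(s) with zero all-gene mean scored 0")
  }
  scores <- vapply(sig_used, function(g) {
    num <- colMeans(v[g, , drop = FALSE])
    ifelse(zero_denom, 0, num / ifelse(zero_denom, 1, denom))
  }, numeric(ncol(v)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = ncol(v),
                                             dimnames = list(colnames(v),
                                                             names(sig_used)))
  rownames(scores) <- colnames(v)
  structure(list(scores = scores, signatures = sig_used),
            class = "lineage_scores")
}

#' Assign one cell state per cluster
#'
#' Averages the per-cell scores within each cluster and assigns the state
#' with the highest mean lineage score; exact ties go to the earlier state
#' in the signature order, with a tie flag.
#'
#' @param scores A `lineage_scores` object.
#' @param cluster_labels Named (by cell) or positional vector of cluster ids
#'   covering every scored cell.
#' @return The `lineage_scores` object completed with `cluster_labels`,
#'   `cluster_mean_scores` (clusters x states), and `assignments`: data.frame
#'   (cluster, state, tie).
#' @export
assign_cluster_states <- function(scores, cluster_labels) {
  sm <- scores$scores
  cells <- rownames(sm)
  if (!is.null(names(cluster_labels))) {
    if (!all(cells %in% names(cluster_labels))) {
      stop("cluster labels missing for some cells")
    }
    cluster_labels <- cluster_labels[cells]
  } else if (length(cluster_labels) != length(cells)) {
    stop("cluster labels must cover every cell")
  }
  if (is.factor(cluster_labels) && any(table(cluster_labels) == 0)) {
    stop("empty cluster: ",
         paste(names(which(table(cluster_labels) == 0)), collapse = ", "))
  }
  cl <- as.character(cluster_labels)
  if (anyNA(cl)) stop("NA cluster label")
  means <- rowsum(sm, group = cl)
  counts <- as.vector(table(factor(cl, levels = rownames(means))))
  means <- means / counts
  top <- apply(means, 1, function(r) which(r == max(r))[1])
  tie <- apply(means, 1, function(r) sum(r == max(r)) > 1)
  assignments <- data.frame(cluster = rownames(means),
                            state = colnames(means)[top],
                            tie = tie, row.names = NULL,
                            stringsAsFactors = FALSE)
  scores$cluster_labels <- stats::setNames(cl, cells)
  scores$cluster_mean_scores <- means
  scores$assignments <- assignments
  scores
}

#' Convenience baseline clustering
#'
#' k-means on the top principal components of log-normalized expression.
#' Cluster labels are normally an input to this pipeline; this baseline is
#' plumbing for self-contained runs.
#'
#' @param expr A `normalized_matrix` over cells.
#' @param k Number of clusters.
#' @param n_pcs Number of principal components.
#' @param seed RNG seed for k-means starts.
#' @return Named integer vector of cluster ids per cell.
#' @export
baseline_clusters <- function(expr, k, n_pcs = 20, seed = 1) {
  v <- t(expr$values)                     # cells x genes
  keep <- apply(v, 2, stats::sd) > 0
  pc <- stats::prcomp(v[, keep, drop = FALSE], rank. = min(n_pcs, sum(keep)),
                      center = TRUE, scale. = FALSE)
  set.seed(seed)
  km <- stats::kmeans(pc$x, centers = k, nstart = 10, iter.max = 50)
  stats::setNames(km$cluster, rownames(v))
}
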