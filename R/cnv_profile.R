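# Simplified expression-based CNV inference: relative expression against a
# normal reference, smoothed along genomic position within each chromosome,
# then summarized to chromosome-level gain/loss calls. This targets the
# chromosome-arm-scale events visible in glioblastoma (chr7 gain, chr10
# loss); it has no HMM, no subclustering and no Bayesian denoising.

#' Smoothed relative-expression CNV profile
#'
#' For every gene with genomic metadata, the per-cell expression is centered
#' on the reference-cell mean, clipped, smoothed by a centered moving average
#' along genomic order within each chromosome (windows shrink symmetrically
#' at chromosome edges and never cross a boundary), and finally each cell is
#' median-centered.
#'
#' @param expr A `normalized_matrix` over cells (lognorm recommended).
#' @param gene_meta data.frame (gene, chromosome, start) as from
#'   [read_gene_meta()]; genes without metadata are dropped (count logged).
#' @param reference_cells Character vector of cell ids taken as
#'   copy-number-normal.
#' @param window Odd moving-average width in genes.
#' @param clip Symmetric clip applied to centered values before smoothing.
#' @param min_genes_per_chrom Chromosomes with fewer genes are excluded
#'   (warning).
#' @return A `cnv_profile`: list with `values` (cells x genes smoothed
#'   matrix, genes ordered by (chromosome, start)), `gene_meta` (the retained
#'   ordered metadata), `window`, `reference_cells`.
#' @export
infer_cnv_profile <- function(expr, gene_meta, reference_cells,
                              window = 101, clip = 3,
                              min_genes_per_chrom = 3) {
  if (length(reference_cells) == 0) stop("reference_cells must be non-empty")
  if (window %% 2 != 1 || window < 1) stop("window must be a positive odd integer")
  v <- expr$values
  cells <- colnames(v)
  missing_ref <- setdiff(reference_cells, cells)
  if (length(missing_ref)) stop("reference cell(s) not in matrix: ",
                                missing_ref[1])
  meta <- gene_meta[gene_meta$gene %in% rownames(v), , drop = FALSE]
  no_meta <- sum(!rownames(v) %in% gene_meta$gene)
  if (no_meta > 0) message(no_meta, " gene(s) without genomic metadata dropped")
  chrom_sizes <- table(meta$chromosome)
  small <- names(chrom_sizes)[chrom_sizes > 0 & chrom_sizes < min_genes_per_chrom]
  if (length(small)) {
    warning("chromosome(s) with < ", min_genes_per_chrom,
            " genes excluded: ", paste(small, collapse = ", "))
    meta <- meta[!(as.character(meta$chromosome) %in% small), , drop = FALSE]
  }
  meta <- meta[order(meta$chromosome, meta$start), , drop = FALSE]
  if (!nrow(meta)) stop("no genes left after metadata filtering")

  m <- t(v[meta$gene, , drop = FALSE])           # cells x genes
  ref_mean <- colMeans(m[reference_cells, , drop = FALSE])
  r <- sweep(m, 2, ref_mean)
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  chrom <- as.character(meta$chromosome)
  smoothed <- r
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    sm <- .moving_average_rows(r[, idx, drop = FALSE], window)
    # mean-preserving: restore each cell's chromosome mean so chromosome-
    # scale shifts are not attenuated by edge windows
    sm <- sm + (rowMeans(r[, idx, drop = FALSE]) - rowMeans(sm))
    smoothed[, idx] <- sm
  }
  med <- apply(smoothed, 1, stats::median)
  smoothed <- sweep(smoothed, 1, med)
  structure(list(values = smoothed, gene_meta = meta, window = window,
                 clip = clip, reference_cells = reference_cells),
            class = "cnv_profile")
}

# centered moving average along columns of each row, with symmetric
# shrunken windows at the edges (width min(h, i-1, n-i) each side); this
# conserves nothing at edges by itself, but the symmetric shrink keeps each
# smoothed value an average of raw values so a constant block stays constant
.moving_average_rows <- function(m, window) {
  n <- ncol(m)
  if (window == 1 || n == 1) return(m)
  h <- (window - 1) / 2
  cs <- cbind(0, t(apply(m, 1, cumsum)))        # rows x (n+1)
  out <- m
  for (j in seq_len(n)) {
    hh <- min(h, j - 1, n - j)
    lo <- j - hh; hi <- j + hh
    out[, j] <- (cs[, hi + 1] - cs[, lo]) / (hi - lo + 1)
  }
  out
}

#' Chromosome-level gain/loss calls per cell group
#'
#' Averages the smoothed profile over each group's cells and each
#' chromosome's genes; mean shifts at or above `gain_thresh` are called
#' gains, at or below `loss_thresh` losses, otherwise neutral.
#'
#' @param profile A `cnv_profile`.
#' @param groups Named (by cell) vector mapping cells to group labels; every
#'   profiled cell must be covered.
#' @param gain_thresh,loss_thresh Call thresholds on the mean smoothed shift.
#' @return data.frame (group, chromosome, mean_shift, call).
#' @export
call_chromosome_events <- function(profile, groups, gain_thresh = 0.1,
                                   loss_thresh = -0.1) {
  cells <- rownames(profile$values)
  if (is.null(names(groups))) {
    if (length(groups) != length(cells)) stop("groups must cover all cells")
    names(groups) <- cells
  }
  if (!all(cells %in% names(groups))) {
    stop("unknown group label for cell(s): ",
         setdiff(cells, names(groups))[1])
  }
  g <- as.character(groups[cells])
  chrom <- as.character(profile$gene_meta$chromosome)
  chroms <- unique(chrom)
  res <- expand.grid(group = unique(g), chromosome = chroms,
                     stringsAsFactors = FALSE)
  res$mean_shift <- mapply(function(gr, ch) {
    mean(profile$values[g == gr, chrom == ch, drop = FALSE])
  }, res$group, res$chromosome)
  res$call <- ifelse(res$mean_shift >= gain_thresh, "gain",
                     ifelse(res$mean_shift <= loss_thresh, "loss", "neutral"))
  res[order(res$group, match(res$chromosome, chroms)), , drop = FALSE]
}
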