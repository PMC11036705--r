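# Gradient-of-regions analysis: one-vs-rest DE across the ordered regions
# (necrosis outward to the vessels), per-region top-gene selection with
# ribosomal exclusion and show-once deduplication, and z-scaled heatmap
# matrices for genes and cell types.

#' One-vs-rest differential expression per gradient region
#'
#' For each region, fits the same gene-wise model as [fit_deg()] with an
#' indicator of that region against all other labeled spots, optionally
#' adjusted for cell-type proportions exactly as in the niche DE.
#'
#' @param expr A `normalized_matrix` over spots.
#' @param regions data.frame (barcode, label) covering the spots to test.
#' @param props Optional `proportion_matrix` for composition adjustment.
#' @param region_order Gradient order of the labels (necrosis first);
#'   defaults to [gradient_region_levels()] filtered to the labels present.
#' @param moderate,alpha Passed to [fit_deg()].
#' @return Named list region -> `deg_table`, in gradient order.
#' @export
region_one_vs_rest <- function(expr, regions, props = NULL,
                               region_order = NULL, moderate = TRUE,
                               alpha = 0.05) {
  labs <- unique(regions$label)
  if (length(labs) < 2) stop("need at least 2 regions")
  if (any(table(regions$label) < 2)) {
    stop("every region needs at least 2 spots")
  }
  region_order <- intersect(.region_order(labs, region_order), labs)
  tabs <- lapply(region_order, function(r) {
    rl <- data.frame(barcode = regions$barcode,
                     label = ifelse(regions$label == r, r, "rest"),
                     stringsAsFactors = FALSE)
    des <- build_design(rl, props = props, niche_label = r)
    fit_deg(expr, des, moderate = moderate, alpha = alpha)
  })
  names(tabs) <- region_order
  tabs
}

.region_order <- function(labs, region_order) {
  if (is.null(region_order)) {
    known <- intersect(gradient_region_levels(), labs)
    return(c(known, setdiff(labs, known)))
  }
  if (length(setdiff(labs, region_order))) {
    stop("region_order must cover every label present")
  }
  region_order
}

#' Per-region top gradient genes
#'
#' Keeps, per region, the positively enriched significant genes
#' (adjusted p < alpha, logFC > 0), drops ribosomal-prefixed symbols, sorts
#' by logFC descending, takes up to `n`, then deduplicates across regions so
#' a gene appears only under its first (most-necrotic) region.
#'
#' @param tables Named list region -> `deg_table` in gradient order.
#' @param n Per-region cap (default 10).
#' @param alpha Significance cutoff on adjusted p.
#' @param ribosomal_prefixes Symbol prefixes treated as ribosomal.
#' @return Named list region -> ranked character vector (possibly empty).
#' @export
top_genes <- function(tables, n = 10, alpha = 0.05,
                      ribosomal_prefixes = c("RPL", "RPS", "MRPL", "MRPS")) {
  is_ribo <- function(g) {
    Reduce(`|`, lapply(ribosomal_prefixes, startsWith, x = g))
  }
  lists <- lapply(tables, function(t) {
    t <- t[t$adj_p < alpha & t$logFC > 0, , drop = FALSE]
    t <- t[!is_ribo(t$gene), , drop = FALSE]
    t <- t[order(-t$logFC, t$gene), , drop = FALSE]
    utils::head(t$gene, n)
  })
  seen <- character(0)
  for (r in names(lists)) {
    lists[[r]] <- setdiff(lists[[r]], seen)
    seen <- c(seen, lists[[r]])
  }
  lists
}

#' Z-scale matrix rows
#'
#' Subtracts each row's mean and divides by its sd (n - 1 denominator).
#' Constant rows are dropped with a message.
#'
#' @param m Numeric matrix with at least 2 columns.
#' @return The row-scaled matrix (possibly with fewer rows).
#' @export
zscale_rows <- function(m) {
  if (ncol(m) < 2) stop("need at least 2 columns to scale")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    message(sum(sds == 0), " constant row(s) dropped: ",
            paste(utils::head(rownames(m)[sds == 0], 5), collapse = ", "))
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  (m - rowMeans(m)) / sds
}

#' Cell-type localization across the gradient
#'
#' Mean deconvolved proportion per (type, region), z-scaled across regions,
#' the matrix behind the cell-type gradient heatmap.
#'
#' @param props A `proportion_matrix` or spots x types matrix.
#' @param regions data.frame (barcode, label); every included spot must be
#'   labeled.
#' @param region_order Gradient order; defaults as in
#'   [region_one_vs_rest()].
#' @return types x regions z-scaled matrix (constant rows dropped).
#' @export
celltype_gradient <- function(props, regions, region_order = NULL) {
  W <- if (inherits(props, "proportion_matrix")) props$proportions else props
  W <- W[stats::complete.cases(W), , drop = FALSE]
  missing <- setdiff(regions$barcode, rownames(W))
  if (length(missing)) stop("proportions missing for spot(s): ", missing[1])
  labs <- unique(regions$label)
  region_order <- .region_order(labs, region_order)
  counts <- table(factor(regions$label, levels = region_order))
  empty <- names(counts)[counts == 0]
  if (length(empty)) {
    warning("region(s) with no spots dropped: ", paste(empty, collapse = ", "))
    region_order <- setdiff(region_order, empty)
  }
  means <- vapply(region_order, function(r) {
    colMeans(W[regions$barcode[regions$label == r], , drop = FALSE])
  }, numeric(ncol(W)))
  zscale_rows(means)
}

#' Full gradient analysis
#'
#' Convenience wrapper: one-vs-rest DE, top-gene selection, the z-scaled
#' gene x spot heatmap matrix (spots grouped by region in gradient order),
#' and the cell-type gradient matrix.
#'
#' @inheritParams region_one_vs_rest
#' @param n_top Per-region top-gene cap.
#' @return A `gradient_result`: list with `region_order`, `tables`,
#'   `top_genes`, `gene_heatmap`, `celltype_heatmap`, `spot_order`.
#' @export
gradient_analysis <- function(expr, regions, props = NULL,
                              region_order = NULL, n_top = 10,
                              moderate = TRUE, alpha = 0.05) {
  region_order <- .region_order(unique(regions$label), region_order)
  tabs <- region_one_vs_rest(expr, regions, props = props,
                             region_order = region_order,
                             moderate = moderate, alpha = alpha)
  tops <- top_genes(tabs, n = n_top, alpha = alpha)
  genes <- unlist(tops, use.names = FALSE)
  spot_order <- regions$barcode[order(match(regions$label, region_order))]
  gene_heatmap <- NULL
  if (length(genes) >= 1) {
    sub <- expr$values[genes, spot_order, drop = FALSE]
    gene_heatmap <- if (length(spot_order) >= 2) zscale_rows(sub) else sub
  }
  ct <- if (!is.null(props)) {
    celltype_gradient(props, regions, region_order = region_order)
  }
  structure(list(region_order = region_order, tables = tabs,
                 top_genes = tops, gene_heatmap = gene_heatmap,
                 celltype_heatmap = ct, spot_order = spot_order),
            class = "gradient_result")
}
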