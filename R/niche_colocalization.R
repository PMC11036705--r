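# Niche selection and cell-type colocalization statistics.
#
# The palisading-necrosis niche is operationalized as spots whose normalized
# VEGFA expression exceeds a threshold (strictly); spots claimed by more
# than one niche are removed from all of them before downstream analysis.
# Colocalization/segregation of deconvolved cell types is tested by Pearson
# correlation of their per-spot proportions with BH adjustment.

#' Select the palisading-necrosis niche by VEGFA expression
#'
#' Returns exactly the spots whose normalized expression of `gene` is
#' strictly larger than `threshold`.
#'
#' @param norm_spots A `normalized_matrix` over spots.
#' @param gene Marker gene (default VEGFA).
#' @param threshold Strict lower cutoff on normalized expression.
#' @return Character vector of spot barcodes.
#' @export
select_necrosis_niche <- function(norm_spots, gene = "VEGFA", threshold = 3) {
  v <- norm_spots$values
  if (!gene %in% rownames(v)) stop("gene not in matrix: ", gene)
  colnames(v)[v[gene, ] > threshold]
}

#' Remove overlaps between niches
#'
#' Any spot appearing in two or more niches is removed from all of them
#' (removed, not reassigned), leaving disjoint sets.
#'
#' @param niches Named list label -> character vector of spot barcodes.
#' @return data.frame (barcode, label) region annotation over the disjoint
#'   sets, with a `removed` attribute listing the discarded barcodes.
#' @export
resolve_niche_overlaps <- function(niches) {
  if (any(lengths(niches) == 0)) {
    stop("empty niche: ", names(niches)[lengths(niches) == 0][1])
  }
  all_bc <- unlist(niches, use.names = FALSE)
  dup <- unique(all_bc[duplicated(all_bc)])
  clean <- lapply(niches, setdiff, y = dup)
  ann <- data.frame(barcode = unlist(clean, use.names = FALSE),
                    label = rep(names(clean), lengths(clean)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(ann, "removed") <- dup
  ann
}

#' Pairwise colocalization/segregation of cell-type proportions
#'
#' For every unordered pair of types, the Pearson correlation of the
#' per-spot proportions with a two-sided p-value from the t-distribution on
#' n - 2 df (as `cor.test` computes it), BH-adjusted jointly across all
#' pairs. A pair is called `segregate` if r < 0 and adjusted p < alpha,
#' `colocalize` if r > 0 and adjusted p < alpha, otherwise `ns`. Note that
#' the simplex constraint on proportions induces some negative correlation
#' a priori; the test is reported as-is (see the `caveat` attribute).
#'
#' @param props A `proportion_matrix` or a plain spots x types matrix.
#' @param alpha Significance cutoff on adjusted p.
#' @return data.frame (type_a, type_b, pearson_r, p_value, adj_p, n_spots,
#'   verdict). Pairs with a zero-variance member get NA statistics and are
#'   excluded from the BH family.
#' @export
pairwise_proportion_correlation <- function(props, alpha = 0.05) {
  W <- if (inherits(props, "proportion_matrix")) props$proportions else props
  W <- W[stats::complete.cases(W), , drop = FALSE]
  if (nrow(W) < 3) stop("need at least 3 spots")
  if (ncol(W) < 2) stop("need at least 2 types")
  types <- colnames(W)
  pairs <- utils::combn(types, 2)
  n <- nrow(W)
  res <- data.frame(type_a = pairs[1, ], type_b = pairs[2, ],
                    pearson_r = NA_real_, p_value = NA_real_,
                    adj_p = NA_real_, n_spots = n,
                    verdict = "ns", stringsAsFactors = FALSE)
  sds <- apply(W, 2, stats::sd)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    if (sds[a] == 0 || sds[b] == 0) next
    ct <- stats::cor.test(W[, a], W[, b], method = "pearson")
    res$pearson_r[i] <- unname(ct$estimate)
    res$p_value[i] <- ct$p.value
  }
  testable <- !is.na(res$p_value)
  if (sum(!testable)) {
    message(sum(!testable), " pair(s) with a zero-variance type excluded ",
            "from BH adjustment")
  }
  res$adj_p[testable] <- bh_adjust(res$p_value[testable])
  sig <- testable & res$adj_p < alpha
  res$verdict[sig & res$pearson_r < 0] <- "segregate"
  res$verdict[sig & res$pearson_r > 0] <- "colocalize"
  res$verdict[!testable] <- NA_character_
  attr(res, "caveat") <- paste(
    "proportions are compositional (rows sum to 1); the simplex induces",
    "negative correlation between types a priori")
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: sort ascending, take running minima of
#' `p_j * m / j` from the largest rank down, restore the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1] with no NA")
  }
  stats::p.adjust(p, method = "BH")
}
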