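# Quality filters at the study's printed thresholds, and the two
# normalizations used downstream (log-normalization for the reference,
# analytic Pearson residuals for the spatial matrix).

.mito_fraction <- function(cm, mito_prefix) {
  is_mito <- startsWith(gene_ids(cm), mito_prefix)
  totals <- colSums(cm$values)
  mito <- if (any(is_mito)) colSums(cm$values[is_mito, , drop = FALSE]) else 0
  ifelse(totals > 0, mito / totals, 0)
}

#' Filter low-quality cells
#'
#' Removes cells expressing fewer than `min_genes` genes, or with a
#' mitochondrial read fraction above `max_mito_frac`. Both comparisons
#' follow the study's prose: "fewer than 500" removes strictly below 500,
#' "more than 5%" removes strictly above 0.05 — a cell at exactly 500
#' expressed genes and exactly 5% mitochondrial reads is retained.
#'
#' @param counts A cell `count_matrix`.
#' @param min_genes Minimum number of genes with count > 0.
#' @param max_mito_frac Maximum mitochondrial count fraction.
#' @param mito_prefix Gene-symbol prefix identifying mitochondrial genes.
#' @return The filtered `count_matrix` (column order preserved) with a
#'   `removal_log` attribute: data.frame (barcode, n_genes, mito_frac,
#'   reason) for every removed cell.
#' @export
filter_cells <- function(counts, min_genes = 500, max_mito_frac = 0.05,
                         mito_prefix = "MT-") {
  stopifnot(counts$unit_kind == "cell")
  n_expressed <- colSums(counts$values > 0)
  mito <- .mito_fraction(counts, mito_prefix)
  too_few <- n_expressed < min_genes
  too_mito <- mito > max_mito_frac
  keep <- !(too_few | too_mito)
  if (!any(keep)) stop("cell filter removed every cell")
  reason <- ifelse(too_few & too_mito, "low_genes;high_mito",
                   ifelse(too_few, "low_genes", "high_mito"))
  log <- data.frame(barcode = unit_ids(counts)[!keep],
                    n_genes = n_expressed[!keep],
                    mito_frac = mito[!keep],
                    reason = reason[!keep], row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- subset_counts(counts, units = keep)
  attr(out, "removal_log") <- log
  out
}

#' Filter spatial spots by mitochondrial fraction
#'
#' Drops spots with over `max_mito_frac` mitochondrial reads ("over 5%" is
#' strict: a spot at exactly 5% is retained).
#'
#' @inheritParams filter_cells
#' @param counts A spot `count_matrix`.
#' @return Filtered `count_matrix` with a `removal_log` attribute.
#' @export
filter_spots <- function(counts, max_mito_frac = 0.05, mito_prefix = "MT-") {
  stopifnot(counts$unit_kind == "spot")
  mito <- .mito_fraction(counts, mito_prefix)
  keep <- mito <= max_mito_frac
  if (!any(keep)) stop("spot filter removed every spot")
  log <- data.frame(barcode = unit_ids(counts)[!keep],
                    mito_frac = mito[!keep],
                    reason = rep("high_mito", sum(!keep)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- subset_counts(counts, units = keep)
  attr(out, "removal_log") <- log
  out
}

#' Log-normalize counts
#'
#' `ln(1 + count * scale_factor / unit_total)`, the standard library-size
#' normalization for single-cell data.
#'
#' @param counts A `count_matrix`.
#' @param scale_factor Target library size (default 1e4).
#' @return A `normalized_matrix`: list with `values` (genes x units),
#'   `method = "lognorm"`, `scale_factor`, `unit_kind`.
#' @export
lognormalize <- function(counts, scale_factor = 1e4) {
  totals <- colSums(counts$values)
  if (any(totals == 0)) {
    stop("unit(s) with zero total counts: ",
         paste(utils::head(unit_ids(counts)[totals == 0], 3), collapse = ", "))
  }
  v <- log1p(sweep(counts$values, 2, scale_factor / totals, `*`))
  structure(list(values = v, method = "lognorm",
                 scale_factor = scale_factor, unit_kind = counts$unit_kind),
            class = "normalized_matrix")
}

#' Analytic Pearson-residual normalization
#'
#' Variance-stabilizing transform used for the spatial matrix: under a
#' null model where every entry is Poisson-like around
#' `mu_gu = (gene total)(unit total) / grand total`, the residual
#' `(x - mu) / sqrt(mu + mu^2 / theta)` with a fixed negative-binomial
#' dispersion `theta` is approximately standard normal. Residuals are
#' clipped to `±sqrt(n_units)`.
#'
#' @param counts A `count_matrix`.
#' @param theta Fixed NB dispersion of the null model.
#' @return A `normalized_matrix` with `method = "pearson_residual"`.
#' @export
pearson_residual_normalize <- function(counts, theta = 100) {
  x <- counts$values
  gt <- rowSums(x); ut <- colSums(x); total <- sum(x)
  if (total == 0) stop("all-zero count matrix")
  mu <- outer(gt, ut) / total
  r <- (x - mu) / sqrt(mu + mu^2 / theta)
  r[mu == 0] <- 0
  clip <- sqrt(ncol(x))
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  structure(list(values = r, method = "pearson_residual", theta = theta,
                 unit_kind = counts$unit_kind),
            class = "normalized_matrix")
}

#' @exportS3Method base::print
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("normalized_matrix (%s): %d genes x %d %ss\n", x$method,
              nrow(x$values), ncol(x$values), x$unit_kind))
  invisible(x)
}
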