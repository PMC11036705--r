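# Gene-wise linear-model differential expression between regions, with
# optional adjustment for deconvolved cell-type proportions (tumor states
# collapsed into one "tumor" column), empirical-Bayes moderated t-statistics
# (method-of-moments prior on log s^2), BH adjustment, and cross-sample
# logFC comparison.

#' Build a DE design matrix
#'
#' Intercept plus one 0/1 niche indicator; when proportions are supplied,
#' the tumor-state columns are collapsed into a single "tumor" covariate and
#' each non-tumor type keeps its own column, with one non-tumor column
#' dropped to break the simplex collinearity (dropped type logged).
#'
#' @param region_labels data.frame (barcode, label) restricted to exactly
#'   two labels: the niche of interest and the reference region.
#' @param props Optional `proportion_matrix` (or spots x types matrix) to
#'   adjust for cell composition.
#' @param tumor_states Types collapsed into the "tumor" column.
#' @param niche_label Which label the indicator marks with 1; defaults to
#'   the label that is not `"generic_tumor"`.
#' @param drop_type Non-tumor type whose column is dropped; default the last
#'   non-tumor column.
#' @return A `design_matrix`: list with `matrix` (spots x covariates, rows
#'   named by barcode), `coef` (the niche column name), `dropped_type`,
#'   `pruned` (degenerate columns removed).
#' @export
build_design <- function(region_labels, props = NULL,
                         tumor_states = TUMOR_STATES,
                         niche_label = NULL, drop_type = NULL) {
  labs <- unique(region_labels$label)
  if (length(labs) != 2) {
    stop("design needs exactly 2 region labels, got: ",
         paste(labs, collapse = ", "))
  }
  if (is.null(niche_label)) {
    niche_label <- setdiff(labs, "generic_tumor")[1]
  }
  if (!niche_label %in% labs) stop("niche_label not among the labels")
  if (min(table(region_labels$label)) < 2) {
    stop("each region needs at least 2 spots")
  }
  bc <- region_labels$barcode
  X <- cbind(intercept = 1,
             niche = as.numeric(region_labels$label == niche_label))
  colnames(X)[2] <- "niche"
  rownames(X) <- bc
  dropped_type <- NULL
  if (!is.null(props)) {
    W <- if (inherits(props, "proportion_matrix")) props$proportions else props
    missing <- setdiff(bc, rownames(W))
    if (length(missing)) stop("proportions missing for spot(s): ", missing[1])
    W <- W[bc, , drop = FALSE]
    ts <- intersect(colnames(W), tumor_states)
    nt <- setdiff(colnames(W), tumor_states)
    tumor <- if (length(ts)) rowSums(W[, ts, drop = FALSE]) else NULL
    if (is.null(drop_type)) drop_type <- nt[length(nt)]
    dropped_type <- drop_type
    nt_keep <- setdiff(nt, drop_type)
    message("dropped proportion column for identifiability: ", drop_type)
    add <- cbind(tumor = tumor, W[, nt_keep, drop = FALSE])
    X <- cbind(X, add)
  }
  # prune degenerate (zero-variance, non-intercept) columns
  v <- apply(X[, -1, drop = FALSE], 2, stats::var)
  pruned <- colnames(X)[-1][v == 0]
  if (length(pruned)) {
    message("pruned degenerate design column(s): ",
            paste(pruned, collapse = ", "))
    X <- X[, !(colnames(X) %in% pruned), drop = FALSE]
  }
  q <- qr(X)
  if (q$rank < ncol(X)) {
    stop("design is rank deficient; collinear columns: ",
         paste(colnames(X)[q$pivot[(q$rank + 1):ncol(X)]], collapse = ", "))
  }
  structure(list(matrix = X, coef = "niche", dropped_type = dropped_type,
                 pruned = pruned),
            class = "design_matrix")
}

# solve trigamma(x) = y by Newton's method (monotone decreasing trigamma)
.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}

#' Gene-wise linear model with empirical-Bayes moderated t
#'
#' Per gene: ordinary least squares on the design; the residual variances
#' `s2_g` (d residual df) inform a scaled-inverse-chi-square prior
#' `(d0, s0^2)` estimated by method of moments on `log s2` (Smyth-style:
#' matching the mean and variance of `log s2 - digamma(d/2) + log(d/2)`
#' against the trigamma of the prior df). The moderated variance
#' `(d0 s0^2 + d s2_g)/(d0 + d)` yields a t-statistic on `d0 + d` df.
#' If the prior-df estimate is non-finite (or `moderate = FALSE`), ordinary
#' unmoderated t-statistics are used.
#'
#' @param expr A `normalized_matrix` over spots.
#' @param design A `design_matrix` from [build_design()], or a plain numeric
#'   matrix with rownames matching spot barcodes.
#' @param coef Name of the tested coefficient (default the design's niche
#'   indicator).
#' @param moderate Use the empirical-Bayes prior (default) or plain OLS t.
#' @param alpha Cutoff on BH-adjusted p for the significance flag.
#' @return A `deg_table` data.frame: gene, logFC, t, p_value, adj_p,
#'   significant; attributes `d0`, `s0_sq`, `df_residual`.
#' @export
fit_deg <- function(expr, design, coef = NULL, moderate = TRUE,
                    alpha = 0.05) {
  X <- if (inherits(design, "design_matrix")) design$matrix else design
  if (is.null(coef)) {
    coef <- if (inherits(design, "design_matrix")) design$coef else
      colnames(X)[2]
  }
  if (!coef %in% colnames(X)) stop("coefficient not in design: ", coef)
  v <- expr$values
  missing <- setdiff(rownames(X), colnames(v))
  if (length(missing)) stop("expression missing for spot(s): ", missing[1])
  E <- v[, rownames(X), drop = FALSE]           # genes x spots
  n <- ncol(E); p <- ncol(X)
  d <- n - p
  if (d < 1) stop("need more spots than design columns")
  XtXi <- solve(crossprod(X))
  B <- E %*% X %*% XtXi                          # genes x p coefficients
  fitted <- B %*% t(X)
  res <- E - fitted
  s2 <- rowSums(res^2) / d
  se_mult <- sqrt(XtXi[coef, coef])
  beta <- B[, coef]

  zero_var <- s2 <= .Machine$double.eps * 100
  ok <- !zero_var
  d0 <- 0; s0_sq <- NA_real_
  if (moderate && sum(ok) >= 3) {
    z <- log(s2[ok])
    e <- z - digamma(d / 2) + log(d / 2)
    evar <- stats::var(e) - trigamma(d / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * .trigamma_inverse(evar)
      s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
    if (!is.finite(d0) || !is.finite(s0_sq) || d0 <= 0) {
      d0 <- 0; s0_sq <- NA_real_                 # fall back to no moderation
    }
  }
  s2_mod <- if (d0 > 0) (d0 * s0_sq + d * s2) / (d0 + d) else s2
  df_total <- d0 + d
  tstat <- beta / (sqrt(s2_mod) * se_mult)
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)
  tstat[zero_var & beta == 0] <- 0
  pval[zero_var] <- 1
  if (any(zero_var)) {
    message(sum(zero_var), " zero-variance gene(s) assigned p = 1")
  }
  pval[!is.finite(pval)] <- 1
  out <- data.frame(gene = rownames(E), logFC = beta, t = tstat,
                    p_value = pval, adj_p = bh_adjust(pval),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$significant <- out$adj_p < alpha
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  attr(out, "df_residual") <- d
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Compare logFC between two DE tables
#'
#' Pearson correlation of logFC over shared genes (the cross-sample
#' reproducibility statistic), plus a 3x3 cross-table of significance
#' categories (sig-up / sig-down / ns) between the two tables.
#'
#' @param deg_a,deg_b `deg_table`s (e.g. the same niche contrast in two
#'   samples).
#' @return List: `pearson_r`, `n_shared`, `cross_table`.
#' @export
compare_logfc <- function(deg_a, deg_b) {
  shared <- intersect(deg_a$gene, deg_b$gene)
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  a <- deg_a[match(shared, deg_a$gene), ]
  b <- deg_b[match(shared, deg_b$gene), ]
  cat_of <- function(t) {
    factor(ifelse(t$significant & t$logFC > 0, "sig-up",
                  ifelse(t$significant & t$logFC < 0, "sig-down", "ns")),
           levels = c("sig-up", "sig-down", "ns"))
  }
  list(pearson_r = stats::cor(a$logFC, b$logFC),
       n_shared = length(shared),
       cross_table = table(a = cat_of(a), b = cat_of(b)))
}

#' Top genes by absolute logFC, per direction
#'
#' Up to `n` genes with the largest logFC among the positives and up to `n`
#' with the most negative, the gene lists exported for external enrichment
#' tools. Ties in |logFC| break stably by gene id.
#'
#' @param deg A `deg_table`.
#' @param n Per-direction cap.
#' @param significant_only Restrict to BH-significant genes first.
#' @return List with `up` and `down` character vectors (ranked).
#' @export
select_top_genes <- function(deg, n = 100, significant_only = FALSE) {
  if (!nrow(deg)) stop("empty DEG table")
  t <- deg
  if (significant_only) t <- t[t$significant, , drop = FALSE]
  up <- t[t$logFC > 0, , drop = FALSE]
  up <- up[order(-up$logFC, up$gene), , drop = FALSE]
  down <- t[t$logFC < 0, , drop = FALSE]
  down <- down[order(down$logFC, down$gene), , drop = FALSE]
  list(up = utils::head(up$gene, n), down = utils::head(down$gene, n))
}
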