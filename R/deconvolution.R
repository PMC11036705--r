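# Spot deconvolution against the matched single-nucleus reference: a plain
# Poisson topic-model maximum-likelihood fit. Each spot's counts are modeled
# as y_g ~ Poisson(N * sum_t w_t mu_tg) with the w on the simplex and mu_t
# the reference type's gene rates; the multiplicative EM update is the
# classic mixture/NMF step with a guaranteed non-decreasing log-likelihood.

#' Build reference signature profiles
#'
#' Cell types with fewer than `min_cells` cells are removed from the
#' reference (the matched deconvolution method's printed minimum is 25; a
#' type with exactly 25 cells is retained). Each retained profile is the
#' gene-wise summed counts of that type's cells, plus a pseudocount,
#' normalized to sum to one.
#'
#' @param ref_counts A cell `count_matrix`.
#' @param type_labels Named (by cell) or positional vector of cell-type
#'   labels covering all cells.
#' @param min_cells Minimum cells per retained type.
#' @param pseudocount Added to every gene before normalizing, keeping the
#'   likelihood finite for genes unseen in a type.
#' @return A `signature_profiles` object: `profiles` (types x genes, rows on
#'   the simplex), `cells_per_type`, `dropped_types`.
#' @export
build_signatures <- function(ref_counts, type_labels, min_cells = 25,
                             pseudocount = 1e-9) {
  cells <- unit_ids(ref_counts)
  if (!is.null(names(type_labels))) {
    if (!all(cells %in% names(type_labels))) {
      stop("type labels missing for some cells")
    }
    type_labels <- type_labels[cells]
  } else if (length(type_labels) != length(cells)) {
    stop("type labels must cover all cells")
  }
  tl <- as.character(type_labels)
  tab <- table(tl)
  dropped <- names(tab)[tab < min_cells]
  kept <- names(tab)[tab >= min_cells]
  if (length(dropped)) {
    message("type(s) with < ", min_cells, " cells dropped from reference: ",
            paste(dropped, collapse = ", "))
  }
  if (length(kept) < 2) stop("fewer than 2 cell types retained")
  prof <- t(vapply(kept, function(t)
    rowSums(ref_counts$values[, tl == t, drop = FALSE]),
    numeric(nrow(ref_counts$values))))
  prof <- prof + pseudocount
  prof <- prof / rowSums(prof)
  colnames(prof) <- gene_ids(ref_counts)
  structure(list(profiles = prof,
                 cells_per_type = as.vector(tab[kept]),
                 dropped_types = dropped),
            class = "signature_profiles")
}

#' Deconvolve spots into cell-type proportions
#'
#' Per spot, maximizes the Poisson mixture log-likelihood
#' `sum_g [ y_g log(sum_t w_t mu_tg) ] - N` over the simplex via the
#' multiplicative EM update
#' `w_t <- w_t * sum_g ( y_g mu_tg / sum_u w_u mu_ug ) / sum_g y_g`,
#' started uniform. The update never decreases the log-likelihood (asserted
#' every iteration). Genes are intersected between spots and profiles.
#'
#' @param spot_counts A spot `count_matrix`.
#' @param profiles A `signature_profiles` object.
#' @param max_iter,tol Stop at `max_iter` iterations or when the relative
#'   log-likelihood change drops below `tol`.
#' @return A `proportion_matrix`: `proportions` (spots x types, rows on the
#'   simplex; all-zero spots are `NA` and flagged), `convergence` data.frame
#'   (barcode, iterations, loglik, converged, zero_total), `shared_genes`.
#' @export
deconvolve <- function(spot_counts, profiles, max_iter = 500, tol = 1e-8) {
  mu <- profiles$profiles
  shared <- intersect(colnames(mu), gene_ids(spot_counts))
  if (length(shared) < 1) stop("no shared genes between spots and profiles")
  message(length(shared), " shared gene(s) used for deconvolution")
  mu <- mu[, shared, drop = FALSE]
  mu <- mu / rowSums(mu)                      # renormalize on shared genes
  Y <- t(spot_counts$values[shared, , drop = FALSE])   # spots x genes
  n_spots <- nrow(Y); n_types <- nrow(mu)
  totals <- rowSums(Y)
  zero <- totals == 0
  W <- matrix(1 / n_types, n_spots, n_types,
              dimnames = list(rownames(Y), rownames(mu)))
  iters <- integer(n_spots)
  ll <- rep(NA_real_, n_spots)
  active <- which(!zero)
  loglik_of <- function(W, idx) {
    lam <- W[idx, , drop = FALSE] %*% mu
    rowSums(Y[idx, , drop = FALSE] * log(lam)) - totals[idx]
  }
  ll_prev <- rep(-Inf, n_spots)
  ll_prev[active] <- loglik_of(W, active)
  for (it in seq_len(max_iter)) {
    if (!length(active)) break
    Wa <- W[active, , drop = FALSE]
    lam <- Wa %*% mu                           # spots x genes mixture rates
    ratio <- Y[active, , drop = FALSE] / lam
    Wa_new <- Wa * (ratio %*% t(mu)) / totals[active]
    ll_new <- {
      lam2 <- Wa_new %*% mu
      rowSums(Y[active, , drop = FALSE] * log(lam2)) - totals[active]
    }
    if (any(ll_new < ll_prev[active] - 1e-6 * pmax(1, abs(ll_prev[active])))) {
      stop("EM log-likelihood decreased; this should be impossible")
    }
    W[active, ] <- Wa_new
    iters[active] <- it
    done <- abs(ll_new - ll_prev[active]) <
      tol * pmax(1, abs(ll_new))
    ll_prev[active] <- ll_new
    ll[active] <- ll_new
    active <- active[!done]
  }
  W[zero, ] <- NA_real_
  conv <- data.frame(barcode = rownames(Y), iterations = iters,
                     loglik = ll, converged = !zero & iters < max_iter,
                     zero_total = zero, row.names = NULL,
                     stringsAsFactors = FALSE)
  if (any(zero)) {
    warning(sum(zero), " spot(s) with zero total counts flagged (NA rows)")
  }
  structure(list(proportions = W, convergence = conv,
                 shared_genes = shared),
            class = "proportion_matrix")
}

#' @exportS3Method base::print
print.proportion_matrix <- function(x, ...) {
  cat(sprintf("proportion_matrix: %d spots x %d types (%d flagged)\n",
              nrow(x$proportions), ncol(x$proportions),
              sum(x$convergence$zero_total)))
  invisible(x)
}
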