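# Paired synthetic reference (single-nucleus) + spatial datasets with known
# ground truth: marker programs per cell type, chromosome-scale expression
# folds in tumor cells (chr7 up, chr10 down by default), spots as small
# mixtures of cells laid out in segregated tumor-state territories, a
# necrotic focus carrying a VEGFA gradient, and vessel loci.

TUMOR_STATES <- c("MES-like", "AC-like", "OPC-like", "NPC-like")

#' Build a simulation configuration
#'
#' Defaults describe one synthetic glioblastoma section: eight cell
#' populations (four Neftel-style tumor states plus macrophage,
#' oligodendrocyte, endothelial, neuron), negative-binomial counts with
#' genome-wide Gamma baseline means, disjoint marker programs, a chromosome 7
#' expression gain and chromosome 10 loss confined to tumor states, tumor
#' states segregated into grid quadrants, a necrotic focus whose
#' surroundings are macrophage-enriched and VEGFA-high, and vessel loci that
#' recruit endothelial cells.
#'
#' @param n_genes Number of genes (mitochondrial pseudo-genes are added on
#'   top of this).
#' @param cell_types Ordered character vector; the intersection with the four
#'   canonical tumor states is treated as tumor.
#' @param n_cells_per_type Named integer vector (recycled if scalar).
#' @param marker_genes_per_type,marker_fold_change Disjoint marker program
#'   size and its expression fold.
#' @param baseline_shape,baseline_rate Gamma parameters for per-gene baseline
#'   mean counts.
#' @param nb_dispersion Negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param libsize_sdlog Log-normal sd of per-cell library-size factors.
#' @param cnv_events List of `list(chromosome=, fold_change=,
#'   affected_types=)`; folds multiply every gene mean on that chromosome in
#'   the affected types.
#' @param n_mito_genes,mito_fraction Number of `MT-` pseudo-genes and the
#'   expected fraction of counts they carry in a healthy cell.
#' @param low_quality_fraction,low_quality_mito_mult Fraction of reference
#'   cells given an inflated mitochondrial load (so QC has work to do) and
#'   the inflation factor.
#' @param grid_shape Spot grid (rows, cols); all grid spots are in tissue.
#' @param cells_per_spot Cells pooled into each spot.
#' @param territory_map Optional rows x cols character matrix of tumor-state
#'   names; default splits the grid into quadrants in `cell_types` order.
#' @param necrosis_center,necrosis_radius Grid coordinates (row, col) and
#'   radius of the necrotic focus; default centers it in the first tumor
#'   state's quadrant.
#' @param vessel_loci Matrix/list of grid points with a vessel; default
#'   places two in the OPC-like quadrant and one in the NPC-like quadrant.
#' @param vegfa_gain_at_necrosis Fold by which the VEGFA mean is raised at
#'   the necrosis center; decays as `1 + (gain-1) exp(-d/tau_vegfa)`.
#' @param tau_vegfa,tau_macrophage,tau_vessel Length scales (grid units) of
#'   the VEGFA gradient, macrophage enrichment, and endothelial recruitment.
#' @param seed Integer; fully determines both datasets (the spatial stage
#'   consumes `seed + 1`).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       cell_types = c(TUMOR_STATES, "macrophage",
                                      "oligodendrocyte", "endothelial",
                                      "neuron"),
                       n_cells_per_type = 150,
                       marker_genes_per_type = 20,
                       marker_fold_change = 4,
                       baseline_shape = 2,
                       baseline_rate = 3,
                       nb_dispersion = 10,
                       libsize_sdlog = 0.2,
                       cnv_events = list(
                         list(chromosome = "7", fold_change = 1.5,
                              affected_types = TUMOR_STATES),
                         list(chromosome = "10", fold_change = 0.5,
                              affected_types = TUMOR_STATES)),
                       n_mito_genes = 13,
                       mito_fraction = 0.02,
                       low_quality_fraction = 0.03,
                       low_quality_mito_mult = 10,
                       grid_shape = c(20, 20),
                       cells_per_spot = 8,
                       territory_map = NULL,
                       necrosis_center = NULL,
                       necrosis_radius = 3,
                       vessel_loci = NULL,
                       vegfa_gain_at_necrosis = 8,
                       tau_vegfa = 2,
                       tau_macrophage = 3,
                       tau_vessel = 1.5,
                       seed = 1L) {
  if (length(n_cells_per_type) == 1L) {
    n_cells_per_type <- stats::setNames(rep(n_cells_per_type,
                                            length(cell_types)), cell_types)
  }
  if (!all(cell_types %in% names(n_cells_per_type))) {
    stop("n_cells_per_type must cover every cell type")
  }
  if (any(n_cells_per_type[cell_types] < 1)) {
    stop("every cell type needs at least 1 cell")
  }
  if (marker_fold_change <= 0 || vegfa_gain_at_necrosis <= 0) {
    stop("fold changes must be positive")
  }
  for (ev in cnv_events) {
    if (ev$fold_change <= 0) stop("cnv fold_change must be positive")
  }
  cfg <- list(n_genes = n_genes, cell_types = cell_types,
              n_cells_per_type = n_cells_per_type[cell_types],
              marker_genes_per_type = marker_genes_per_type,
              marker_fold_change = marker_fold_change,
              baseline_shape = baseline_shape, baseline_rate = baseline_rate,
              nb_dispersion = nb_dispersion, libsize_sdlog = libsize_sdlog,
              cnv_events = cnv_events, n_mito_genes = n_mito_genes,
              mito_fraction = mito_fraction,
              low_quality_fraction = low_quality_fraction,
              low_quality_mito_mult = low_quality_mito_mult,
              grid_shape = grid_shape, cells_per_spot = cells_per_spot,
              territory_map = territory_map,
              necrosis_center = necrosis_center,
              necrosis_radius = necrosis_radius, vessel_loci = vessel_loci,
              vegfa_gain_at_necrosis = vegfa_gain_at_necrosis,
              tau_vegfa = tau_vegfa, tau_macrophage = tau_macrophage,
              tau_vessel = tau_vessel, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

tumor_states_of <- function(config) {
  intersect(config$cell_types, TUMOR_STATES)
}

# Deterministic gene universe shared by reference and spatial stages:
# regular genes G0001.. spread over chromosomes 1-22 in contiguous blocks,
# one gene renamed VEGFA, a dozen renamed RPL/RPS decoys, then MT- genes
# (excluded from genomic metadata). Marker genes are evenly spaced across
# the genome so no single chromosome carries one type's program.
.gene_universe <- function(config) {
  n <- config$n_genes
  genes <- sprintf("G%04d", seq_len(n))
  chroms <- as.character(1:22)
  chrom_of <- chroms[ceiling(seq_len(n) / (n / 22))]
  start <- unlist(lapply(split(seq_len(n), factor(chrom_of, levels = chroms)),
                         function(i) (seq_along(i) - 1L) * 10000L),
                  use.names = FALSE)
  # special symbols: VEGFA lives wherever its index falls (truth: chr6 block)
  n_rib <- 12L
  rib_names <- c(sprintf("RPL%d", 1:6), sprintf("RPS%d", 1:6))
  vegfa_idx <- which(chrom_of == "6")[1]
  rib_idx <- setdiff(round(seq(3, n - 2, length.out = n_rib + 1)),
                     vegfa_idx)[seq_len(n_rib)]
  genes[rib_idx] <- rib_names
  genes[vegfa_idx] <- "VEGFA"
  n_types <- length(config$cell_types)
  n_marker <- config$marker_genes_per_type * n_types
  if (n_marker > n - n_rib - 1) stop("not enough genes for the marker programs")
  pool <- setdiff(seq_len(n), c(rib_idx, vegfa_idx))
  marker_idx <- pool[round(seq(1, length(pool), length.out = n_marker))]
  marker_of <- rep(NA_character_, n)
  # interleave types along the genome so no chromosome concentrates one
  # type's program (would masquerade as a CNV)
  marker_of[marker_idx] <- rep(config$cell_types,
                               length.out = n_marker)
  mito <- sprintf("MT-%d", seq_len(config$n_mito_genes))
  list(genes = genes, chrom_of = chrom_of, start = start,
       marker_of = marker_of, mito = mito, vegfa = "VEGFA")
}

# genes x types matrix of per-cell expected counts (library factor 1),
# including mitochondrial rows; the generative mean is
# base_g * markerfold(g,t) * cnvfold(chrom(g),t).
.type_mean_matrix <- function(config, universe, base_means, mito_means) {
  types <- config$cell_types
  mu <- matrix(base_means, nrow = length(universe$genes), ncol = length(types),
               dimnames = list(universe$genes, types))
  for (t in types) {
    mu[which(universe$marker_of == t), t] <-
      mu[which(universe$marker_of == t), t] * config$marker_fold_change
  }
  for (ev in config$cnv_events) {
    on_chr <- universe$chrom_of == ev$chromosome
    aff <- intersect(ev$affected_types, types)
    mu[on_chr, aff] <- mu[on_chr, aff] * ev$fold_change
  }
  rbind(mu, matrix(mito_means, nrow = length(universe$mito),
                   ncol = length(types),
                   dimnames = list(universe$mito, types)))
}

#' Simulate the single-nucleus reference dataset
#'
#' Draws raw counts for each cell negative-binomially around
#' `base_g * markerfold(g, type) * cnvfold(chrom(g), type) * libsize_cell`.
#' A configurable fraction of cells gets an inflated mitochondrial load so
#' the QC filters are exercised.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (a cell `count_matrix`) and `truth`, a ground
#'   truth list carrying per-cell type labels, the low-quality flag, the
#'   marker-of map, per-(type, chromosome) CNV folds, the gene metadata
#'   table, the tumor-state signature lists, and the genes x types mean
#'   matrix reused by [simulate_spatial()].
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  uni <- .gene_universe(config)
  base_means <- stats::rgamma(config$n_genes, shape = config$baseline_shape,
                              rate = config$baseline_rate)
  base_means <- pmax(base_means, 1e-3)
  # MT- pseudo-gene means sized so the expected mito fraction is as asked
  mito_total <- sum(base_means) * config$mito_fraction /
    (1 - config$mito_fraction)
  w <- stats::rgamma(config$n_mito_genes, shape = 4, rate = 1)
  mito_means <- mito_total * w / sum(w)
  mu <- .type_mean_matrix(config, uni, base_means, mito_means)

  types <- config$cell_types
  cell_type <- rep(types, times = config$n_cells_per_type[types])
  n_cells <- length(cell_type)
  libsize <- stats::rlnorm(n_cells, meanlog = 0, sdlog = config$libsize_sdlog)
  low_q <- stats::runif(n_cells) < config$low_quality_fraction

  mean_mat <- mu[, cell_type, drop = FALSE] *
    rep(libsize, each = nrow(mu))
  mito_rows <- seq.int(nrow(mu) - config$n_mito_genes + 1L, nrow(mu))
  mean_mat[mito_rows, low_q] <- mean_mat[mito_rows, low_q] *
    config$low_quality_mito_mult
  counts <- matrix(stats::rnbinom(length(mean_mat), mu = mean_mat,
                                  size = config$nb_dispersion),
                   nrow = nrow(mu))
  barcodes <- sprintf("cell_%04d", seq_len(n_cells))
  cm <- count_matrix(counts, gene_ids = rownames(mu), unit_ids = barcodes,
                     unit_kind = "cell")

  gene_meta <- data.frame(gene = uni$genes,
                          chromosome = factor(uni$chrom_of,
                                              levels = default_chromosomes()),
                          start = uni$start, stringsAsFactors = FALSE)
  cnv_truth <- do.call(rbind, lapply(config$cnv_events, function(ev) {
    data.frame(chromosome = ev$chromosome, fold_change = ev$fold_change,
               type = intersect(ev$affected_types, types),
               stringsAsFactors = FALSE)
  }))
  sigs <- lapply(tumor_states_of(config), function(t)
    uni$genes[which(uni$marker_of == t)])
  names(sigs) <- tumor_states_of(config)

  truth <- list(cell_type = stats::setNames(cell_type, barcodes),
                low_quality = stats::setNames(low_q, barcodes),
                marker_of = stats::setNames(uni$marker_of, uni$genes),
                cnv = cnv_truth, gene_meta = gene_meta,
                signatures = sigs, type_means = mu,
                mito_genes = uni$mito, config = config)
  list(counts = cm, truth = truth)
}

.default_territory_map <- function(config) {
  states <- tumor_states_of(config)
  if (length(states) == 0) stop("no tumor states among cell_types")
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  tm <- matrix(states[1], nr, nc)
  half_r <- ceiling(nr / 2); half_c <- ceiling(nc / 2)
  pick <- function(i) states[((i - 1) %% length(states)) + 1]
  tm[seq_len(half_r), seq_len(half_c)] <- pick(1)
  tm[seq_len(half_r), (half_c + 1):nc] <- pick(2)
  tm[(half_r + 1):nr, seq_len(half_c)] <- pick(3)
  tm[(half_r + 1):nr, (half_c + 1):nc] <- pick(4)
  tm
}

.quadrant_center <- function(config, quadrant) {
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  half_r <- ceiling(nr / 2); half_c <- ceiling(nc / 2)
  centers <- list(c(half_r / 2, half_c / 2),
                  c(half_r / 2, half_c + (nc - half_c) / 2),
                  c(half_r + (nr - half_r) / 2, half_c / 2),
                  c(half_r + (nr - half_r) / 2, half_c + (nc - half_c) / 2))
  round(centers[[quadrant]])
}

#' Simulate the spatial dataset over the planted territories
#'
#' Each in-tissue spot pools `cells_per_spot` cells whose types follow the
#' spot's territory plus distance-decayed niche terms: macrophages are
#' enriched toward the necrotic focus and endothelial cells at vessel loci.
#' Spot counts are sums of per-cell negative-binomial draws from the same
#' genes x types mean matrix as the reference; the VEGFA mean is multiplied
#' by `1 + (vegfa_gain_at_necrosis - 1) exp(-d_necrosis / tau_vegfa)`.
#' Realized per-spot type fractions are recorded as the true proportions.
#'
#' @param config The same [sim_config()] used for the reference.
#' @param truth Ground truth returned by [simulate_reference()].
#' @return List with `counts` (spot `count_matrix`), `geometry`
#'   (`spot_geometry`), and `truth`: true proportion matrix (spots x types,
#'   rows on the simplex), gradient-region labels per spot (necrosis ->
#'   palisade -> layer bands -> perivascular), the territory map, necrosis
#'   center/radius, and vessel loci.
#' @export
simulate_spatial <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  tm <- config$territory_map
  if (is.null(tm)) tm <- .default_territory_map(config)
  if (!all(dim(tm) == c(nr, nc)) || anyNA(tm)) {
    stop("territory map must cover the full ", nr, " x ", nc, " grid")
  }
  if (!all(tm %in% tumor_states_of(config))) {
    stop("territory map contains unknown tumor states")
  }
  states <- tumor_states_of(config)
  types <- config$cell_types
  necro <- config$necrosis_center
  if (is.null(necro)) necro <- .quadrant_center(config, 1)
  vessels <- config$vessel_loci
  if (is.null(vessels)) {
    vessels <- rbind(.quadrant_center(config, 3),
                     .quadrant_center(config, 3) + c(2, 3),
                     .quadrant_center(config, 4))
  }
  vessels <- matrix(as.numeric(vessels), ncol = 2)

  grid <- expand.grid(array_row = seq_len(nr), array_col = seq_len(nc))
  n_spots <- nrow(grid)
  d_nec <- sqrt((grid$array_row - necro[1])^2 + (grid$array_col - necro[2])^2)
  d_ves <- apply(vessels, 1, function(v)
    sqrt((grid$array_row - v[1])^2 + (grid$array_col - v[2])^2))
  d_ves <- if (is.matrix(d_ves)) apply(d_ves, 1, min) else d_ves

  # composition weights: dominant territory state, faint other tumor states,
  # glia/neuron background, macrophages decaying from the necrotic focus,
  # endothelium pinned to vessels
  W <- matrix(0, n_spots, length(types), dimnames = list(NULL, types))
  dom <- tm[cbind(grid$array_row, grid$array_col)]
  for (s in states) W[, s] <- ifelse(dom == s, 0.55, 0.03)
  if ("macrophage" %in% types) {
    W[, "macrophage"] <- 0.06 + 0.55 * exp(-d_nec / config$tau_macrophage)
  }
  if ("endothelial" %in% types) {
    W[, "endothelial"] <- 0.02 + 0.8 * exp(-d_ves / config$tau_vessel)
  }
  if ("oligodendrocyte" %in% types) W[, "oligodendrocyte"] <- 0.08
  if ("neuron" %in% types) W[, "neuron"] <- 0.08
  W <- W / rowSums(W)

  k <- config$cells_per_spot
  cell_counts <- t(apply(W, 1, function(w) stats::rmultinom(1, k, w)))
  colnames(cell_counts) <- types
  props <- cell_counts / k

  mu <- truth$type_means
  vegfa_row <- match("VEGFA", rownames(mu))
  vegfa_mult <- 1 + (config$vegfa_gain_at_necrosis - 1) *
    exp(-d_nec / config$tau_vegfa)
  # spot counts are sums of per-cell NB draws; lay all spots' cells out in
  # one genes x (n_spots * k) mean matrix, draw once, then pool by spot
  cell_type_vec <- unlist(lapply(seq_len(n_spots), function(i)
    rep(types, times = cell_counts[i, ])), use.names = FALSE)
  spot_of_cell <- rep(seq_len(n_spots), each = k)
  cell_mu <- mu[, cell_type_vec, drop = FALSE]
  cell_mu[vegfa_row, ] <- cell_mu[vegfa_row, ] * vegfa_mult[spot_of_cell]
  cell_draws <- matrix(stats::rnbinom(length(cell_mu), mu = cell_mu,
                                      size = config$nb_dispersion),
                       nrow = nrow(cell_mu))
  counts <- t(rowsum(t(cell_draws), group = spot_of_cell))
  barcodes <- sprintf("spot_%04d", seq_len(n_spots))
  cm <- count_matrix(counts, gene_ids = rownames(mu), unit_ids = barcodes,
                     unit_kind = "spot")
  geom <- data.frame(barcode = barcodes, in_tissue = TRUE,
                     array_row = grid$array_row, array_col = grid$array_col,
                     y = grid$array_row * 100, x = grid$array_col * 100,
                     stringsAsFactors = FALSE)
  class(geom) <- c("spot_geometry", "data.frame")

  region <- .gradient_regions(d_nec, d_ves, config)
  rownames(props) <- barcodes
  truth_sp <- list(proportions = props,
                   region = stats::setNames(region, barcodes),
                   territory = stats::setNames(dom, barcodes),
                   necrosis_center = necro,
                   necrosis_radius = config$necrosis_radius,
                   vessel_loci = vessels,
                   d_necrosis = stats::setNames(d_nec, barcodes),
                   d_vessel = stats::setNames(d_ves, barcodes))
  list(counts = cm, geometry = geom, truth = truth_sp)
}

#' Gradient-region vocabulary, ordered from the necrotic focus outward
#' @return Character vector of region labels in gradient order.
#' @export
gradient_region_levels <- function() {
  c("necrosis", "palisade", "layer2", "layer3", "layer4", "layer5", "layer6",
    "perivascular")
}

# concentric distance bands around the necrosis center; spots hugging a
# vessel (and not already necrotic/palisading) become perivascular
.gradient_regions <- function(d_nec, d_ves, config) {
  r <- config$necrosis_radius
  band <- cut(d_nec, breaks = c(-Inf, r, r + 1.5, r + 3.5, r + 5.5, r + 7.5,
                                r + 9.5, Inf),
              labels = c("necrosis", "palisade", "layer2", "layer3", "layer4",
                         "layer5", "layer6"))
  region <- as.character(band)
  peri <- d_ves <= config$tau_vessel & !(region %in% c("necrosis", "palisade"))
  region[peri] <- "perivascular"
  region
}
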