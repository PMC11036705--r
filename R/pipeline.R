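# Configuration-driven orchestration of the full synthetic-data flow:
# simulate -> qc -> score -> cnv -> deconvolve -> niches -> coloc -> deg ->
# gradient, each step writing CSV artifacts plus a reproducibility manifest.

PIPELINE_STEPS <- c("simulate", "qc", "score", "cnv", "deconvolve",
                    "niches", "coloc", "deg", "gradient")

#' Pipeline parameter defaults
#'
#' Every study-printed constant surfaces here under a named key: the
#' 500-gene / 5% mitochondrial cell filter, the 5% spot filter, the VEGFA >
#' 3 niche rule, the 25-cell reference minimum, alpha 0.05, top 10 gradient
#' genes and top 100 enrichment genes.
#'
#' @return Named list of defaults; override via the `params` argument of
#'   [run_pipeline()].
#' @export
pipeline_defaults <- function() {
  list(min_genes = 500, max_mito_frac = 0.05, mito_prefix = "MT-",
       scale_factor = 1e4, pearson_theta = 100,
       vegfa_gene = "VEGFA", vegfa_threshold = 3,
       min_cells = 25, cnv_window = 101, cnv_clip = 3,
       gain_thresh = 0.1, loss_thresh = -0.1,
       alpha = 0.05, n_top_gradient = 10, n_top_enrichment = 100,
       generic_tumor_bands = c("layer4", "layer5", "layer6"))
}

#' Run the full pipeline on a synthetic sample
#'
#' Executes the enabled steps in order on one simulated sample, writing each
#' step's tables under `outdir` and a `manifest.json` recording the
#' configuration, its hash, the seed, and per-step timing/record counts.
#' Reruns with the same config and seed are bit-identical for all
#' deterministic steps.
#'
#' @param sim A [sim_config()] (its seed drives all randomness).
#' @param params Named list overriding [pipeline_defaults()].
#' @param outdir Output directory (created).
#' @param steps Which steps to run (prerequisites are computed in-memory
#'   regardless; toggling only controls what is written/analyzed).
#' @return Invisibly, a list with every step's in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(sim = sim_config(), params = list(),
                         outdir = tempfile("gbmniche_run_"),
                         steps = PIPELINE_STEPS) {
  bad <- setdiff(steps, PIPELINE_STEPS)
  if (length(bad)) stop("unknown step(s): ", paste(bad, collapse = ", "))
  p <- utils::modifyList(pipeline_defaults(), params)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = sim$seed, steps = list(),
                   config = sim[setdiff(names(sim), "territory_map")])
  cfg_json <- jsonlite::toJSON(manifest$config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest$config_hash <- unname(tools::md5sum(tf)); unlink(tf)
  res <- list()
  tick <- function(step, n_records) {
    manifest$steps[[step]] <<- list(completed = TRUE, records = n_records)
  }

  # simulate ----
  ref <- simulate_reference(sim)
  sp <- simulate_spatial(sim, ref$truth)
  res$reference <- ref; res$spatial <- sp
  if ("simulate" %in% steps) {
    utils::write.csv(data.frame(barcode = names(ref$truth$cell_type),
                                cell_type = ref$truth$cell_type,
                                low_quality = ref$truth$low_quality,
                                row.names = NULL),
                     file.path(outdir, "truth_cells.csv"), row.names = FALSE)
    utils::write.csv(data.frame(barcode = rownames(sp$truth$proportions),
                                region = sp$truth$region,
                                sp$truth$proportions, check.names = FALSE,
                                row.names = NULL),
                     file.path(outdir, "truth_spots.csv"), row.names = FALSE)
    write_gene_meta(ref$truth$gene_meta, file.path(outdir, "gene_meta.csv"))
    write_spot_positions(sp$geometry, file.path(outdir, "spot_positions.csv"))
    tick("simulate", ncol(ref$counts$values) + ncol(sp$counts$values))
  }

  # qc ----
  cells <- filter_cells(ref$counts, min_genes = p$min_genes,
                        max_mito_frac = p$max_mito_frac,
                        mito_prefix = p$mito_prefix)
  spots <- filter_spots(sp$counts, max_mito_frac = p$max_mito_frac,
                        mito_prefix = p$mito_prefix)
  ref_norm <- lognormalize(cells, scale_factor = p$scale_factor)
  spot_norm <- pearson_residual_normalize(spots, theta = p$pearson_theta)
  res$cells <- cells; res$spots <- spots
  res$ref_norm <- ref_norm; res$spot_norm <- spot_norm
  if ("qc" %in% steps) {
    utils::write.csv(attr(cells, "removal_log"),
                     file.path(outdir, "qc_removed_cells.csv"),
                     row.names = FALSE)
    utils::write.csv(attr(spots, "removal_log"),
                     file.path(outdir, "qc_removed_spots.csv"),
                     row.names = FALSE)
    tick("qc", nrow(attr(cells, "removal_log")) +
           nrow(attr(spots, "removal_log")))
  }

  labels <- ref$truth$cell_type[unit_ids(cells)]

  # score ----
  if ("score" %in% steps) {
    sc <- suppressMessages(lineage_score(ref_norm, ref$truth$signatures))
    sc <- assign_cluster_states(sc, labels)
    res$scores <- sc
    utils::write.csv(data.frame(barcode = rownames(sc$scores), sc$scores,
                                check.names = FALSE, row.names = NULL),
                     file.path(outdir, "lineage_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(cbind(data.frame(cluster =
                                        rownames(sc$cluster_mean_scores)),
                           as.data.frame(sc$cluster_mean_scores),
                           state = sc$assignments$state),
                     file.path(outdir, "cluster_states.csv"),
                     row.names = FALSE)
    tick("score", nrow(sc$scores))
  }

  # cnv ----
  if ("cnv" %in% steps) {
    normal <- unit_ids(cells)[!(labels %in% TUMOR_STATES)]
    prof <- suppressMessages(infer_cnv_profile(
      ref_norm, ref$truth$gene_meta, reference_cells = normal,
      window = p$cnv_window, clip = p$cnv_clip))
    calls <- call_chromosome_events(prof, labels,
                                    gain_thresh = p$gain_thresh,
                                    loss_thresh = p$loss_thresh)
    res$cnv_profile <- prof; res$cnv_calls <- calls
    utils::write.csv(calls, file.path(outdir, "cnv_calls.csv"),
                     row.names = FALSE)
    tick("cnv", nrow(calls))
  }

  # deconvolve ----
  profs <- suppressMessages(build_signatures(cells, labels,
                                             min_cells = p$min_cells))
  props <- suppressMessages(deconvolve(spots, profs))
  res$profiles <- profs; res$proportions <- props
  if ("deconvolve" %in% steps) {
    utils::write.csv(data.frame(barcode = rownames(props$proportions),
                                props$proportions, check.names = FALSE,
                                row.names = NULL),
                     file.path(outdir, "proportions.csv"), row.names = FALSE)
    utils::write.csv(props$convergence,
                     file.path(outdir, "deconvolution_convergence.csv"),
                     row.names = FALSE)
    tick("deconvolve", nrow(props$proportions))
  }

  # niches ----
  region <- sp$truth$region[unit_ids(spots)]
  necrosis <- select_necrosis_niche(spot_norm, gene = p$vegfa_gene,
                                    threshold = p$vegfa_threshold)
  perivascular <- names(region)[region == "perivascular"]
  generic <- names(region)[region %in% p$generic_tumor_bands]
  niches <- resolve_niche_overlaps(list(
    palisading_necrosis = necrosis, perivascular = perivascular,
    generic_tumor = generic))
  res$niches <- niches
  if ("niches" %in% steps) {
    write_region_annotation(niches, file.path(outdir, "niches.csv"))
    tick("niches", nrow(niches))
  }

  # coloc ----
  if ("coloc" %in% steps) {
    coloc <- suppressMessages(
      pairwise_proportion_correlation(props, alpha = p$alpha))
    res$colocalization <- coloc
    utils::write.csv(coloc, file.path(outdir, "colocalization.csv"),
                     row.names = FALSE)
    tick("coloc", nrow(coloc))
  }

  # deg ----
  if ("deg" %in% steps) {
    nl <- niches[niches$label %in% c("palisading_necrosis", "generic_tumor"), ]
    des_un <- build_design(nl, niche_label = "palisading_necrosis")
    des_ad <- suppressMessages(
      build_design(nl, props = props, niche_label = "palisading_necrosis"))
    deg_un <- suppressMessages(fit_deg(spot_norm, des_un, alpha = p$alpha))
    deg_ad <- suppressMessages(fit_deg(spot_norm, des_ad, alpha = p$alpha))
    res$deg_unadjusted <- deg_un; res$deg_adjusted <- deg_ad
    utils::write.csv(deg_un, file.path(outdir, "deg_necrosis_unadjusted.csv"),
                     row.names = FALSE)
    utils::write.csv(deg_ad, file.path(outdir, "deg_necrosis_adjusted.csv"),
                     row.names = FALSE)
    tops <- select_top_genes(deg_ad, n = p$n_top_enrichment)
    writeLines(tops$up, file.path(outdir, "enrichment_genes_up.txt"))
    writeLines(tops$down, file.path(outdir, "enrichment_genes_down.txt"))
    tick("deg", nrow(deg_ad))
  }

  # gradient ----
  if ("gradient" %in% steps) {
    reg_df <- data.frame(barcode = names(region), label = unname(region),
                         stringsAsFactors = FALSE)
    keep <- names(table(reg_df$label))[table(reg_df$label) >= 2]
    reg_df <- reg_df[reg_df$label %in% keep, ]
    grad <- suppressMessages(gradient_analysis(
      spot_norm, reg_df, props = props, n_top = p$n_top_gradient,
      alpha = p$alpha))
    res$gradient <- grad
    utils::write.csv(data.frame(region = rep(names(grad$top_genes),
                                             lengths(grad$top_genes)),
                                gene = unlist(grad$top_genes,
                                              use.names = FALSE)),
                     file.path(outdir, "gradient_top_genes.csv"),
                     row.names = FALSE)
    if (!is.null(grad$celltype_heatmap)) {
      utils::write.csv(data.frame(type = rownames(grad$celltype_heatmap),
                                  grad$celltype_heatmap, check.names = FALSE,
                                  row.names = NULL),
                       file.path(outdir, "celltype_gradient.csv"),
                       row.names = FALSE)
    }
    tick("gradient", length(unlist(grad$top_genes)))
  }

  manifest$n_steps_completed <- length(manifest$steps)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  res$outdir <- outdir
  invisible(res)
}
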