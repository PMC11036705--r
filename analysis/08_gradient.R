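#!/usr/bin/env Rscript
# Gradient-of-regions analysis: one-vs-rest DE across the ordered bands
# from the necrotic focus out to the vessels, top-10 genes per region
# (ribosomal excluded, shown once), and z-scaled heatmap matrices for
# genes and cell types.

suppressPackageStartupMessages(library(gbmniche))

outdir <- "results/sample1"
sp <- read_counts(file.path(outdir, "visium"), unit_kind = "spot")
kept_spots <- read.csv(file.path(outdir, "kept_spots.csv"))$barcode
spots <- subset_counts(sp, units = kept_spots)
norm <- pearson_residual_normalize(spots)
truth <- read.csv(file.path(outdir, "truth_spots.csv"), check.names = FALSE)
props <- read.csv(file.path(outdir, "proportions.csv"), check.names = FALSE)
W <- as.matrix(props[, -1]); rownames(W) <- props$barcode

reg <- data.frame(barcode = truth$barcode, label = truth$region,
                  stringsAsFactors = FALSE)
reg <- reg[reg$barcode %in% kept_spots, ]
reg <- reg[reg$label %in% names(which(table(reg$label) >= 2)), ]

grad <- gradient_analysis(norm, reg, props = W)
write.csv(data.frame(region = rep(names(grad$top_genes),
                                  lengths(grad$top_genes)),
                     gene = unlist(grad$top_genes, use.names = FALSE)),
          file.path(outdir, "gradient_top_genes.csv"), row.names = FALSE)
write.csv(data.frame(type = rownames(grad$celltype_heatmap),
                     grad$celltype_heatmap, check.names = FALSE,
                     row.names = NULL),
          file.path(outdir, "celltype_gradient.csv"), row.names = FALSE)
if (!is.null(grad$gene_heatmap)) {
  write.csv(data.frame(gene = rownames(grad$gene_heatmap),
                       grad$gene_heatmap, check.names = FALSE,
                       row.names = NULL),
            file.path(outdir, "gene_gradient_heatmap.csv"),
            row.names = FALSE)
}

cat("regions in gradient order:", paste(grad$region_order, collapse = " -> "),
    "\n")
cat("top genes per region:\n")
print(lengths(grad$top_genes))
ct <- grad$celltype_heatmap
cat(sprintf("macrophage profile peaks at: %s\n",
            colnames(ct)[which.max(ct["macrophage", ])]))
cat(sprintf("OPC-like profile peaks at:   %s\n",
            colnames(ct)[which.max(ct["OPC-like", ])]))
cat(sprintf("VEGFA among necrosis top genes: %s\n",
            "VEGFA" %in% grad$top_genes$necrosis))
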