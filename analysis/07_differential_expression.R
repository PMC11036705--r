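#!/usr/bin/env Rscript
# DE between the palisading-necrosis niche and the generic tumor region,
# with and without adjustment for deconvolved cell-type proportions (tumor
# states collapsed into one design column), plus the top-100 gene lists for
# external enrichment tools.

suppressPackageStartupMessages(library(gbmniche))

outdir <- "results/sample1"
sp <- read_counts(file.path(outdir, "visium"), unit_kind = "spot")
kept_spots <- read.csv(file.path(outdir, "kept_spots.csv"))$barcode
spots <- subset_counts(sp, units = kept_spots)
norm <- pearson_residual_normalize(spots)
niches <- read_region_annotation(file.path(outdir, "niches.csv"))
props <- read.csv(file.path(outdir, "proportions.csv"), check.names = FALSE)
W <- as.matrix(props[, -1]); rownames(W) <- props$barcode

nl <- niches[niches$label %in% c("palisading_necrosis", "generic_tumor"), ]
deg_un <- fit_deg(norm, build_design(nl, niche_label = "palisading_necrosis"))
deg_ad <- fit_deg(norm, build_design(nl, props = W,
                                     niche_label = "palisading_necrosis"))
write.csv(deg_un, file.path(outdir, "deg_necrosis_unadjusted.csv"),
          row.names = FALSE)
write.csv(deg_ad, file.path(outdir, "deg_necrosis_adjusted.csv"),
          row.names = FALSE)

cat(sprintf("significant genes: %d unadjusted, %d adjusted\n",
            sum(deg_un$significant), sum(deg_ad$significant)))
cat(sprintf("mean |logFC|: %.3f unadjusted, %.3f adjusted\n",
            mean(abs(deg_un$logFC)), mean(abs(deg_ad$logFC))))
cat("top adjusted niche genes:\n")
print(head(deg_ad[order(-deg_ad$logFC), c("gene", "logFC", "adj_p")], 5))

tops <- select_top_genes(deg_ad, n = 100)
writeLines(tops$up, file.path(outdir, "enrichment_genes_up.txt"))
writeLines(tops$down, file.path(outdir, "enrichment_genes_down.txt"))
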