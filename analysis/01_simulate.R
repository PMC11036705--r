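#!/usr/bin/env Rscript
# Generate one synthetic glioblastoma sample: a single-nucleus reference
# with planted tumor-state marker programs and chr7-gain/chr10-loss
# expression folds, and a paired spatial section with segregated tumor
# territories, a necrotic VEGFA-high focus, and vessel loci.
#
# Writes the raw inputs every later script consumes under results/sample1/.

suppressPackageStartupMessages(library(gbmniche))

outdir <- "results/sample1"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 1L)
ref <- simulate_reference(cfg)
sp <- simulate_spatial(cfg, ref$truth)

write_counts(ref$counts, file.path(outdir, "snrna"), format = "mtx")
write_counts(sp$counts, file.path(outdir, "visium"), format = "mtx")
write_spot_positions(sp$geometry, file.path(outdir, "spot_positions.csv"))
write_gene_meta(ref$truth$gene_meta, file.path(outdir, "gene_meta.csv"))
write_signatures(ref$truth$signatures, file.path(outdir, "signatures.csv"))
write.csv(data.frame(barcode = names(ref$truth$cell_type),
                     cell_type = ref$truth$cell_type, row.names = NULL),
          file.path(outdir, "cell_labels.csv"), row.names = FALSE)
write.csv(data.frame(barcode = rownames(sp$truth$proportions),
                     region = sp$truth$region,
                     sp$truth$proportions, check.names = FALSE,
                     row.names = NULL),
          file.path(outdir, "truth_spots.csv"), row.names = FALSE)

cat(sprintf("reference: %d genes x %d cells\n", nrow(ref$counts$values),
            ncol(ref$counts$values)))
cat(sprintf("spatial:   %d genes x %d spots over a %dx%d grid\n",
            nrow(sp$counts$values), ncol(sp$counts$values),
            cfg$grid_shape[1], cfg$grid_shape[2]))
cat("region sizes:\n")
print(table(sp$truth$region))
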