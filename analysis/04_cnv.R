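#!/usr/bin/env Rscript
# Expression-based CNV profile of the reference cells against the non-tumor
# populations, with chromosome-level gain/loss calls. The planted truth is a
# chromosome 7 gain (x1.5) and chromosome 10 loss (x0.5) in tumor states.

suppressPackageStartupMessages(library(gbmniche))

outdir <- "results/sample1"
ref <- read_counts(file.path(outdir, "snrna"), unit_kind = "cell")
kept <- read.csv(file.path(outdir, "kept_cells.csv"))$barcode
cells <- subset_counts(ref, units = kept)
meta <- read_gene_meta(file.path(outdir, "gene_meta.csv"))
labels <- read.csv(file.path(outdir, "cell_labels.csv"))
labels <- setNames(labels$cell_type, labels$barcode)[kept]
tumor <- c("MES-like", "AC-like", "OPC-like", "NPC-like")

prof <- infer_cnv_profile(lognormalize(cells), meta,
                          reference_cells = kept[!(labels %in% tumor)])
calls <- call_chromosome_events(prof, labels)
write.csv(calls, file.path(outdir, "cnv_calls.csv"), row.names = FALSE)

cat("tumor-state chromosome calls (non-neutral):\n")
print(calls[calls$call != "neutral" & calls$group %in% tumor, ])
cat("non-tumor groups non-neutral calls:",
    sum(calls$call != "neutral" & !calls$group %in% tumor), "\n")
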