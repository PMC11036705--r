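#!/usr/bin/env Rscript
# Score every reference cell for the four tumor cell states (lineage score:
# mean signature expression over mean all-gene expression) and assign one
# state per cluster by the highest mean score.

suppressPackageStartupMessages(library(gbmniche))

outdir <- "results/sample1"
ref <- read_counts(file.path(outdir, "snrna"), unit_kind = "cell")
kept <- read.csv(file.path(outdir, "kept_cells.csv"))$barcode
cells <- subset_counts(ref, units = kept)
sigs <- read_signatures(file.path(outdir, "signatures.csv"), counts = cells)
labels <- read.csv(file.path(outdir, "cell_labels.csv"))
labels <- setNames(labels$cell_type, labels$barcode)[kept]

sc <- lineage_score(lognormalize(cells), sigs)
sc <- assign_cluster_states(sc, labels)

write.csv(data.frame(barcode = rownames(sc$scores), sc$scores,
                     check.names = FALSE, row.names = NULL),
          file.path(outdir, "lineage_scores.csv"), row.names = FALSE)
write.csv(cbind(data.frame(cluster = rownames(sc$cluster_mean_scores)),
                as.data.frame(sc$cluster_mean_scores),
                state = sc$assignments$state, tie = sc$assignments$tie),
          file.path(outdir, "cluster_states.csv"), row.names = FALSE)

cat("per-cluster assigned states (clusters here are the annotated types):\n")
print(sc$assignments)
tum <- sc$assignments[sc$assignments$cluster %in%
                        c("MES-like", "AC-like", "OPC-like", "NPC-like"), ]
cat(sprintf("tumor clusters recovering their generating state: %d/%d\n",
            sum(tum$state == tum$cluster), nrow(tum)))
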