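#!/usr/bin/env Rscript
# Quality control at the study thresholds (cells: >= 500 expressed genes and
# <= 5% mitochondrial reads; spots: <= 5% mitochondrial reads), then
# log-normalize the reference and Pearson-residual-normalize the spatial
# matrix.

suppressPackageStartupMessages(library(gbmniche))

outdir <- "results/sample1"
ref <- read_counts(file.path(outdir, "snrna"), unit_kind = "cell")
sp <- read_counts(file.path(outdir, "visium"), unit_kind = "spot")

cells <- filter_cells(ref)
spots <- filter_spots(sp)
write.csv(attr(cells, "removal_log"), file.path(outdir, "qc_removed_cells.csv"),
          row.names = FALSE)
write.csv(attr(spots, "removal_log"), file.path(outdir, "qc_removed_spots.csv"),
          row.names = FALSE)

cat(sprintf("cells: %d kept, %d removed\n", ncol(cells$values),
            nrow(attr(cells, "removal_log"))))
print(table(attr(cells, "removal_log")$reason))
cat(sprintf("spots: %d kept, %d removed\n", ncol(spots$values),
            nrow(attr(spots, "removal_log"))))

# normalized matrices are cheap to recompute; later scripts rebuild them
# from the filtered barcode lists written here
write.csv(data.frame(barcode = colnames(cells$values)),
          file.path(outdir, "kept_cells.csv"), row.names = FALSE)
write.csv(data.frame(barcode = colnames(spots$values)),
          file.path(outdir, "kept_spots.csv"), row.names = FALSE)
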