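#!/usr/bin/env Rscript
# Build reference signature profiles (types with < 25 cells dropped) and
# estimate per-spot cell-type proportions by Poisson mixture EM; compare
# against the planted spot compositions.

suppressPackageStartupMessages(library(gbmniche))

outdir <- "results/sample1"
ref <- read_counts(file.path(outdir, "snrna"), unit_kind = "cell")
sp <- read_counts(file.path(outdir, "visium"), unit_kind = "spot")
kept_cells <- read.csv(file.path(outdir, "kept_cells.csv"))$barcode
kept_spots <- read.csv(file.path(outdir, "kept_spots.csv"))$barcode
cells <- subset_counts(ref, units = kept_cells)
spots <- subset_counts(sp, units = kept_spots)
labels <- read.csv(file.path(outdir, "cell_labels.csv"))
labels <- setNames(labels$cell_type, labels$barcode)[kept_cells]

profs <- build_signatures(cells, labels)
fit <- deconvolve(spots, profs)
write.csv(data.frame(barcode = rownames(fit$proportions), fit$proportions,
                     check.names = FALSE, row.names = NULL),
          file.path(outdir, "proportions.csv"), row.names = FALSE)
write.csv(fit$convergence, file.path(outdir, "deconvolution_convergence.csv"),
          row.names = FALSE)

truth <- read.csv(file.path(outdir, "truth_spots.csv"), check.names = FALSE)
tr <- as.matrix(truth[match(rownames(fit$proportions), truth$barcode),
                      colnames(fit$proportions)])
cat("per-type correlation between true and estimated proportions:\n")
print(round(diag(cor(tr, fit$proportions)), 3))
cat(sprintf("mean absolute proportion error: %.4f\n",
            mean(abs(tr - fit$proportions))))
cat(sprintf("median EM iterations: %d\n",
            median(fit$convergence$iterations)))
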