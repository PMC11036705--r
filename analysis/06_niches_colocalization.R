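#!/usr/bin/env Rscript
# Select the palisading-necrosis niche (normalized VEGFA > 3), take the
# perivascular and generic-tumor regions from the annotation, remove
# overlapping spots from all niches, and test pairwise colocalization /
# segregation of the deconvolved cell types.

suppressPackageStartupMessages(library(gbmniche))

outdir <- "results/sample1"
sp <- read_counts(file.path(outdir, "visium"), unit_kind = "spot")
kept_spots <- read.csv(file.path(outdir, "kept_spots.csv"))$barcode
spots <- subset_counts(sp, units = kept_spots)
truth <- read.csv(file.path(outdir, "truth_spots.csv"), check.names = FALSE)
region <- setNames(truth$region, truth$barcode)[kept_spots]

norm <- pearson_residual_normalize(spots)
necrosis <- select_necrosis_niche(norm)
niches <- resolve_niche_overlaps(list(
  palisading_necrosis = necrosis,
  perivascular = names(region)[region == "perivascular"],
  generic_tumor = names(region)[region %in% c("layer4", "layer5", "layer6")]))
write_region_annotation(niches, file.path(outdir, "niches.csv"))
cat("niche sizes after overlap removal:\n")
print(table(niches$label))
cat(sprintf("overlapping spots removed: %d\n",
            length(attr(niches, "removed"))))

props <- read.csv(file.path(outdir, "proportions.csv"), check.names = FALSE)
W <- as.matrix(props[, -1]); rownames(W) <- props$barcode
tab <- pairwise_proportion_correlation(W)
write.csv(tab, file.path(outdir, "colocalization.csv"), row.names = FALSE)
cat("\nsignificant pairs:\n")
print(tab[tab$verdict != "ns", c("type_a", "type_b", "pearson_r", "adj_p",
                                 "verdict")])
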