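---
title: "Models and methods behind gbmniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gbmniche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gbmniche analyzes a pair of matrices from one glioblastoma tissue block —
a single-nucleus RNA-seq reference (genes x cells) and a spatial
transcriptomics slide (genes x spots) — to ask where tumor cell states
and non-tumor cell types sit relative to the tissue's hallmark niches.
This vignette explains each model, its assumptions, the tunable
parameters, and the design choices made where the procedure was genuinely
open. The companion `analysis/` scripts run every step on a synthetic
sample; nothing stated here goes beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## Quality control and normalization

Cells are kept when they express at least 500 genes and carry at most 5%
mitochondrial reads; spots are kept at up to 5% mitochondrial reads. The
prose conventions ("fewer than", "over") are encoded strictly: a cell at
exactly 500 expressed genes and exactly 5% mitochondrial fraction is
retained, a spot at 5.0% is retained and one at 5.1% removed.
Mitochondrial genes are recognized by a configurable symbol prefix
(default `MT-`). Ambient-RNA removal and doublet detection are not
reimplemented; the pipeline expects pre-cleaned counts.

Two normalizations are provided. `lognormalize()` is the standard
library-size transform `ln(1 + 10^4 x / total)` and feeds the lineage
scores and CNV profile. `pearson_residual_normalize()` is the
variance-stabilizing transform used for the spatial matrix: residuals
`(x - mu)/sqrt(mu + mu^2/theta)` about the rank-1 null
`mu = (row total)(column total)/(grand total)`, clipped to
`±sqrt(n_units)`, with a fixed negative-binomial dispersion
`theta = 100`. This is a deliberate closed-form stand-in for a
regularized-NB regression fit: it keeps the variance-stabilization
property in a fully specified, dependency-free form. Because the niche
rule (below) thresholds normalized expression, absolute selections depend
on which normalization is handed in; Pearson residuals are the documented
default for spatial data.

## Lineage scores and cluster states

The lineage score of cell $c$ for state $s$ is

$$\mathrm{score}(c,s) = \frac{\mathrm{mean}_{g \in \mathrm{sig}(s)}\, x_{gc}}
{\mathrm{mean}_{g \in \mathrm{all\ genes}}\, x_{gc}},$$

a unitless ratio that is invariant to rescaling a cell's expression
vector. The denominator averages over **all** genes of the post-QC
matrix; a flag (`detected_only`) restricts it to detected genes for
sensitivity analysis, but the all-genes form is the default. Each cluster
receives the state with the highest mean score; exact ties go to the
earlier state in the declared signature order and are flagged. Clustering
itself is an input — a k-means-on-PCs baseline (`baseline_clusters()`) is
provided only as plumbing. Transitional/hybrid states are deliberately
not modeled.

## Expression-based CNV

`infer_cnv_profile()` is an intentionally simplified, inferCNV-style
caller aimed only at chromosome-arm-scale events: per-gene centering on
the mean of declared copy-number-normal reference cells, clipping at ±3,
a centered moving average of 101 genes within each chromosome, and
per-cell median centering. Three numerical choices matter:

* **Windows never cross chromosome boundaries** and shrink symmetrically
  at the edges.
* **The smoother is mean-preserving per (cell, chromosome)**: after
  window averaging, each chromosome's mean of the centered values is
  restored. A plain edge-shrunken moving average slightly redistributes
  mass near chromosome ends; restoring the mean makes the
  chromosome-level average — exactly the quantity the caller thresholds —
  immune to edge attenuation, and gives the conservation property the
  tests assert to 1e-9.
* **Calls are thresholded means**: a (group, chromosome) mean shift of at
  least +0.1 is a gain, at most −0.1 a loss. The thresholds, window and
  clip are free parameters of this package, not literature claims; there
  is no HMM, no subclustering, no Bayesian denoising.

Genes lacking genomic metadata are dropped with a logged count;
chromosomes with fewer than 3 genes are excluded with a warning.

## Spot deconvolution

Each spot's counts are modeled as a Poisson mixture of reference
profiles: $y_g \sim \mathrm{Pois}(N \sum_t w_t \mu_{tg})$ with weights on
the simplex. Profiles are per-type summed counts plus a pseudocount
(1e-9) normalized to rates; types with fewer than 25 reference cells are
dropped (retain-at-exactly-25). The multiplicative EM update

$$w_t \leftarrow w_t \cdot \frac{\sum_g y_g \mu_{tg} / \lambda_g}{\sum_g y_g},
\qquad \lambda_g = \sum_u w_u \mu_{ug},$$

is the classic mixture/NMF step: it preserves the simplex and never
decreases the log-likelihood, which the implementation asserts on every
iteration. Iteration starts uniform and stops at a relative
log-likelihood change below 1e-8 or 500 iterations. Collinear profiles
leave flat likelihood directions; the uniform start makes the returned
split deterministic (identical profiles receive equal weights, and only
their sum is identified). Platform effects, per-type dispersion and
doublet modes of richer deconvolution methods are intentionally out of
scope — downstream analyses consume only the proportion estimates.

## Niches and colocalization

The palisading-necrosis niche is the set of spots with normalized VEGFA
expression strictly greater than 3. The perivascular and generic-tumor
regions are annotation inputs (in the original study, histology-reviewed
selections). Spots claimed by two or more niches are **removed from all
of them**, not reassigned.

Colocalization is tested per unordered type pair by the Pearson
correlation of per-spot proportions, with the two-sided p-value from the
t-distribution on $n-2$ df and Benjamini–Hochberg adjustment jointly
across all pairs of one sample's table (the BH family is a package
choice; it is configurable by filtering the table before adjustment).
Verdicts: `segregate` if $r<0$ and adjusted $p<0.05$, `colocalize` if
$r>0$ and adjusted $p<0.05$. Because proportions sum to one, the simplex
itself induces negative correlation a priori; the table carries this
caveat in an attribute, and the test is reported as defined rather than
replaced by a compositional-aware alternative. Zero-variance proportion
columns yield NA rows that are excluded from the BH family.

## Differential expression

Both niche DE and gradient DE fit, per gene, an ordinary least-squares
linear model on normalized expression with an intercept and a 0/1 region
indicator. With composition adjustment, the deconvolved proportions enter
the design with all tumor states collapsed into a single "tumor" column
and one non-tumor column dropped (proportions sum to one; the dropped
type is logged — by default the last non-tumor column). Degenerate
columns are pruned with a log; remaining rank deficiency is a hard error
naming the collinear columns.

Variance moderation follows the empirical-Bayes moderated-t construction:
residual variances $s^2_g$ on $d$ df inform a scaled-inverse-chi-square
prior $(d_0, s_0^2)$ estimated by method of moments on $\log s^2$
(matching mean and variance of $\log s^2 - \psi(d/2) + \log(d/2)$ via the
trigamma function, with a Newton inversion of the trigamma). The
moderated variance $(d_0 s_0^2 + d s^2_g)/(d_0+d)$ gives a t-statistic on
$d_0+d$ df. If the prior-df estimate is non-finite the fit falls back to
ordinary unmoderated t-statistics, and `moderate = FALSE` forces that
mode (it reproduces the pooled-variance two-sample t exactly on a
two-group design, which the tests check to 1e-9). Zero-variance genes get
p = 1 with a log. Significance is adjusted p strictly below 0.05.

Cross-sample reproducibility is summarized by the Pearson correlation of
logFC over shared genes plus a 3x3 significance cross-table. Gene lists
for external enrichment tools take up to 100 genes per direction by
|logFC|, ties broken stably by gene id.

## Gradient analysis

Regions are ordered from the necrotic focus outward
(necrosis, palisade, layer2…layer6, perivascular). Each region is tested
one-vs-rest with the same DE machinery (optionally
composition-adjusted). Top genes per region keep positively enriched
significant genes (adjusted p < 0.05, logFC > 0), exclude
ribosomal-prefixed symbols (`RPL`, `RPS`, `MRPL`, `MRPS`; the prefix set
is configurable since "ribosomal" has no operational definition in
symbols alone), sort by logFC, cap at 10, and deduplicate across regions
keeping the first occurrence in gradient order — a gene enriched in two
regions is shown under the more necrotic one. Heatmap matrices are
z-scaled per row with the n−1 standard deviation; constant rows are
dropped rather than imputed.

## The synthetic-data generator

`simulate_reference()` draws negative-binomial counts (dispersion
`nb_dispersion = 10`, i.e. moderately overdispersed) around
`base_g × markerfold(g,t) × cnvfold(chrom(g),t) × libsize_c`, with
Gamma-distributed per-gene baselines, 20 disjoint marker genes per type
at fold 4 interleaved along the genome (so no chromosome concentrates one
type's program and masquerades as a CNV), a chr7×1.5 / chr10×0.5 fold in
the four tumor states, `MT-` pseudo-genes at a 2% expected fraction, and
a 3% subpopulation with 10-fold inflated mitochondrial load so QC has
work to do.

`simulate_spatial()` lays a 20x20 grid whose quadrants are owned by the
four tumor states (dominant weight 0.55 against a faint background of the
others), with macrophage weight decaying from the necrotic focus
(`0.06 + 0.55 e^{-d/3}`), endothelial weight pinned to vessel loci
(`0.02 + 0.8 e^{-d/1.5}`), and neutral glia/neuron background. Each spot
pools 8 cells drawn multinomially from these weights; spot counts are
sums of per-cell NB draws, and the realized type fractions are the
recorded truth. The VEGFA mean is multiplied by
`1 + (gain − 1) e^{-d/τ}` with gain 8 and τ = 2 — written so the
center-to-far ratio equals the configured gain while distant spots revert
to baseline. Gradient-region truth labels are concentric distance bands
around the necrosis center, with vessel-hugging spots relabeled
perivascular — mirroring the idea of a hand-annotated eight-region
gradient without claiming any real slide's geometry. Since no
quantitative niche composition is published, all of these weights are
free parameters declared in `sim_config()`, chosen once as plausible for
a densely infiltrated tumor section; they are package defaults, not
literature claims.

One seed determines everything: the reference consumes `seed`, the
spatial stage `seed + 1`, each in a documented fixed order, so partial
reruns are reproducible bit for bit.

What the generator does **not** emulate: transcriptome-wide co-expression
structure, ambient RNA, doublets, segmentation artifacts, platform
effects between snRNA-seq and spatial chemistry, and continuous
state-transition gradients. Passing tests therefore demonstrate that the
implementations recover planted structure under a clean generative model
— not that they are robust to every artifact of real tissue.

## Problem sizes and runtime posture

The default sample is 2000 genes (+13 mitochondrial pseudo-genes), 150
cells per type (1200 cells) and a 400-spot grid — small enough that the
full pipeline runs in well under a minute while leaving every statistical
property measurable. Multi-seed recovery checks in the tests use a
further reduced 1200-gene / 60-cells-per-type / 144-spot configuration;
these sizes are the package's own scaling choices, stated here so results
can be reproduced exactly.

## Known limitations

* The CNV module detects arm-scale shifts only; focal events and
  subclonal structure are invisible to it.
* The Poisson deconvolution ignores overdispersion and platform effects;
  its accuracy on real Visium data will be lower than on the generator.
* The colocalization test inherits the compositional negative-correlation
  bias discussed above.
* Linear adjustment for proportions removes composition effects only to
  first order on the normalized scale.
* Niche selection by a single marker gene threshold (VEGFA > 3) is
  sensitive to the normalization handed in.
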