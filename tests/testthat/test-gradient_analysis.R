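grad_fixture <- function(seed = 71, n_genes = 60, spots_per_region = 10,
                         regions = c("necrosis", "palisade", "layer2")) {
  set.seed(seed)
  n <- spots_per_region * length(regions)
  v <- matrix(rnorm(n_genes * n), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n))))
  reg <- data.frame(barcode = colnames(v),
                    label = rep(regions, each = spots_per_region),
                    stringsAsFactors = FALSE)
  list(expr = as_norm(v, "spot"), regions = reg)
}

test_that("with two regions the one-vs-rest tables are mutual mirrors", {
  fx <- grad_fixture(regions = c("necrosis", "layer2"))
  tabs <- suppressMessages(region_one_vs_rest(fx$expr, fx$regions))
  a <- tabs$necrosis; b <- tabs$layer2
  expect_equal(a$logFC, -b$logFC, tolerance = 1e-9)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
})

test_that("a planted region-specific marker tops its region's table", {
  fx <- grad_fixture(seed = 72, regions = c("necrosis", "palisade",
                                            "layer2", "layer3"))
  target <- fx$regions$barcode[fx$regions$label == "layer2"]
  fx$expr$values["g07", target] <- fx$expr$values["g07", target] + 4
  tabs <- suppressMessages(region_one_vs_rest(fx$expr, fx$regions))
  t2 <- tabs$layer2
  expect_equal(t2$gene[which.max(t2$logFC)], "g07")
  expect_true(t2$significant[t2$gene == "g07"])
  tops <- top_genes(tabs)
  expect_equal(tops$layer2[1], "g07")
})

test_that("uniform expression yields a controlled significant fraction", {
  fx <- grad_fixture(seed = 73, n_genes = 500, spots_per_region = 12)
  tabs <- suppressMessages(region_one_vs_rest(fx$expr, fx$regions))
  fracs <- vapply(tabs, function(t) mean(t$adj_p < 0.05), numeric(1))
  expect_true(all(fracs <= 0.05 + 2 * sqrt(0.05 * 0.95 / 500)))
})

test_that("top-gene selection caps at 10, excludes ribosomal, dedupes by order", {
  mk <- function(genes, lfc, p = 1e-4) {
    t <- data.frame(gene = genes, logFC = lfc, t = 1, p_value = p,
                    adj_p = p, significant = TRUE, stringsAsFactors = FALSE)
    class(t) <- c("deg_table", "data.frame")
    t
  }
  g <- sprintf("G%02d", 1:15)
  tabs <- list(
    necrosis = mk(c(g[1:12], "RPL7"), c(seq(12, 1), 99)),
    palisade = mk(c(g[1], g[13:15]), c(5, 3, 2, 1))
  )
  tops <- top_genes(tabs)
  expect_length(tops$necrosis, 10)
  expect_false("RPL7" %in% tops$necrosis)      # largest logFC but ribosomal
  expect_false(g[1] %in% tops$palisade)        # shown once, under necrosis
  expect_identical(tops$palisade, g[13:15])    # "up to" 10: three qualify

  # non-significant or negative genes never qualify
  t3 <- mk(c("x", "y"), c(4, 3))
  t3$adj_p <- c(0.2, 1e-5); t3$logFC <- c(4, -3)
  expect_length(top_genes(list(r = t3))$r, 0)
})

test_that("z-scaling matches the arithmetic and is idempotent", {
  m <- matrix(c(1, 2, 3), 1, dimnames = list("r", NULL))
  expect_equal(unname(zscale_rows(m)), matrix(c(-1, 0, 1), 1))
  set.seed(74)
  m2 <- matrix(rnorm(50), 5, dimnames = list(letters[1:5], NULL))
  z <- zscale_rows(m2)
  expect_true(all(abs(rowMeans(z)) < 1e-9))
  expect_equal(unname(apply(z, 1, sd)), rep(1, 5), tolerance = 1e-9)
  expect_equal(zscale_rows(z), z, tolerance = 1e-12)
  m2[2, ] <- 7
  expect_message(z2 <- zscale_rows(m2), "constant")
  expect_equal(nrow(z2), 4)
})

test_that("cell-type gradient peaks where a type exclusively lives", {
  set.seed(75)
  reg <- data.frame(barcode = sprintf("s%02d", 1:30),
                    label = rep(c("necrosis", "layer2", "layer4"), each = 10),
                    stringsAsFactors = FALSE)
  W <- matrix(runif(30 * 3, 0.1, 0.4), 30,
              dimnames = list(reg$barcode, c("A", "B", "C")))
  W[reg$label == "necrosis", "A"] <- 0.9       # A lives only in necrosis
  W[reg$label != "necrosis", "A"] <- 0.01
  ct <- celltype_gradient(W, reg)
  expect_equal(colnames(ct)[which.max(ct["A", ])], "necrosis")
  expect_equal(colnames(ct), c("necrosis", "layer2", "layer4"))

  # uniform composition scales to nothing (all rows constant)
  W2 <- matrix(1 / 3, 30, 3, dimnames = dimnames(W))
  means_equal <- suppressMessages(celltype_gradient(W2, reg))
  expect_equal(nrow(means_equal), 0)

  # an empty declared region is dropped with a warning
  expect_warning(celltype_gradient(W, reg,
                                   region_order = c("necrosis", "palisade",
                                                    "layer2", "layer4")),
                 "palisade")
})

test_that("full gradient analysis recovers the planted niche geography", {
  cfg <- small_config(seed = 29)
  ref <- simulate_reference(cfg)
  sp <- simulate_spatial(cfg, ref$truth)
  reg <- data.frame(barcode = names(sp$truth$region),
                    label = unname(sp$truth$region),
                    stringsAsFactors = FALSE)
  keep <- names(which(table(reg$label) >= 2))
  reg <- reg[reg$label %in% keep, ]
  expr <- pearson_residual_normalize(sp$counts)
  grad <- suppressMessages(gradient_analysis(
    expr, reg, props = sp$truth$proportions[reg$barcode, ]))
  ct <- grad$celltype_heatmap
  mac_peak <- colnames(ct)[which.max(ct["macrophage", ])]
  expect_true(mac_peak %in% c("necrosis", "palisade"))
  opc_peak <- colnames(ct)[which.max(ct["OPC-like", ])]
  expect_equal(opc_peak, "perivascular")
  # VEGFA should rank among necrosis genes
  expect_true("VEGFA" %in% grad$top_genes$necrosis)
  # heatmap rows are scaled
  if (!is.null(grad$gene_heatmap) && nrow(grad$gene_heatmap) > 0) {
    expect_true(all(abs(rowMeans(grad$gene_heatmap)) < 1e-6))
  }
})
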