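two_group_labels <- function(n1, n2) {
  data.frame(barcode = sprintf("s%03d", seq_len(n1 + n2)),
             label = rep(c("necrosis", "generic_tumor"), c(n1, n2)),
             stringsAsFactors = FALSE)
}

test_that("design matrix shape follows the tumor-collapse rule", {
  rl <- two_group_labels(5, 5)
  des <- build_design(rl)
  expect_equal(colnames(des$matrix), c("intercept", "niche"))
  expect_true(all(des$matrix[, "niche"] %in% 0:1))

  set.seed(61)
  W <- matrix(rgamma(10 * 7, 2), 10,
              dimnames = list(rl$barcode,
                              c(tumor_states, "macrophage",
                                "oligodendrocyte", "endothelial")))
  W <- W / rowSums(W)
  des2 <- suppressMessages(build_design(rl, props = W))
  expect_equal(colnames(des2$matrix),
               c("intercept", "niche", "tumor", "macrophage",
                 "oligodendrocyte"))
  expect_identical(des2$dropped_type, "endothelial")
  expect_equal(des2$matrix[, "tumor"],
               rowSums(W[, tumor_states]), tolerance = 1e-12)
})

test_that("degenerate and collinear designs are reported", {
  rl <- two_group_labels(4, 4)
  rl$label <- "necrosis"                      # one group only
  expect_error(build_design(rl), "exactly 2")
  rl <- two_group_labels(1, 7)
  expect_error(build_design(rl), "at least 2 spots")
  rl <- two_group_labels(4, 4)
  W <- cbind(A = rep(0.5, 8), B = rep(0.5, 8))
  rownames(W) <- rl$barcode
  # constant proportion columns are pruned rather than fatal
  des <- suppressMessages(build_design(rl, props = W, tumor_states = "A"))
  expect_true("tumor" %in% des$pruned)
})

test_that("a gene identical across groups gets logFC 0 and p 1", {
  rl <- two_group_labels(4, 4)
  v <- matrix(rnorm(8 * 5), 5, dimnames = list(sprintf("g%d", 1:5),
                                               rl$barcode))
  v[3, ] <- 2.5                                # constant gene
  des <- build_design(rl)
  deg <- suppressMessages(fit_deg(as_norm(v, "spot"), des))
  expect_equal(deg$logFC[3], 0, tolerance = 1e-12)
  expect_equal(deg$p_value[3], 1)
})

test_that("unmoderated fit reproduces the pooled-variance two-sample t", {
  set.seed(62)
  n1 <- 6; n2 <- 8
  rl <- two_group_labels(n1, n2)
  v <- matrix(rnorm(200 * (n1 + n2), sd = 2), 200,
              dimnames = list(sprintf("g%03d", 1:200), rl$barcode))
  des <- build_design(rl)
  deg <- fit_deg(as_norm(v, "spot"), des, moderate = FALSE)
  g1 <- rl$barcode[rl$label == "necrosis"]
  g2 <- rl$barcode[rl$label == "generic_tumor"]
  for (g in sprintf("g%03d", c(1, 57, 200))) {
    x <- v[g, g1]; y <- v[g, g2]
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    t_ref <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    i <- match(g, deg$gene)
    expect_equal(deg$logFC[i], mean(x) - mean(y), tolerance = 1e-9)
    expect_equal(deg$t[i], t_ref, tolerance = 1e-9)
    expect_equal(deg$p_value[i],
                 2 * pt(-abs(t_ref), df = n1 + n2 - 2), tolerance = 1e-9)
  }
})

test_that("moderated statistics agree with limma on a shared design", {
  skip_if_not_installed("limma")
  set.seed(63)
  rl <- two_group_labels(10, 10)
  v <- matrix(rnorm(300 * 20, sd = rep(runif(300, 0.5, 2), 20)), 300,
              dimnames = list(sprintf("g%03d", 1:300), rl$barcode))
  des <- build_design(rl)
  deg <- fit_deg(as_norm(v, "spot"), des)
  fit <- limma::lmFit(v, des$matrix)
  fit <- limma::eBayes(fit)
  expect_equal(deg$logFC, unname(fit$coefficients[, "niche"]),
               tolerance = 1e-9)
  # the moments-based prior is not limma's exact fit, but the moderated t
  # should track it closely on a well-behaved dataset
  expect_gt(cor(deg$t, fit$t[, "niche"]), 0.999)
  expect_lt(mean(abs(deg$t - fit$t[, "niche"])) / mean(abs(deg$t)), 0.05)
})

test_that("a null simulation keeps the BH-significant fraction controlled", {
  set.seed(64)
  rl <- two_group_labels(15, 15)
  v <- matrix(rnorm(2000 * 30), 2000,
              dimnames = list(sprintf("g%04d", 1:2000), rl$barcode))
  deg <- fit_deg(as_norm(v, "spot"), build_design(rl))
  frac <- mean(deg$adj_p < 0.05)
  expect_lte(frac, 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))
})

test_that("fit is invariant to spot order and per-gene constants", {
  set.seed(65)
  rl <- two_group_labels(5, 6)
  v <- matrix(rnorm(50 * 11), 50, dimnames = list(sprintf("g%02d", 1:50),
                                                  rl$barcode))
  des <- build_design(rl)
  base <- fit_deg(as_norm(v, "spot"), des)
  perm <- sample(11)
  shifted <- fit_deg(as_norm(v[, perm] + 0, "spot"), des)
  expect_equal(shifted$t, base$t, tolerance = 1e-9)
  v2 <- v + matrix(rnorm(50), 50, 11)          # gene-wise constant offsets
  offset <- fit_deg(as_norm(v2, "spot"), des)
  expect_equal(offset$logFC, base$logFC, tolerance = 1e-9)
  expect_equal(offset$t, base$t, tolerance = 1e-9)
})

test_that("logFC comparison behaves on identity, negation, and planted effects", {
  set.seed(66)
  rl <- two_group_labels(8, 8)
  v <- matrix(rnorm(100 * 16), 100, dimnames = list(sprintf("g%03d", 1:100),
                                                    rl$barcode))
  deg <- fit_deg(as_norm(v, "spot"), build_design(rl))
  self <- compare_logfc(deg, deg)
  expect_equal(self$pearson_r, 1, tolerance = 1e-12)
  expect_equal(self$n_shared, 100)
  neg <- deg; neg$logFC <- -neg$logFC
  expect_equal(compare_logfc(deg, neg)$pearson_r, -1, tolerance = 1e-12)
  expect_error(compare_logfc(deg[1:2, ], deg[3:4, ]), "shared")

  # two samples sharing planted niche effects correlate positively
  effect <- c(rep(1, 20), rep(0, 80))
  make_sample <- function(seed) {
    set.seed(seed)
    vi <- matrix(rnorm(100 * 16), 100,
                 dimnames = list(sprintf("g%03d", 1:100), rl$barcode))
    vi[, rl$label == "necrosis"] <- vi[, rl$label == "necrosis"] + effect
    fit_deg(as_norm(vi, "spot"), build_design(rl))
  }
  cmp <- compare_logfc(make_sample(67), make_sample(68))
  expect_gt(cmp$pearson_r, 0.3)
})

test_that("top-gene selection ranks by |logFC| per direction with stable ties", {
  deg <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    logFC = c(2, -3, 1, -1, 2),
                    t = 0, p_value = 0.01, adj_p = 0.01,
                    significant = TRUE, stringsAsFactors = FALSE)
  class(deg) <- c("deg_table", "data.frame")
  top <- select_top_genes(deg, n = 2)
  expect_identical(top$up, c("a", "e"))       # tie at 2 -> alphabetical
  expect_identical(top$down, c("b", "d"))
  all_pos <- deg; all_pos$logFC <- abs(all_pos$logFC)
  expect_length(select_top_genes(all_pos, n = 2)$down, 0)
  expect_error(select_top_genes(deg[0, ]), "empty")
})
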