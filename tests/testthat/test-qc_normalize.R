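# helper: build a cell matrix with a prescribed number of expressed genes
# and mitochondrial fraction per cell
qc_fixture <- function(n_expressed, mito_frac, n_genes = 600) {
  n_cells <- length(n_expressed)
  genes <- c(sprintf("G%03d", seq_len(n_genes)), "MT-1")
  m <- matrix(0, n_genes + 1, n_cells,
              dimnames = list(genes, sprintf("c%d", seq_len(n_cells))))
  for (j in seq_len(n_cells)) {
    m[seq_len(n_expressed[j]), j] <- 1
    # add mito counts to hit the target fraction exactly:
    # mito / (mito + n_expressed) = f  =>  mito = f*n/(1-f)
    f <- mito_frac[j]
    mito <- round(f * n_expressed[j] / (1 - f))
    m["MT-1", j] <- mito
  }
  count_matrix(m, unit_kind = "cell")
}

test_that("cell filter honors the printed 500-gene / 5%-mito boundaries", {
  cm <- qc_fixture(n_expressed = c(499, 500, 500), mito_frac = c(0, 0.05, 0))
  # c2: 500 expressed genes + mito gene also expressed -> recount
  out <- filter_cells(cm)
  kept <- colnames(out$values)
  expect_false("c1" %in% kept)              # 499 expressed genes: removed
  expect_true("c3" %in% kept)               # 500 genes, 0% mito: retained
  log <- attr(out, "removal_log")
  expect_true(all(log$reason == "low_genes"))
})

test_that("exact 5% mitochondrial fraction is retained, over 5% removed", {
  genes <- c("g1", "g2", "MT-1")
  m <- matrix(c(950, 0, 50,        # exactly 5%
                949, 0, 51),       # 5.1%
              nrow = 3, dimnames = list(genes, c("s1", "s2")))
  cm <- count_matrix(m, unit_kind = "spot")
  out <- filter_spots(cm)
  expect_identical(colnames(out$values), "s1")
  expect_equal(attr(out, "removal_log")$barcode, "s2")

  # all-zero-mito input passes through untouched
  cm2 <- rand_cm(1, unit_kind = "spot")
  out2 <- filter_spots(cm2)
  expect_identical(out2$values, cm2$values)
})

test_that("a 10-cell fixture filters to exactly the brute-force retained set", {
  set.seed(42)
  n_expr <- sample(480:520, 10, replace = TRUE)
  mito <- runif(10, 0, 0.1)
  cm <- qc_fixture(n_expr, mito)
  out <- filter_cells(cm)
  # independent scalar oracle over the realized matrix
  keep <- vapply(seq_len(10), function(j) {
    col <- cm$values[, j]
    ng <- sum(col > 0)
    mf <- col["MT-1"] / sum(col)
    ng >= 500 && mf <= 0.05
  }, logical(1))
  expect_identical(colnames(out$values), colnames(cm$values)[keep])
})

test_that("filters are idempotent", {
  set.seed(8)
  cm <- qc_fixture(sample(480:520, 8, TRUE), runif(8, 0, 0.08))
  once <- filter_cells(cm)
  twice <- filter_cells(once)
  expect_identical(twice$values, once$values)
  sp <- qc_fixture(sample(480:520, 8, TRUE), runif(8, 0, 0.08))
  sp$unit_kind <- "spot"
  o1 <- filter_spots(sp)
  expect_identical(filter_spots(o1)$values, o1$values)
})

test_that("lognormalize matches its closed form and a scalar reference loop", {
  m <- matrix(c(0, 10, 90, 9900), 2, dimnames = list(c("a", "b"),
                                                     c("u1", "u2")))
  m["b", "u1"] <- 1e4 - 10   # u1 total = 1e4
  cm <- count_matrix(m, unit_kind = "cell")
  nm <- lognormalize(cm, scale_factor = 1e4)
  expect_equal(nm$values["a", "u1"], 0)
  expect_equal(nm$values["a", "u2"] == 0, FALSE)
  # count 10 at unit total 1e4, scale 1e4 -> ln(11): construct directly
  m2 <- matrix(c(10, 9990), 2, dimnames = list(c("x", "y"), "u"))
  expect_equal(lognormalize(count_matrix(m2, unit_kind = "cell"))$values["x", "u"],
               log(11))

  cm3 <- rand_cm(3, 5, 5)
  nm3 <- lognormalize(cm3, scale_factor = 1234)
  ref <- cm3$values
  for (i in 1:5) for (j in 1:5) {
    ref[i, j] <- log(1 + cm3$values[i, j] * 1234 / sum(cm3$values[, j]))
  }
  expect_equal(nm3$values, ref, tolerance = 1e-12)
  # monotone in the count for fixed unit total
  ord <- order(cm3$values[, 1])
  expect_true(all(diff(nm3$values[ord, 1]) >= 0))

  m0 <- matrix(c(1, 0), 1, dimnames = list("g", c("u1", "u2")))
  expect_error(lognormalize(count_matrix(m0, unit_kind = "cell")), "u2")
})

test_that("pearson residuals vanish on rank-1 tables and match the scalar form", {
  # rank-1 expected table: x_gu = r_g * c_u with integer entries
  r <- c(2, 4, 6); cu <- c(1, 3, 5, 7)
  m <- outer(r, cu)
  dimnames(m) <- list(c("a", "b", "c"), sprintf("u%d", 1:4))
  nm <- pearson_residual_normalize(count_matrix(m, unit_kind = "spot"))
  expect_true(all(abs(nm$values) < 1e-12))

  # Poisson limit: x = mu + sqrt(mu) with theta -> inf gives residual 1
  mu <- 64
  x <- mu + sqrt(mu)
  expect_equal((x - mu) / sqrt(mu + mu^2 / 1e12), 1, tolerance = 1e-4)

  cm <- rand_cm(5, 6, 8, unit_kind = "spot")
  nm2 <- pearson_residual_normalize(cm, theta = 50)
  x <- cm$values
  gt <- rowSums(x); ut <- colSums(x); tot <- sum(x)
  ref <- x
  for (i in 1:6) for (j in 1:8) {
    mu_ij <- gt[i] * ut[j] / tot
    ref[i, j] <- (x[i, j] - mu_ij) / sqrt(mu_ij + mu_ij^2 / 50)
  }
  clip <- sqrt(8)
  ref[ref > clip] <- clip; ref[ref < -clip] <- -clip
  expect_equal(nm2$values, ref, tolerance = 1e-12)
})

test_that("pearson residual rows are approximately standard normal under the null", {
  set.seed(77)
  n_units <- 2000
  rates <- rgamma(200, 2, 0.5)
  depth <- runif(n_units, 0.5, 2)
  m <- matrix(rpois(200 * n_units, outer(rates, depth)), 200,
              dimnames = list(sprintf("g%d", 1:200),
                              sprintf("u%d", seq_len(n_units))))
  nm <- pearson_residual_normalize(count_matrix(m, unit_kind = "cell"))
  expect_lt(mean(abs(rowMeans(nm$values))), 0.1)
  expect_lt(abs(mean(apply(nm$values, 1, sd)) - 1), 0.2)
})
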