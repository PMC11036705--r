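# small deterministic profiles for identifiability tests
toy_profiles <- function(seed = 1, n_types = 2, n_genes = 40) {
  set.seed(seed)
  p <- matrix(rgamma(n_types * n_genes, 0.5), n_types,
              dimnames = list(sprintf("t%d", seq_len(n_types)),
                              sprintf("g%02d", seq_len(n_genes))))
  p <- p / rowSums(p)
  structure(list(profiles = p, cells_per_type = rep(100, n_types),
                 dropped_types = character(0)),
            class = "signature_profiles")
}

spot_cm_from <- function(counts_mat) {
  count_matrix(counts_mat, unit_kind = "spot")
}

test_that("the 25-cell reference minimum is a retain-at-25 boundary", {
  set.seed(2)
  n <- 24 + 25 + 30
  m <- matrix(rpois(50 * n, 3), 50,
              dimnames = list(sprintf("g%02d", 1:50),
                              sprintf("c%03d", seq_len(n))))
  labels <- rep(c("rare", "edge", "common"), c(24, 25, 30))
  cm <- count_matrix(m, unit_kind = "cell")
  profs <- suppressMessages(build_signatures(cm, labels, min_cells = 25))
  expect_setequal(rownames(profs$profiles), c("edge", "common"))
  expect_identical(profs$dropped_types, "rare")
})

test_that("profiles are normalized sums matching a hand computation", {
  m <- matrix(c(3, 1, 0,
                1, 1, 2,
                0, 2, 2,
                4, 0, 0), nrow = 4, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3", "g4"),
                              c("c1", "c2", "c3")))
  cm <- count_matrix(m, unit_kind = "cell")
  labels <- c("A", "A", "B")
  profs <- build_signatures(cm, labels, min_cells = 1, pseudocount = 0.5)
  sums_a <- rowSums(m[, 1:2]) + 0.5
  expect_equal(unname(profs$profiles["A", ]), unname(sums_a / sum(sums_a)),
               tolerance = 1e-12)
  # identical cells in two labels give identical rows
  labels2 <- c("X", "Y", "Z")
  m2 <- m; m2[, 2] <- m2[, 1]
  profs2 <- build_signatures(count_matrix(m2, unit_kind = "cell"), labels2,
                             min_cells = 1)
  expect_equal(profs2$profiles["X", ], profs2$profiles["Y", ],
               tolerance = 1e-12)
  expect_error(build_signatures(cm, c("A", "A", "B"), min_cells = 3),
               "fewer than 2")
})

test_that("a pure multinomial spot is assigned to its generating type", {
  profs <- toy_profiles(seed = 3, n_types = 3)
  set.seed(4)
  y <- rmultinom(1, 1e5, profs$profiles["t2", ])
  cm <- spot_cm_from(matrix(y, ncol = 1,
                            dimnames = list(colnames(profs$profiles), "s1")))
  fit <- suppressMessages(deconvolve(cm, profs))
  expect_gte(fit$proportions["s1", "t2"], 0.95)
  expect_equal(sum(fit$proportions["s1", ]), 1, tolerance = 1e-6)
})

test_that("50/50 two-type mixtures are recovered within 0.05 mean error", {
  profs <- toy_profiles(seed = 5, n_types = 2, n_genes = 60)
  set.seed(6)
  mix <- 0.5 * profs$profiles["t1", ] + 0.5 * profs$profiles["t2", ]
  Y <- rmultinom(100, 1e4, mix)
  dimnames(Y) <- list(colnames(profs$profiles), sprintf("s%03d", 1:100))
  fit <- suppressMessages(deconvolve(spot_cm_from(Y), profs))
  expect_lt(mean(abs(fit$proportions[, "t1"] - 0.5)), 0.05)
  expect_true(all(abs(rowSums(fit$proportions) - 1) < 1e-6))
  expect_true(all(fit$proportions >= 0))
})

test_that("identical profiles are non-identifiable but their sum is stable", {
  profs <- toy_profiles(seed = 7, n_types = 3)
  profs$profiles["t2", ] <- profs$profiles["t1", ]
  set.seed(8)
  mix <- 0.6 * profs$profiles["t1", ] + 0.4 * profs$profiles["t3", ]
  Y <- rmultinom(20, 2e4, mix)
  dimnames(Y) <- list(colnames(profs$profiles), sprintf("s%02d", 1:20))
  fit <- suppressMessages(deconvolve(spot_cm_from(Y), profs))
  shared <- fit$proportions[, "t1"] + fit$proportions[, "t2"]
  expect_lt(mean(abs(shared - 0.6)), 0.05)
  # uniform initialization splits the flat direction evenly
  expect_equal(fit$proportions[, "t1"], fit$proportions[, "t2"],
               tolerance = 1e-8)
})

test_that("EM attains at least the coarse grid-search optimum (2 types)", {
  for (seed in 1:20) {
    profs <- toy_profiles(seed = 100 + seed, n_types = 2, n_genes = 25)
    set.seed(200 + seed)
    w_true <- runif(1)
    mix <- w_true * profs$profiles["t1", ] +
      (1 - w_true) * profs$profiles["t2", ]
    y <- as.vector(rmultinom(1, 3000, mix))
    cm <- spot_cm_from(matrix(y, ncol = 1,
                              dimnames = list(colnames(profs$profiles), "s")))
    fit <- suppressMessages(deconvolve(cm, profs, tol = 1e-12))
    # independent oracle: exhaustive grid over the simplex
    grid <- seq(0, 1, by = 0.01)
    ll_grid <- vapply(grid, function(w) {
      lam <- w * profs$profiles["t1", ] + (1 - w) * profs$profiles["t2", ]
      sum(y * log(lam)) - sum(y)
    }, numeric(1))
    expect_gte(fit$convergence$loglik[1] + 1e-9, max(ll_grid))
  }
})

test_that("zero-total spots are flagged and excluded, gene mismatch errors", {
  profs <- toy_profiles(seed = 9, n_types = 2)
  Y <- matrix(c(rep(1, 40), rep(0, 40)), 40,
              dimnames = list(colnames(profs$profiles), c("ok", "empty")))
  expect_warning(fit <- suppressMessages(deconvolve(spot_cm_from(Y), profs)),
                 "zero total")
  expect_true(all(is.na(fit$proportions["empty", ])))
  expect_true(fit$convergence$zero_total[2])
  bad <- count_matrix(matrix(1, 1, 1, dimnames = list("nope", "s")),
                      unit_kind = "spot")
  expect_error(suppressMessages(deconvolve(bad, profs)), "no shared genes")
})

test_that("deconvolution recovers the planted spot composition end to end", {
  cfg <- small_config(seed = 23)
  ref <- simulate_reference(cfg)
  sp <- simulate_spatial(cfg, ref$truth)
  cells <- filter_cells(ref$counts)
  labels <- ref$truth$cell_type[colnames(cells$values)]
  profs <- suppressMessages(build_signatures(cells, labels))
  fit <- suppressMessages(deconvolve(sp$counts, profs))
  W <- fit$proportions
  tr <- sp$truth$proportions[rownames(W), colnames(W)]
  cors <- diag(cor(tr, W))
  expect_true(all(cors > 0.8))
})
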