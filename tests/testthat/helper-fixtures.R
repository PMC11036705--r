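# Fixture builders shared across the suite. Everything is generated in code;
# no stored data files.

# tiny deterministic count matrix
tiny_cm <- function(unit_kind = "cell") {
  m <- matrix(c(2, 4, 0, 2,
                1, 0, 3, 5,
                0, 0, 0, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("u1", "u2", "u3", "u4")))
  count_matrix(m, unit_kind = unit_kind)
}

rand_cm <- function(seed, n_genes = 20, n_units = 10, unit_kind = "cell",
                    lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_units, lambda), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("u%02d", seq_len(n_units))))
  count_matrix(m, unit_kind = unit_kind)
}

# scaled-down simulation for multi-seed loops; overrides win
small_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_genes = 1200, n_cells_per_type = 60, baseline_rate = 2,
         grid_shape = c(12, 12), cells_per_spot = 6,
         low_quality_fraction = 0, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# normalized_matrix wrapper around a plain value matrix
as_norm <- function(values, unit_kind = "cell", method = "lognorm") {
  structure(list(values = values, method = method, unit_kind = unit_kind),
            class = "normalized_matrix")
}

tumor_states <- c("MES-like", "AC-like", "OPC-like", "NPC-like")
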