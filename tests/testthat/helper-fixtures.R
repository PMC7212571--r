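# Shared fixtures, built once per test run.  Sizes are deliberately small;
# the acceptance tests build their own full-scale inputs.

with_seed <- biobombe:::with_seed

tiny_sim <- generate_expression(synthetic_spec(
  n_samples = 120, n_genes = 300, n_factors = 3, genes_per_factor = 20,
  factor_strength = 1, noise_sd = 0.1, n_tissues = 3,
  n_decoy_sets = 10, decoy_set_size = 20, seed = 7
))

tiny_split <- stratified_split(
  tiny_sim$expression,
  stats::setNames(tiny_sim$metadata$tissue, tiny_sim$metadata$sample_id),
  train_fraction = 0.9, seed = 11
)
tiny_train <- minmax_scale(tiny_split$train)
tiny_test <- minmax_scale(tiny_split$test)

tiny_gmt_path <- tempfile(fileext = ".gmt")
tiny_collection <- write_planted_gmt(
  tiny_sim$truth, tiny_gmt_path, universe = colnames(tiny_sim$expression),
  n_decoy_sets = 10, decoy_set_size = 20, seed = 13
)
tiny_H <- build_membership(tiny_collection, colnames(tiny_train))

# random bipartite membership matrix for network permutation tests
random_bipartite <- function(n_sets, n_genes, p_edge, seed) {
  with_seed(seed, {
    H <- matrix(rbinom(n_sets * n_genes, 1, p_edge), n_sets, n_genes,
                dimnames = list(sprintf("set%02d", seq_len(n_sets)),
                                sprintf("g%03d", seq_len(n_genes))))
  })
  H
}

# brute-force per-cell z-score oracle, independent of the matrix engine
zscore_loop_oracle <- function(G, perm_list) {
  Z <- G * NA_real_
  for (i in seq_len(nrow(G))) {
    for (j in seq_len(ncol(G))) {
      vals <- vapply(perm_list, function(P) P[i, j], numeric(1))
      m <- mean(vals)
      s <- sqrt(mean((vals - m)^2))
      Z[i, j] <- if (s == 0) {
        if (G[i, j] == m) 0 else NA_real_
      } else {
        (G[i, j] - m) / s
      }
    }
  }
  Z
}
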