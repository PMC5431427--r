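# Shared fixtures and independent oracles.

# Tiny hand-sized study: 4 genes x 4 samples, 2 organs x 2 replicates.
tiny_study <- function() {
  counts <- matrix(c(10L, 0L, 5L, 100L,
                     20L, 0L, 6L, 90L,
                     12L, 3L, 50L, 80L,
                     15L, 4L, 60L, 70L), nrow = 4,
                   dimnames = list(paste0("g", 1:4),
                                   c("root_1", "root_2", "leaf_1", "leaf_2")))
  design <- data.frame(sample_id = colnames(counts),
                       organ = rep(c("root", "leaf"), each = 2),
                       replicate = rep(1:2, 2))
  expression_study(counts, setNames(c(1000, 2000, 500, 1500), rownames(counts)), design)
}

# Independent TOM oracle: literal triple loop over the definition.
tom_oracle <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  k <- rowSums(a)
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    u <- setdiff(seq_len(n), c(i, j))
    L <- sum(a[i, u] * a[u, j])
    out[i, j] <- (L + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

random_adjacency <- function(n) {
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

random_tom <- function(n) {
  tom_similarity(signed_adjacency(random_adjacency(n) * 2 - 1, beta = 4))
}

# Quick simulated study for stage tests.
quick_sim <- function(seed = 1, ...) {
  generate_dataset(simulation_config(
    n_genes = 300, n_modules = 3, module_sizes = rep(40, 3),
    n_tfs = 8, n_pathway_genes = 4, n_planted_links = 4,
    n_organ_specific = 12, seed = seed, ...))
}
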