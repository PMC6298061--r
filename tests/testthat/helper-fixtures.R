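# Fixtures built in code, shared across test files.

# deterministic small dataset: linear gene/sample grid plus optional noise
make_dataset <- function(id, tissue, genes, n_samples, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(length(genes) * n_samples, mean = 7),
              nrow = length(genes), dimnames = list(genes, NULL))
  colnames(m) <- sprintf("s%02d", seq_len(n_samples))
  expression_dataset(id, tissue, m)
}

# a random correlation_entry on `n_genes` genes (already bin-transformed
# when bins is not NULL)
make_entry <- function(n_genes = 10, n_samples = 50, seed = 1,
                       tissue = "brain", id = "d1", bins = NULL) {
  d <- make_dataset(id, tissue, sprintf("g%03d", seq_len(n_genes)),
                    n_samples, seed = seed)
  e <- correlation_network(d, d$gene_ids)
  if (!is.null(bins)) e <- bin_transform(e, bins)
  e
}

# brute-force per-pair Pearson loop (oracle for correlation_network)
oracle_pearson <- function(m) {
  g <- rownames(m)
  out <- matrix(NA_real_, nrow(m), nrow(m), dimnames = list(g, g))
  for (i in seq_len(nrow(m)))
    for (j in seq_len(nrow(m)))
      if (i != j) out[i, j] <- cor(m[i, ], m[j, ])
  out
}

# brute-force binned rank value of one correlation among a vector (oracle
# for bin_transform): per-pair rank/ceil computation
oracle_bin <- function(r, all_r, n_bins) {
  if (r < 0) return(0.5)
  q <- sum(all_r <= r) / length(all_r)
  max(ceiling(q * n_bins) / n_bins, 0.5)
}

# literal double-sum TSS (oracle for tss_score)
oracle_tss <- function(target_vals, other_vals) {
  acc <- 0
  for (p in target_vals)
    for (q in other_vals)
      acc <- acc + max(p - q, 0)
  acc / (length(target_vals) * length(other_vals))
}

# small multi-tissue collection with planted structure for pipeline tests
small_sim <- function(seed = 7, ...) {
  simulate_collection(simulation_design(
    n_tissues = 3, datasets_per_tissue = c(7, 8),
    samples_per_dataset = c(30, 60), n_genes = 150,
    n_planted_pure = 3, n_planted_induced1 = 3, n_planted_induced2 = 3,
    n_modules = 2, module_size = 6, rng_seed = seed, ...))
}

# store/datasets pair with controlled SB values for the expression model:
# 4 genes, n_ds datasets with random per-dataset expression means
model_fixture <- function(n_ds = 20, seed = 1) {
  set.seed(seed)
  genes <- c("gA", "gB", "gC", "gD")
  datasets <- lapply(seq_len(n_ds), function(k) {
    m <- matrix(rnorm(4 * 6, mean = rnorm(4, 8, 1.5)), nrow = 4,
                dimnames = list(genes, NULL))
    expression_dataset(sprintf("d%02d", k), sprintf("t%d", (k %% 4) + 1), m)
  })
  names(datasets) <- vapply(datasets, `[[`, "", "dataset_id")
  store <- lapply(datasets, function(d)
    bin_transform(correlation_network(d, genes), 1000))
  list(datasets = datasets, store = store, genes = genes)
}

# overwrite the SB value of pair (gA,gB) in every store entry
set_sb <- function(store, values) {
  for (k in seq_along(store)) {
    store[[k]]$sb["gA", "gB"] <- values[k]
    store[[k]]$sb["gB", "gA"] <- values[k]
  }
  store
}

random_links <- function(genes, n, seed = 1) {
  set.seed(seed)
  a <- sample(genes, n, replace = TRUE)
  b <- sample(genes, n, replace = TRUE)
  keep <- a != b
  unique(canonical_pairs(a[keep], b[keep]))
}
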