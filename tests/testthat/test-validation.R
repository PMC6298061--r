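# a reference TAN and an external correlation entry on a shared universe
validation_fixture <- function(seed = 1, n_genes = 120) {
  genes <- sprintf("g%03d", seq_len(n_genes))
  bns <- lapply(1:7, function(k) {
    e <- make_entry(n_genes = n_genes, n_samples = 25, seed = seed * 100 + k)
    binarize(e, 0.97)
  })
  tan <- build_tan(bns, n = 2, tissue = "brain")
  ext <- make_entry(n_genes = n_genes, n_samples = 40, seed = seed * 999,
                    tissue = "brain", id = "ext")
  list(genes = genes, tan = tan, ext = ext)
}

test_that("density matching reproduces the reference density", {
  fx <- validation_fixture(seed = 2)
  bin <- match_density_binarize(fx$ext, fx$tan)
  n_pairs <- choose(length(bin$genes), 2)
  expect_lte(abs(bin$density - bin$reference_density), 1 / n_pairs)
  # cutoff agrees with a sort-based oracle
  m <- nrow(fx$tan$links)
  v <- sort(fx$ext$corr[upper.tri(fx$ext$corr)], decreasing = TRUE)
  expect_equal(bin$cutoff, v[m + 1])
  expect_equal(sum(bin$adjacency[upper.tri(bin$adjacency)]),
               sum(fx$ext$corr[upper.tri(fx$ext$corr)] > v[m + 1]))
})

test_that("an empty reference TAN yields an empty external network", {
  fx <- validation_fixture(seed = 3)
  empty_tan <- build_tan(list(binarize(make_entry(120, 25, seed = 5), 0.97)),
                         n = 2, tissue = "brain")
  expect_equal(nrow(empty_tan$links), 0L)
  bin <- match_density_binarize(fx$ext, empty_tan)
  expect_equal(sum(bin$adjacency), 0L)
})

test_that("insufficient gene overlap is fatal", {
  fx <- validation_fixture(seed = 4, n_genes = 30)
  expect_error(match_density_binarize(fx$ext, fx$tan, min_overlap = 100),
               "shared")
})

test_that("overlap likelihood ratio hits its closed-form anchors", {
  fx <- validation_fixture(seed = 5)
  bin <- match_density_binarize(fx$ext, fx$tan)
  adj <- which(bin$adjacency & upper.tri(bin$adjacency), arr.ind = TRUE)
  inside <- data.frame(gene_a = bin$genes[adj[, 1]],
                       gene_b = bin$genes[adj[, 2]])
  # a group entirely inside the external links: LR = 1/density
  expect_equal(overlap_likelihood_ratio(inside, bin), 1 / bin$density)
  # a disjoint group: LR = 0
  non <- which(!bin$adjacency & upper.tri(bin$adjacency), arr.ind = TRUE)
  outside <- data.frame(gene_a = bin$genes[non[1:50, 1]],
                        gene_b = bin$genes[non[1:50, 2]])
  expect_equal(overlap_likelihood_ratio(outside, bin), 0)
  expect_equal(reproduced_fraction(inside, bin), 1.0)
  expect_equal(reproduced_fraction(outside, bin), 0.0)
  # empty group: missing
  expect_true(is.na(overlap_likelihood_ratio(
    data.frame(gene_a = "zz1", gene_b = "zz2"), bin)))
})

test_that("random link groups have likelihood ratio near 1", {
  fx <- validation_fixture(seed = 6)
  bin <- match_density_binarize(fx$ext, fx$tan)
  grp <- random_links(bin$genes, 2000, seed = 6)
  expect_lt(abs(overlap_likelihood_ratio(grp, bin) - 1), 0.2)
})

test_that("group correlation distributions collapse to the null for all pairs", {
  fx <- validation_fixture(seed = 7)
  pairs <- which(upper.tri(fx$ext$corr), arr.ind = TRUE)
  all_pairs <- data.frame(gene_a = fx$genes[pairs[, 1]],
                          gene_b = fx$genes[pairs[, 2]])
  res <- group_correlation_distributions(
    list(all = all_pairs, none = data.frame(gene_a = "zz", gene_b = "zz2")),
    fx$ext)
  expect_equal(unname(unlist(res$groups[1, c("q05", "q25", "q50",
                                             "q75", "q95")])),
               unname(res$null_quantiles))
  expect_true(is.na(res$groups$p_greater[2]))
  expect_equal(res$groups$n[2], 0L)
})

test_that("topological overlap matches set arithmetic", {
  mk_tan <- function(links, genes) {
    structure(list(tissue = "x", genes = genes, links = links),
              class = "tan")
  }
  genes <- c("a", "b", paste0("n", 1:6))
  # identical neighborhoods of size 5
  links <- rbind(data.frame(gene_a = "a", gene_b = paste0("n", 1:5)),
                 data.frame(gene_a = "b", gene_b = paste0("n", 1:5)))
  links <- canonical_pairs(links$gene_a, links$gene_b)
  expect_equal(unname(topological_overlap("a", "b",
                                          list(x = mk_tan(links, genes)))), 1.0)
  # disjoint neighborhoods
  links2 <- canonical_pairs(c("a", "a", "b", "b"),
                            c("n1", "n2", "n3", "n4"))
  expect_equal(unname(topological_overlap("a", "b",
                                          list(x = mk_tan(links2, genes)))), 0.0)
  # gene absent from the universe: NA
  expect_true(is.na(topological_overlap("a", "zz",
                                        list(x = mk_tan(links, genes)))[1]))
  # random TANs against an explicit set oracle
  set.seed(71)
  for (i in 1:10) {
    lk <- random_links(genes, 12, seed = 70 + i)
    to <- topological_overlap("a", "b", list(x = mk_tan(lk, genes)))
    nb <- function(g) setdiff(unique(c(lk$gene_b[lk$gene_a == g],
                                       lk$gene_a[lk$gene_b == g])),
                              c("a", "b"))
    na_ <- nb("a"); nb_ <- nb("b")
    oracle <- if (length(na_) == 0 || length(nb_) == 0) 0 else
      length(intersect(na_, nb_)) / min(length(na_), length(nb_))
    expect_equal(unname(to), oracle)
  }
})

test_that("planted links reproduce directionally across collections", {
  sim1 <- small_sim(seed = 81)
  sim2 <- small_sim(seed = 82)
  h1 <- harmonize_genes(sim1$datasets)
  dt1 <- vapply(h1$datasets, `[[`, "", "tissue")
  t1 <- sim1$truth$tissue[1]
  ex <- mark_expressed(h1$datasets[dt1 == t1])
  bns <- lapply(h1$datasets[dt1 == t1], function(d)
    binarize(correlation_network(d, ex), 0.90))
  tan <- build_tan(bns, n = aggregation_threshold(length(bns), 0.1,
                                                  choose(length(ex), 2),
                                                  1e-4,
                                                  support_tab = NULL),
                   tissue = t1)
  # external: pooled samples of the same tissue from the second collection
  ext_ds <- Filter(function(d) d$tissue == t1, sim2$datasets)
  pooled <- do.call(cbind, lapply(ext_ds, `[[`, "matrix"))
  ext <- correlation_network(
    expression_dataset("ext", t1, pooled),
    intersect(rownames(pooled), tan$genes))
  bin <- match_density_binarize(ext, tan, min_overlap = 20)
  planted <- sim1$truth[sim1$truth$tissue == t1, c("gene_a", "gene_b")]
  lr_planted <- overlap_likelihood_ratio(planted, bin)
  expect_gt(lr_planted, 1)
  # planted links reproduce far better than background pairs
  bg <- random_links(setdiff(bin$genes, unlist(planted)), 300, seed = 83)
  rf_bg <- reproduced_fraction(bg, bin)
  expect_gte(reproduced_fraction(planted, bin),
             3 * max(rf_bg, 1e-9))
})
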