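test_that("shared-annotation LR matches brute-force enumeration", {
  genes <- sprintf("g%02d", 1:10)
  # two term blocks; links join within-term genes only
  ann <- annotation_map(rep(genes, 1),
                        rep(c("t1", "t2"), each = 5))
  links <- rbind(canonical_pairs(rep(genes[1], 4), genes[2:5]),
                 canonical_pairs(rep(genes[6], 3), genes[7:9]))
  lr <- shared_annotation_lr(links, ann, genes)
  # brute force over all 45 pairs
  share <- function(a, b) length(intersect(ann$gene_terms[[a]],
                                           ann$gene_terms[[b]])) > 0
  pairs <- t(combn(genes, 2))
  key <- paste(pairs[, 1], pairs[, 2])
  lkey <- paste(links$gene_a, links$gene_b)
  is_link <- key %in% lkey
  shares <- mapply(share, pairs[, 1], pairs[, 2])
  oracle <- mean(shares[is_link]) / mean(shares[!is_link])
  expect_equal(as.numeric(lr), oracle)
  expect_gt(as.numeric(lr), 1)
})

test_that("a universal shared term forces LR = 1", {
  genes <- sprintf("g%02d", 1:8)
  ann <- annotation_map(genes, rep("everything", 8))
  links <- canonical_pairs(genes[1:3], genes[4:6])
  expect_equal(as.numeric(shared_annotation_lr(links, ann, genes)), 1)
})

test_that("annotation-blind random links give LR near 1", {
  set.seed(91)
  genes <- sprintf("g%03d", 1:120)   # 7140 pairs
  ann <- annotation_map(rep(genes, times = 2),
                        c(sample(rep(paste0("t", 1:12), each = 10)),
                          sample(rep(paste0("u", 1:12), each = 10))))
  links <- random_links(genes, 2600, seed = 91)
  expect_lt(abs(as.numeric(shared_annotation_lr(links, ann, genes)) - 1),
            0.15)
})

test_that("term enrichment p-values behave at the extremes", {
  set.seed(92)
  genes <- sprintf("g%02d", 1:30)
  links <- random_links(genes, 60, seed = 92)
  # a clique planted on 5 dedicated genes in a sparse random background
  clique_genes <- sprintf("c%d", 1:5)
  universe <- c(genes, clique_genes)
  clique <- as.data.frame(t(combn(clique_genes, 2)))
  names(clique) <- c("gene_a", "gene_b")
  network <- rbind(links, clique)
  res <- term_enrichment(network, clique_genes, universe, n_null = 999,
                         seed = 92)
  expect_equal(res$observed, 10L)
  expect_lte(res$p_emp, 2 / 1000)
  # a fully disconnected term
  lonely <- sprintf("z%d", 1:4)
  res2 <- term_enrichment(network, lonely, c(universe, lonely),
                          n_null = 199, seed = 93)
  expect_equal(res2$observed, 0L)
  expect_gt(res2$p_emp, 0.9)
})

test_that("observed within-term counts match a brute-force filter", {
  set.seed(94)
  genes <- sprintf("g%02d", 1:30)
  links <- random_links(genes, 80, seed = 94)
  term <- sample(genes, 12)
  res <- term_enrichment(links, term, genes, n_null = 9, seed = 94)
  oracle <- sum(links$gene_a %in% term & links$gene_b %in% term)
  expect_equal(res$observed, oracle)
  # removing links can only shrink the within-term count
  fewer <- links[-(1:20), ]
  res2 <- term_enrichment(fewer, term, genes, n_null = 9, seed = 94)
  expect_lte(res2$observed, res$observed)
})

test_that("degree-preserving rewiring null preserves the degree sequence", {
  set.seed(95)
  genes <- sprintf("g%02d", 1:20)
  links <- random_links(genes, 40, seed = 95)
  term <- genes[1:6]
  res <- term_enrichment(links, term, genes, n_null = 49, seed = 95,
                         null_method = "rewire")
  expect_true(res$p_emp > 0 && res$p_emp <= 1)
})

test_that("dropout analysis isolates terms carried by the removed set", {
  # network: a clique on term genes (the "pure" set) plus random background
  set.seed(96)
  bg_genes <- sprintf("g%02d", 1:40)
  term_genes <- sprintf("p%d", 1:6)
  universe <- c(bg_genes, term_genes)
  pure <- as.data.frame(t(combn(term_genes, 2)))
  names(pure) <- c("gene_a", "gene_b")
  background <- random_links(bg_genes, 120, seed = 96)
  network <- rbind(background, pure)
  ann <- annotation_map(term_genes, rep("pure_term", 6))

  before <- enrich_terms(network, ann, universe, n_null = 499, seed = 1)
  expect_true(before$fdr_pass[before$term == "pure_term"])
  after_pure <- enrich_terms(puredc:::remove_links(network, pure), ann,
                             universe, n_null = 499, seed = 1)
  expect_false(isTRUE(after_pure$fdr_pass[after_pure$term == "pure_term"]))
  # random removals disjoint from the pure set never drop the term
  for (r in 1:5) {
    rm_set <- background[sample(nrow(background), nrow(pure)), ]
    after_r <- enrich_terms(puredc:::remove_links(network, rm_set), ann,
                            universe, n_null = 499, seed = 1)
    expect_true(after_r$fdr_pass[after_r$term == "pure_term"])
  }
})

test_that("dropout_analysis reports counts and one-sided p-values", {
  set.seed(97)
  genes <- sprintf("g%02d", 1:30)
  network <- random_links(genes, 90, seed = 97)
  ann <- simulate_annotations(genes, truth = NULL, n_random_terms = 8,
                              term_size_range = c(4, 8), seed = 97)
  empty <- network[0, ]
  res <- dropout_analysis(network, empty, empty, ann, genes,
                          n_random = 5, n_null = 99, seed = 97)
  expect_equal(res$dropout_pure, 0L)
  expect_equal(res$p_vs_random, 1)       # nothing removed: never fewer
  expect_true(all(res$dropout_random == 0L))
  # removing everything drops every enriched term
  res2 <- dropout_analysis(network, network, empty, ann, genes,
                           n_random = 3, n_null = 99, seed = 97)
  expect_equal(res2$dropout_pure, length(res2$enriched_before))
  # removal sets outside the network are fatal
  alien <- data.frame(gene_a = "zz1", gene_b = "zz2")
  expect_error(dropout_analysis(network, alien, empty, ann, genes,
                                n_random = 2, n_null = 49, seed = 1),
               "outside")
})

test_that("exclusive enrichment is a per-tissue set difference", {
  mk <- function(terms, pass) data.frame(term = terms, fdr_pass = pass)
  res <- list(
    brain = mk(c("t1", "t2", "t3"), c(TRUE, TRUE, FALSE)),
    liver = mk(c("t1", "t4"), c(TRUE, TRUE)),
    lung = mk(c("t5"), TRUE))
  ex <- exclusive_enrichment(res)
  expect_equal(ex$brain, "t2")   # t1 shared with liver, t3 not enriched
  expect_equal(ex$liver, "t4")
  expect_equal(ex$lung, "t5")
  # random fixture against a set-difference oracle
  set.seed(98)
  rnd <- lapply(1:4, function(i)
    mk(paste0("t", 1:10), runif(10) < 0.4))
  names(rnd) <- paste0("tis", 1:4)
  ex2 <- exclusive_enrichment(rnd)
  enriched <- lapply(rnd, function(r) r$term[r$fdr_pass])
  for (t in names(rnd)) {
    others <- unlist(enriched[setdiff(names(rnd), t)])
    expect_setequal(ex2[[t]], setdiff(enriched[[t]], others))
  }
})
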