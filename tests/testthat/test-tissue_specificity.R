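test_that("binned rank transform matches a per-pair rank/ceil oracle", {
  e <- make_entry(n_genes = 21, n_samples = 25, seed = 61, bins = 1000)
  v <- e$corr[upper.tri(e$corr)]   # 210 pairs
  sb <- e$sb[upper.tri(e$sb)]
  oracle <- vapply(v, oracle_bin, 0.0, all_r = v, n_bins = 1000)
  expect_equal(sb, oracle, tolerance = 1e-12)
})

test_that("binned values obey the floor and top-bin anchors", {
  e <- make_entry(n_genes = 21, n_samples = 25, seed = 62, bins = 1000)
  v <- e$corr[upper.tri(e$corr)]
  sb <- e$sb[upper.tri(e$sb)]
  # any negative correlation maps to exactly 0.5, regardless of rank
  expect_true(all(sb[v < 0] == 0.5))
  # the single largest correlation gets the top bin
  expect_equal(sb[which.max(v)], 1.0)
  # the floor holds everywhere, on the n_bins grid
  expect_true(all(sb >= 0.5))
  expect_true(all(abs(sb * 1000 - round(sb * 1000)) < 1e-9))
  # the median correlation sits near the middle bin
  med_i <- which(rank(v, ties.method = "first") == ceiling(length(v) / 2))
  expect_lt(abs(sb[med_i] - 0.5), 0.02)
})

test_that("TSS equals the literal double sum and hits its anchors", {
  tissues <- c("brain", "brain", "liver", "lung")
  # all-identical SB values: zero score
  expect_equal(tss_score(rep(0.7, 4), tissues, "brain"), 0)
  # maximal separation: 0.5
  expect_equal(tss_score(c(1, 1, 0.5, 0.5), tissues, "brain"), 0.5)
  # hand-computed 2x2 example: (0.4 + 0.1 + 0.1 + 0) / 4
  expect_equal(tss_score(c(0.9, 0.6, 0.5, 0.8), tissues, "brain"), 0.15)
  # random cases against the oracle
  set.seed(63)
  dt <- rep(c("a", "b", "c"), times = c(5, 7, 4))
  for (i in 1:20) {
    sb <- matrix(runif(16, 0.5, 1), nrow = 1)
    expect_equal(tss_score(sb, dt, "a"),
                 oracle_tss(sb[dt == "a"], sb[dt != "a"]))
  }
})

test_that("TSS is rank-based: invariant to monotone transforms", {
  set.seed(64)
  sim <- small_sim(seed = 64)
  dt0 <- vapply(sim$datasets, `[[`, "", "tissue")
  pick <- unlist(lapply(split(seq_along(dt0), dt0), utils::head, 2))
  h <- harmonize_genes(sim$datasets[pick])
  store <- lapply(h$datasets, function(d) correlation_network(d, h$gene_universe))
  tf <- lapply(store, function(e) {
    e$corr <- tanh(3 * e$corr)  # strictly monotone, sign-preserving
    e
  })
  dt <- vapply(h$datasets, `[[`, "", "tissue")
  links <- random_links(h$gene_universe, 40, seed = 64)
  sb1 <- sb_for_links(bin_transform(store, 1000), links)
  sb2 <- sb_for_links(bin_transform(tf, 1000), links)
  expect_equal(tss_score(sb1, dt, dt[1]), tss_score(sb2, dt, dt[1]))
})

test_that("TSS is invariant to dataset ordering", {
  set.seed(65)
  sb <- matrix(runif(30, 0.5, 1), nrow = 2)
  dt <- rep(c("a", "b", "c"), each = 5)
  perm <- sample(15)
  expect_equal(tss_score(sb, dt, "a"),
               tss_score(sb[, perm], dt[perm], "a"))
})

test_that("the Wilcoxon alternative gives the exact rank-sum p", {
  dt <- rep(c("t", "o"), each = 5)
  # complete separation of 5 vs 5: one-sided exact p = 1 / choose(10,5)
  sb <- c(0.9, 0.95, 0.96, 0.97, 0.98, 0.5, 0.6, 0.62, 0.64, 0.7)
  expect_equal(tss_wilcoxon(sb, dt, "t")[1], 1 / 252)
  # all tied: no evidence
  expect_equal(tss_wilcoxon(rep(0.5, 10), dt, "t")[1], 1)
  # fewer than 2 per side: p = 1 with the underpowered flag
  p <- tss_wilcoxon(c(0.9, 0.5, 0.5), c("t", "o", "o"), "t")
  expect_equal(p[1], 1)
  expect_true(attr(p, "underpowered"))
})

test_that("Wilcoxon p-values are calibrated under the null", {
  set.seed(66)
  dt <- rep(c("t", "o"), times = c(8, 12))
  p <- replicate(400, tss_wilcoxon(runif(20, 0.5, 1), dt, "t")[1])
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("TSS and Wilcoxon rank links concordantly", {
  sim <- small_sim(seed = 67)
  h <- harmonize_genes(sim$datasets)
  dt <- vapply(h$datasets, `[[`, "", "tissue")
  store <- bin_transform(lapply(h$datasets, function(d)
    correlation_network(d, h$gene_universe)), 1000)
  links <- rbind(sim$truth[, c("gene_a", "gene_b")],
                 random_links(h$gene_universe, 80, seed = 67))
  sb <- sb_for_links(store, links)
  t1 <- dt[1]
  tss <- tss_score(sb, dt, t1)
  wp <- tss_wilcoxon(sb, dt, t1)
  expect_gte(cor(tss, -log10(wp + 1e-12), method = "spearman"), 0.8)
})

test_that("pseudo-tissues are balanced across real tissues", {
  dt <- setNames(rep(c("a", "b", "c", "d", "e"), times = c(10, 3, 3, 3, 3)),
                 sprintf("d%02d", 1:22))
  ps <- make_pseudo_tissues(dt, "a", n_pseudo = 5, seed = 1)
  for (p in ps) {
    counts <- table(dt[p$dataset_ids])
    expect_equal(sum(counts), 10L)
    expect_true(all(counts >= floor(10 / 5)))
    expect_true(all(counts <= ceiling(10 / 5) + 1))  # reallocation slack
    expect_equal(anyDuplicated(p$dataset_ids), 0L)
  }
  # size 7, 5 tissues: counts are {2,2,1,1,1} in some order
  dt2 <- setNames(rep(c("a", "b", "c", "d", "e"), times = c(7, 4, 4, 4, 4)),
                  sprintf("d%02d", 1:23))
  ps2 <- make_pseudo_tissues(dt2, "a", n_pseudo = 10, seed = 2)
  for (p in ps2)
    expect_equal(sort(as.integer(table(dt2[p$dataset_ids]))),
                 c(1L, 1L, 1L, 2L, 2L))
  # determinism
  expect_equal(make_pseudo_tissues(dt, "a", 3, seed = 9),
               make_pseudo_tissues(dt, "a", 3, seed = 9))
})

test_that("the TSS FDR curve reproduces hand-computed values", {
  real <- c(0.05, 0.1, 0.2, 0.3, 0.4)
  pseudo <- list(c(0.05, 0.05, 0.1, 0.1, 0.15),
                 c(0.02, 0.08, 0.12, 0.25, 0.3))
  curve <- tss_fdr_curve(real, pseudo)
  # raw Eq-style values at each real tss: mean pseudo-exceedance / real count
  at <- function(t) (sum(unlist(pseudo) > t) / 2) / sum(real > t)
  for (t in c(0.05, 0.1, 0.2, 0.3))
    expect_equal(curve$fdr_raw[match(t, curve$tss)], min(at(t), 1))
  # denominator 0 at the max: FDR defined as 0
  expect_equal(curve$fdr_raw[match(0.4, curve$tss)], 0)
  # smoothing is monotone non-increasing
  expect_true(all(diff(curve$fdr) <= 0))
})

test_that("pseudo TSS all zero means zero FDR above zero", {
  curve <- tss_fdr_curve(c(0.1, 0.2, 0.3), list(rep(0, 3), rep(0, 3)))
  expect_true(all(fdr_at(curve, c(0.1, 0.2, 0.3)) == 0))
})

test_that("FDR near the median is ~1 when real and pseudo nulls coincide", {
  set.seed(68)
  real <- runif(2000, 0, 0.5)
  # each pseudo-tissue scores the same link universe, so same length
  pseudo <- replicate(10, runif(2000, 0, 0.5), simplify = FALSE)
  curve <- tss_fdr_curve(real, pseudo)
  expect_lt(abs(fdr_at(curve, median(real)) - 1), 0.15)
})

test_that("TSN selection applies the threshold and cross-tissue ceiling", {
  tt <- expand.grid(link = 1:3, tissue = c("a", "b"),
                    stringsAsFactors = FALSE)
  tab <- data.frame(gene_a = paste0("g", tt$link),
                    gene_b = paste0("h", tt$link),
                    tan_tissue = "a", tissue = tt$tissue,
                    tss = c(0.45, 0.44, 0.1,    # in tissue a
                            0.1, 0.45, 0.2))    # in tissue b
  curves <- list(a = tss_fdr_curve(c(0.45, 0.44, 0.1),
                                   list(c(0.2, 0.3, 0.12))))
  sel <- select_tsn(tab, curves, fdr_target = 0.01, other_max = 0.4)
  # link 1 passes; link 2 passes FDR but fails the 0.4 ceiling in b;
  # link 3 is below threshold
  expect_equal(sel$a$links$gene_a, "g1")
  # with fdr_target 1 the threshold collapses to the smallest value and
  # only the ceiling filters
  sel2 <- select_tsn(tab, curves, fdr_target = 1, other_max = 0.4)
  expect_setequal(sel2$a$links$gene_a, c("g1", "g3"))
})
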