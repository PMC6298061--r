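# Link-based functional statistics: the shared-annotation likelihood ratio,
# per-term link enrichment against sampling nulls, the drop-out analysis for
# pure vs random vs expression-induced link removal, and exclusive
# enrichment across tissues.

# genes x terms logical incidence matrix restricted to a gene set
term_incidence <- function(annotations, genes) {
  genes <- intersect(genes, names(annotations$gene_terms))
  terms <- sort(unique(unlist(annotations$gene_terms[genes],
                              use.names = FALSE)))
  M <- matrix(FALSE, length(genes), length(terms),
              dimnames = list(genes, terms))
  for (g in genes) M[g, annotations$gene_terms[[g]]] <- TRUE
  M
}

#' Shared-annotation likelihood ratio of a network
#'
#' The probability that two connected genes share at least one annotation
#' term, divided by the same probability for unconnected gene pairs, over
#' all pairs of annotated genes in the universe. LR > 1 means the network's
#' links preferentially join functionally similar genes.
#'
#' @param network_links Data.frame with \code{gene_a}, \code{gene_b}.
#' @param annotations An \code{\link{annotation_map}}.
#' @param gene_universe Character vector of the network's gene universe.
#' @return The likelihood ratio (Inf when no unconnected pair shares a
#'   term), with attributes \code{p_connected} and \code{p_unconnected}.
#' @export
shared_annotation_lr <- function(network_links, annotations, gene_universe) {
  M <- term_incidence(annotations, gene_universe)
  genes <- rownames(M)
  if (length(genes) < 2L)
    stop_fatal("fewer than 2 annotated genes in the universe")
  share <- tcrossprod(M) > 0   # genes x genes: share >= 1 term
  n_pairs <- choose(length(genes), 2)
  s_total <- sum(ut_vec(share))
  idx <- shared_link_index(canonical_pairs(network_links$gene_a,
                                           network_links$gene_b), genes)
  idx <- unique(idx, MARGIN = 1)
  n_conn <- nrow(idx)
  if (n_conn == 0L) stop_fatal("no links among annotated universe genes")
  s_conn <- sum(share[idx])
  p_conn <- s_conn / n_conn
  n_unconn <- n_pairs - n_conn
  s_unconn <- s_total - s_conn
  p_unconn <- if (n_unconn == 0L) NA_real_ else s_unconn / n_unconn
  lr <- if (is.na(p_unconn) || p_unconn == 0) Inf else p_conn / p_unconn
  structure(lr, p_connected = p_conn, p_unconnected = p_unconn)
}

count_within <- function(ia, ib, member) {
  sum(member[ia] & member[ib])
}

#' Link enrichment of one term
#'
#' A term is enriched in a network when the genes annotated with it are
#' joined by more links than expected under the null. The default null
#' draws \code{n_null} random gene sets of the same size from the network's
#' gene universe and counts within-set links; the \code{"rewire"}
#' alternative preserves the degree sequence and counts within-term links
#' in rewired networks. Empirical p = (1 + #(null >= observed)) /
#' (1 + n_null).
#'
#' @param network_links Data.frame with \code{gene_a}, \code{gene_b}.
#' @param term_genes Character vector of the term's genes.
#' @param gene_universe The network's gene universe.
#' @param n_null Number of null draws. Default 999.
#' @param seed Integer seed.
#' @param null_method \code{"gene_sampling"} or \code{"rewire"}.
#' @return List with \code{term_size} (genes in universe), \code{observed},
#'   \code{null_mean}, \code{null_sd} and \code{p_emp}.
#' @export
term_enrichment <- function(network_links, term_genes, gene_universe,
                            n_null = 999L, seed = 1L,
                            null_method = c("gene_sampling", "rewire")) {
  null_method <- match.arg(null_method)
  tg <- intersect(term_genes, gene_universe)
  if (length(tg) < 2L)
    stop_fatal("term has fewer than 2 genes in the universe")
  ia <- match(network_links$gene_a, gene_universe)
  ib <- match(network_links$gene_b, gene_universe)
  keep <- !is.na(ia) & !is.na(ib)
  ia <- ia[keep]
  ib <- ib[keep]
  member <- gene_universe %in% tg
  observed <- count_within(ia, ib, member)
  nulls <- with_seed(child_seed(seed, "term_null"), function() {
    if (null_method == "gene_sampling") {
      vapply(seq_len(n_null), function(s) {
        m <- logical(length(gene_universe))
        m[sample.int(length(gene_universe), length(tg))] <- TRUE
        count_within(ia, ib, m)
      }, 0L)
    } else {
      g <- igraph::graph_from_edgelist(cbind(gene_universe[ia],
                                             gene_universe[ib]),
                                       directed = FALSE)
      vapply(seq_len(n_null), function(s) {
        rw <- igraph::rewire(g, igraph::keeping_degseq(
          niter = 10 * igraph::ecount(g)))
        el <- igraph::as_edgelist(rw)
        sum(el[, 1L] %in% tg & el[, 2L] %in% tg)
      }, 0L)
    }
  })
  list(term_size = length(tg), observed = observed,
       null_mean = mean(nulls), null_sd = stats::sd(nulls),
       p_emp = (1 + sum(nulls >= observed)) / (1 + n_null))
}

#' Link enrichment across all terms of an annotation map
#'
#' Runs \code{\link{term_enrichment}} for every term with at least 2 genes
#' in the universe (smaller terms are skipped, not reported, to avoid
#' diluting the FDR) and applies Benjamini-Hochberg across terms.
#'
#' @inheritParams term_enrichment
#' @param annotations An \code{\link{annotation_map}}.
#' @param fdr BH FDR level for \code{fdr_pass}. Default 0.01.
#' @return Data.frame with one row per tested term: \code{term},
#'   \code{term_size}, \code{observed}, \code{null_mean}, \code{null_sd},
#'   \code{p_emp}, \code{p_adj}, \code{fdr_pass}.
#' @export
enrich_terms <- function(network_links, annotations, gene_universe,
                         n_null = 999L, fdr = 0.01, seed = 1L,
                         null_method = c("gene_sampling", "rewire")) {
  null_method <- match.arg(null_method)
  sizes <- vapply(annotations$term_genes,
                  function(g) length(intersect(g, gene_universe)), 0L)
  terms <- names(sizes)[sizes >= 2L]
  rows <- lapply(seq_along(terms), function(i) {
    res <- term_enrichment(network_links, annotations$term_genes[[terms[i]]],
                           gene_universe, n_null = n_null,
                           seed = child_seed(seed, terms[i]),
                           null_method = null_method)
    data.frame(term = terms[i], term_size = res$term_size,
               observed = res$observed, null_mean = res$null_mean,
               null_sd = res$null_sd, p_emp = res$p_emp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), term_size = integer(),
                      observed = integer(), null_mean = numeric(),
                      null_sd = numeric(), p_emp = numeric(),
                      p_adj = numeric(), fdr_pass = logical()))
  out$p_adj <- stats::p.adjust(out$p_emp, method = "BH")
  out$fdr_pass <- out$p_adj <= fdr
  rownames(out) <- NULL
  out
}

remove_links <- function(links, removal) {
  if (nrow(removal) == 0L) return(links)
  keys <- pair_key(links$gene_a, links$gene_b)
  rm_keys <- pair_key(removal$gene_a, removal$gene_b)
  links[!(keys %in% rm_keys), , drop = FALSE]
}

#' Drop-out analysis of pure-link removal
#'
#' Measures the contribution of a designated link set (typically the pure
#' links) to a network's term enrichment: which terms are enriched before
#' removal, which lose enrichment after removing (1) the pure set, (2)
#' random link sets of equal size, and (3) random subsets of the
#' expression-induced links of equal size. Reports one-sided empirical
#' p-values for the pure removal causing FEWER drop-outs than each random
#' reference.
#'
#' @param network_links Data.frame of the network's links.
#' @param removal_pure Data.frame of the pure links to remove (subset of the
#'   network).
#' @param removal_induced Data.frame of expression-induced links (pool for
#'   condition 3); may be empty.
#' @param annotations An \code{\link{annotation_map}}.
#' @param gene_universe The network's gene universe.
#' @param n_random Random removal repetitions per condition. Default 20.
#' @param n_null Null draws per enrichment run. Default 499.
#' @param fdr Enrichment FDR. Default 0.01.
#' @param seed Integer seed.
#' @return Object of class \code{"dropout_result"}: list with
#'   \code{enriched_before}, \code{enriched_after_pure},
#'   \code{dropout_pure}, \code{dropout_random} (vector),
#'   \code{dropout_induced} (vector or NULL), \code{p_vs_random},
#'   \code{p_vs_induced} and \code{pure_only_terms} (terms that drop only
#'   under pure removal and under none of the random draws).
#' @export
dropout_analysis <- function(network_links, removal_pure, removal_induced,
                             annotations, gene_universe, n_random = 20L,
                             n_null = 499L, fdr = 0.01, seed = 1L) {
  keys <- pair_key(network_links$gene_a, network_links$gene_b)
  for (nm in list(pure = removal_pure, induced = removal_induced)) {
    if (nrow(nm) > 0L && !all(pair_key(nm$gene_a, nm$gene_b) %in% keys))
      stop_fatal("removal set contains links outside the network")
  }
  run <- function(links, s) {
    res <- enrich_terms(links, annotations, gene_universe, n_null = n_null,
                        fdr = fdr, seed = s)
    res$term[res$fdr_pass]
  }
  before <- run(network_links, seed)
  after_pure <- run(remove_links(network_links, removal_pure), seed)
  size <- nrow(removal_pure)
  dropout <- function(after) length(setdiff(before, after))
  d_pure <- dropout(after_pure)
  random_draws <- with_seed(child_seed(seed, "dropout_random"), function() {
    lapply(seq_len(n_random), function(r)
      network_links[sample.int(nrow(network_links),
                               min(size, nrow(network_links))), ,
                    drop = FALSE])
  })
  after_random <- lapply(random_draws,
                         function(rm) run(remove_links(network_links, rm),
                                          seed))
  d_random <- vapply(after_random, dropout, 0L)
  d_induced <- NULL
  p_induced <- NA_real_
  if (nrow(removal_induced) > 0L) {
    induced_draws <- with_seed(child_seed(seed, "dropout_induced"),
                               function() {
      lapply(seq_len(n_random), function(r)
        removal_induced[sample.int(nrow(removal_induced),
                                   min(size, nrow(removal_induced))), ,
                        drop = FALSE])
    })
    d_induced <- vapply(induced_draws, function(rm)
      dropout(run(remove_links(network_links, rm), seed)), 0L)
    p_induced <- (1 + sum(d_induced <= d_pure)) / (1 + length(d_induced))
  }
  p_random <- (1 + sum(d_random <= d_pure)) / (1 + length(d_random))
  dropped_pure <- setdiff(before, after_pure)
  dropped_any_random <- unique(unlist(lapply(after_random,
                                             function(a) setdiff(before, a))))
  structure(list(enriched_before = before,
                 enriched_after_pure = after_pure,
                 dropout_pure = d_pure, dropout_random = d_random,
                 dropout_induced = d_induced,
                 p_vs_random = p_random, p_vs_induced = p_induced,
                 pure_only_terms = setdiff(dropped_pure,
                                           dropped_any_random)),
            class = "dropout_result")
}

#' @export
print.dropout_result <- function(x, ...) {
  cat(sprintf("<dropout_result> %d terms enriched; pure removal drops %d\n",
              length(x$enriched_before), x$dropout_pure))
  cat(sprintf("  random removals drop %.1f on average (p pure<=random: %.3f)\n",
              mean(x$dropout_random), x$p_vs_random))
  if (!is.null(x$dropout_induced))
    cat(sprintf("  induced removals drop %.1f on average (p: %.3f)\n",
                mean(x$dropout_induced), x$p_vs_induced))
  if (length(x$pure_only_terms))
    cat("  sensitive only to pure removal:",
        paste(x$pure_only_terms, collapse = ", "), "\n")
  invisible(x)
}

#' Terms enriched exclusively in one tissue
#'
#' @param tsn_results Named list (tissue -> \code{\link{enrich_terms}}
#'   data.frame) computed on a common term collection.
#' @return Named list: tissue -> character vector of terms enriched in that
#'   tissue's network and in no other.
#' @export
exclusive_enrichment <- function(tsn_results) {
  enriched <- lapply(tsn_results, function(r) r$term[r$fdr_pass])
  out <- lapply(names(enriched), function(t) {
    others <- unique(unlist(enriched[setdiff(names(enriched), t)],
                            use.names = FALSE))
    setdiff(enriched[[t]], others)
  })
  names(out) <- names(enriched)
  out
}
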