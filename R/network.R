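# Per-dataset correlation networks, binarization at a percentile cutoff, and
# aggregation into tissue-aggregated networks (TANs) against a binomial null.

#' Harmonize datasets to a common gene universe
#'
#' Restricts every dataset to the intersection of gene sets across all
#' datasets, reindexed to sorted gene IDs. Genes present in only some
#' datasets cannot be compared across tissues, so the pipeline operates on
#' the shared universe.
#'
#' @param datasets List of \code{\link{expression_dataset}} objects (>= 2).
#' @return List with \code{gene_universe} (sorted character vector) and
#'   \code{datasets} (the restricted datasets).
#' @export
harmonize_genes <- function(datasets) {
  stopifnot(length(datasets) >= 2L)
  universe <- Reduce(intersect, lapply(datasets, `[[`, "gene_ids"))
  if (length(universe) == 0L)
    stop_fatal("no genes shared by all %d datasets", length(datasets))
  universe <- sort(universe)
  restricted <- lapply(datasets, function(d) {
    expression_dataset(d$dataset_id, d$tissue,
                       d$matrix[universe, , drop = FALSE])
  })
  names(restricted) <- vapply(restricted, `[[`, "", "dataset_id")
  list(gene_universe = universe, datasets = restricted)
}

#' Mark expressed genes for one tissue
#'
#' Expression data are bimodal on the log scale: an expressed and a
#' not-expressed population. The default method fits a 2-component Gaussian
#' mixture to the tissue-wide per-gene mean log-expression (the mean across
#' the tissue's datasets of each dataset's per-gene mean) and marks genes
#' with posterior >= 0.5 for the higher-mean component as expressed. A fixed
#' threshold on the mean is available as an alternative. If the mixture fit
#' is degenerate (component means separated by less than two pooled
#' within-component SDs, i.e. the components overlap so much that no
#' bimodality is resolved — the unimodal case), the function falls back to
#' a fixed threshold at the distribution median, with a warning.
#'
#' @param datasets List of harmonized \code{\link{expression_dataset}}
#'   objects, all from one tissue.
#' @param method \code{"gmm2"} or \code{"fixed"}.
#' @param threshold Numeric threshold (required for \code{"fixed"}).
#' @return Character vector of expressed gene IDs, with attributes
#'   \code{threshold} (the implied split point) and \code{method}.
#' @importFrom mclust Mclust mclustBIC
#' @export
mark_expressed <- function(datasets, method = c("gmm2", "fixed"),
                           threshold = NULL) {
  method <- match.arg(method)
  stopifnot(length(datasets) >= 1L)
  means <- rowMeans(vapply(datasets, `[[`,
                           numeric(length(datasets[[1L]]$gene_ids)),
                           "mean_expression"))
  genes <- datasets[[1L]]$gene_ids
  if (method == "gmm2") {
    fit <- tryCatch(
      mclust::Mclust(means, G = 2, modelNames = "V", verbose = FALSE),
      error = function(e) NULL)
    degenerate <- is.null(fit) ||
      abs(diff(fit$parameters$mean)) <
        2 * sqrt(mean(fit$parameters$variance$sigmasq))
    if (degenerate) {
      warning("degenerate 2-component mixture; falling back to the median ",
              "as a fixed expression threshold")
      method <- "fixed"
      threshold <- stats::median(means)
    } else {
      hi <- which.max(fit$parameters$mean)
      expressed <- genes[fit$z[, hi] >= 0.5]
      # implied split point: midpoint between the extremes of the two calls
      split <- mean(c(max(means[fit$z[, hi] < 0.5], -Inf),
                      min(means[fit$z[, hi] >= 0.5], Inf)))
      return(structure(expressed, threshold = split, method = "gmm2"))
    }
  }
  if (is.null(threshold))
    stop_fatal("method 'fixed' requires a threshold")
  structure(genes[means > threshold], threshold = threshold,
            method = "fixed")
}

#' Per-dataset Pearson correlation network
#'
#' Computes the Pearson correlation for every unordered pair of expressed
#' genes in one dataset (the raw coexpression matrix). Self-pairs are
#' excluded. Pairs involving a zero-variance gene get correlation 0 and the
#' gene is flagged, rather than propagating NaN.
#'
#' @param dataset An \code{\link{expression_dataset}}.
#' @param expressed Character vector of genes expressed in the dataset's
#'   tissue.
#' @return Object of class \code{"correlation_entry"}: list with
#'   \code{dataset_id}, \code{tissue}, \code{genes}, \code{corr} (symmetric
#'   matrix, diagonal NA) and \code{zero_var} (logical per gene).
#' @export
correlation_network <- function(dataset, expressed) {
  genes <- intersect(dataset$gene_ids, expressed)
  if (length(genes) < 2L)
    stop_fatal("dataset '%s': fewer than 2 expressed genes",
               dataset$dataset_id)
  m <- dataset$matrix[genes, , drop = FALSE]
  if (ncol(m) < 3L)
    stop_fatal("dataset '%s' has fewer than 3 samples", dataset$dataset_id)
  sds <- apply(m, 1L, stats::sd)
  zero_var <- sds == 0 | !is.finite(sds)
  cc <- suppressWarnings(stats::cor(t(m)))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- NA_real_
  structure(list(dataset_id = dataset$dataset_id, tissue = dataset$tissue,
                 genes = genes, corr = cc, zero_var = zero_var),
            class = "correlation_entry")
}

#' Binarize a correlation network at a percentile cutoff
#'
#' Keeps the gene pairs whose correlation is strictly greater than the
#' empirical percentile of all eligible pair correlations in the dataset.
#' The cutoff is the ceiling(p * n)-th order statistic; ties at the cutoff
#' are excluded by the strict inequality.
#'
#' @param entry A \code{\link{correlation_network}} result.
#' @param percentile Fraction in (0,1), e.g. 0.90.
#' @return Object of class \code{"binary_network"}: list with
#'   \code{dataset_id}, \code{genes}, \code{adjacency} (logical symmetric
#'   matrix), \code{cutoff} and \code{n_links}.
#' @export
binarize <- function(entry, percentile = 0.90) {
  stopifnot(inherits(entry, "correlation_entry"),
            percentile > 0, percentile < 1)
  v <- ut_vec(entry$corr)
  if (length(v) == 0L) stop_fatal("empty correlation store entry")
  cutoff <- sort(v)[ceiling(percentile * length(v))]
  adj <- entry$corr > cutoff
  adj[is.na(adj)] <- FALSE
  structure(list(dataset_id = entry$dataset_id, genes = entry$genes,
                 adjacency = adj, cutoff = cutoff,
                 n_links = sum(ut_vec(adj))),
            class = "binary_network")
}

#' Minimum support for TAN aggregation under a binomial null
#'
#' A link spurious in every dataset appears in each binary network
#' independently with probability \code{keep_fraction}, so its support count
#' across \code{n_datasets} networks is Binomial(n_datasets, keep_fraction).
#' The aggregation threshold is the smallest support n meeting the FDR
#' criterion. With observed support counts (\code{support_tab}), the
#' empirical-FDR criterion is
#' \code{n_pairs * P(X >= n) / (#links with support >= n) <= fdr}; a support
#' level with no observed links also qualifies (no discoveries means the FDR
#' is trivially controlled and the TAN is empty). Without observed counts
#' (planning mode) the conservative pure-tail criterion
#' \code{P(X >= n) <= fdr} is used.
#'
#' @param n_datasets Number of binary networks for the tissue.
#' @param keep_fraction Fraction of pairs kept per network (1 - percentile).
#' @param n_pairs Number of eligible gene pairs.
#' @param fdr Target FDR (e.g. 1e-4).
#' @param support_tab Optional integer vector of observed per-link support
#'   counts (only links with support >= 1 need be included).
#' @return The smallest integer n meeting the criterion.
#' @export
aggregation_threshold <- function(n_datasets, keep_fraction, n_pairs, fdr,
                                  support_tab = NULL) {
  stopifnot(n_datasets >= 1L, keep_fraction > 0, keep_fraction < 1)
  tail_p <- function(n) stats::pbinom(n - 1L, n_datasets, keep_fraction,
                                      lower.tail = FALSE)
  for (n in seq_len(n_datasets)) {
    crit <- if (is.null(support_tab)) {
      tail_p(n) <= fdr
    } else {
      observed <- sum(support_tab >= n)
      observed == 0L || n_pairs * tail_p(n) / observed <= fdr
    }
    if (crit) return(n)
  }
  stop_fatal(paste0("no support threshold <= %d datasets achieves FDR %g ",
                    "(try a looser fdr)"), n_datasets, fdr)
}

#' Build a tissue-aggregated network (TAN)
#'
#' Counts, for every gene pair, in how many of the tissue's binary networks
#' the link is present, and keeps links with support >= n.
#'
#' @param binary_networks List of \code{\link{binarize}} results for one
#'   tissue, sharing a gene universe.
#' @param n Minimum support (from \code{\link{aggregation_threshold}}).
#' @param tissue Tissue label.
#' @return Object of class \code{"tan"}: list with \code{tissue},
#'   \code{genes}, \code{n_datasets}, \code{min_support}, \code{support}
#'   (symmetric integer matrix), \code{links} (data.frame \code{gene_a},
#'   \code{gene_b}, \code{support}, canonical order) and \code{cutoffs}
#'   (per-dataset binarization cutoffs).
#' @export
build_tan <- function(binary_networks, n, tissue) {
  stopifnot(length(binary_networks) >= 1L)
  genes <- binary_networks[[1L]]$genes
  for (bn in binary_networks)
    if (!identical(bn$genes, genes))
      stop_fatal("binary networks do not share a gene universe")
  support <- Reduce(`+`, lapply(binary_networks,
                                function(bn) 1L * bn$adjacency))
  keep <- which(upper.tri(support) & support >= n, arr.ind = TRUE)
  links <- canonical_pairs(genes[keep[, 1L]], genes[keep[, 2L]])
  links$support <- support[keep]
  links <- links[order(links$gene_a, links$gene_b), , drop = FALSE]
  rownames(links) <- NULL
  cutoffs <- vapply(binary_networks, `[[`, 0.0, "cutoff")
  names(cutoffs) <- vapply(binary_networks, `[[`, "", "dataset_id")
  structure(list(tissue = tissue, genes = genes,
                 n_datasets = length(binary_networks),
                 min_support = as.integer(n), support = support,
                 links = links, cutoffs = cutoffs),
            class = "tan")
}

#' @export
print.tan <- function(x, ...) {
  cat(sprintf("<tan '%s'> %d genes, %d datasets, min support %d, %d links\n",
              x$tissue, length(x$genes), x$n_datasets, x$min_support,
              nrow(x$links)))
  invisible(x)
}

#' Write a TAN to disk
#'
#' Writes the link TSV (io dialect) plus a JSON sidecar with tissue,
#' dataset count, minimum support and per-dataset cutoffs.
#'
#' @param tan A \code{\link{build_tan}} result.
#' @param path Output path for the link TSV; the sidecar gets
#'   \code{<path>.json}.
#' @export
write_tan <- function(tan, path) {
  links <- tan$links
  links$tissue <- tan$tissue
  write_linkset(links, path)
  jsonlite::write_json(
    list(tissue = tan$tissue, n_datasets = tan$n_datasets,
         min_support = tan$min_support,
         cutoffs = as.list(tan$cutoffs)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
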