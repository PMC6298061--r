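# Reproducibility of link groups (TAN / TSN / pure) in an external
# expression cohort: density-matched binary networks, overlap likelihood
# ratios, correlation-distribution comparisons and neighborhood topological
# overlap.

#' Density-matched binarization of an external dataset
#'
#' Thresholds the external dataset's correlations so that its binary network
#' has the same density, on the shared gene universe, as the reference TAN.
#' The cutoff is the value just below the m-th largest shared-pair
#' correlation (m = reference link count on shared pairs), with strict ">",
#' so the external link count equals the reference count up to ties.
#'
#' @param external A \code{\link{correlation_network}} entry for the
#'   external dataset.
#' @param reference_tan A \code{\link{build_tan}} result.
#' @param min_overlap Minimum shared-gene count (default 100); below this
#'   the comparison is not meaningful and the function stops.
#' @return Object of class \code{"external_network"}: list with
#'   \code{tissue}, \code{genes} (shared universe), \code{adjacency},
#'   \code{cutoff}, \code{density} and \code{reference_density}.
#' @export
match_density_binarize <- function(external, reference_tan,
                                   min_overlap = 100L) {
  stopifnot(inherits(external, "correlation_entry"),
            inherits(reference_tan, "tan"))
  shared <- intersect(external$genes, reference_tan$genes)
  if (length(shared) < min_overlap)
    stop_fatal("only %d genes shared with the TAN universe (need >= %d)",
               length(shared), min_overlap)
  shared <- sort(shared)
  n_pairs <- choose(length(shared), 2)
  ref_links <- reference_tan$links
  m <- sum(ref_links$gene_a %in% shared & ref_links$gene_b %in% shared)
  cc <- external$corr[shared, shared]
  v <- ut_vec(cc)
  if (m == 0L) {
    cutoff <- Inf
  } else {
    sorted <- sort(v, decreasing = TRUE)
    cutoff <- if (m >= length(sorted)) -Inf else sorted[m + 1L]
  }
  adj <- cc > cutoff
  adj[is.na(adj)] <- FALSE
  structure(list(tissue = external$tissue, genes = shared, adjacency = adj,
                 cutoff = cutoff, density = sum(ut_vec(adj)) / n_pairs,
                 reference_density = m / n_pairs),
            class = "external_network")
}

# restrict a link data.frame to pairs fully inside a gene set; returns
# matching row indices into the external adjacency
shared_link_index <- function(links, genes) {
  i <- match(links$gene_a, genes)
  j <- match(links$gene_b, genes)
  ok <- !is.na(i) & !is.na(j)
  cbind(i[ok], j[ok])
}

#' Overlap likelihood ratio of a link group in an external network
#'
#' LR = observed count of group links present in the external binary network
#' divided by the count expected by chance (group size on the shared
#' universe times the external network density). LR > 1 means the group's
#' links recur in the external cohort more often than random pairs do.
#'
#' @param link_group Data.frame with \code{gene_a}, \code{gene_b}.
#' @param external_binary A \code{\link{match_density_binarize}} result.
#' @return A single likelihood ratio, or NA when the group is empty on the
#'   shared universe.
#' @export
overlap_likelihood_ratio <- function(link_group, external_binary) {
  idx <- shared_link_index(link_group, external_binary$genes)
  if (nrow(idx) == 0L) return(NA_real_)
  observed <- sum(external_binary$adjacency[idx])
  expected <- nrow(idx) * external_binary$density
  if (expected == 0) return(NA_real_)
  observed / expected
}

#' Fraction of a link group reproduced in an external network
#'
#' The fraction of the group's links (restricted to the shared gene
#' universe) present in the density-matched external binary network.
#'
#' @inheritParams overlap_likelihood_ratio
#' @return Fraction in [0,1], or NA for an empty group.
#' @export
reproduced_fraction <- function(link_group, external_binary) {
  idx <- shared_link_index(link_group, external_binary$genes)
  if (nrow(idx) == 0L) return(NA_real_)
  mean(external_binary$adjacency[idx])
}

#' External correlation distributions of link groups
#'
#' Summarizes, for each link group, the distribution of its links' raw
#' correlations in the external dataset against the all-shared-pairs null:
#' quantiles (5, 25, 50, 75, 95 percent) and a one-sided rank-sum p-value
#' for group > null.
#'
#' @param link_groups Named list of link data.frames.
#' @param external A \code{\link{correlation_network}} entry for the
#'   external dataset.
#' @param universe Optional character vector restricting the shared
#'   universe; defaults to the external entry's genes.
#' @return List with \code{null_quantiles} and \code{groups} (data.frame
#'   with one row per group: n, q05..q95, p_greater).
#' @export
group_correlation_distributions <- function(link_groups, external,
                                            universe = NULL) {
  stopifnot(inherits(external, "correlation_entry"))
  genes <- if (is.null(universe)) external$genes
           else intersect(external$genes, universe)
  cc <- external$corr[genes, genes]
  all_vals <- ut_vec(cc)
  probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  qn <- function(v) stats::quantile(v, probs, names = FALSE, na.rm = TRUE)
  rows <- lapply(names(link_groups), function(g) {
    idx <- shared_link_index(link_groups[[g]], genes)
    if (nrow(idx) == 0L)
      return(data.frame(group = g, n = 0L, q05 = NA, q25 = NA, q50 = NA,
                        q75 = NA, q95 = NA, p_greater = NA))
    vals <- cc[idx]
    q <- qn(vals)
    p <- suppressWarnings(
      stats::wilcox.test(vals, all_vals, alternative = "greater",
                         exact = FALSE)$p.value)
    data.frame(group = g, n = nrow(idx), q05 = q[1], q25 = q[2], q50 = q[3],
               q75 = q[4], q95 = q[5], p_greater = p)
  })
  list(null_quantiles = stats::setNames(qn(all_vals),
                                        sprintf("q%02d", probs * 100)),
       groups = do.call(rbind, rows))
}

#' Neighborhood topological overlap of a link across tissues
#'
#' For each TAN, the topological overlap of the pair (a, b) is
#' |N(a) intersect N(b)| / min(|N(a)|, |N(b)|), over the TAN neighborhoods
#' excluding a and b themselves; 0 when either neighborhood is empty, NA
#' when either gene is absent from the TAN's universe. Pure
#' differential-coexpression links are expected to show higher overlap in
#' their target tissue.
#'
#' @param gene_a,gene_b The link's genes.
#' @param tans Named list of \code{\link{build_tan}} results (name = tissue).
#' @return Named numeric vector, one value per TAN.
#' @export
topological_overlap <- function(gene_a, gene_b, tans) {
  vapply(tans, function(tan) {
    if (!(gene_a %in% tan$genes && gene_b %in% tan$genes))
      return(NA_real_)
    lk <- tan$links
    nb <- function(g) {
      setdiff(unique(c(lk$gene_b[lk$gene_a == g], lk$gene_a[lk$gene_b == g])),
              c(gene_a, gene_b))
    }
    na <- nb(gene_a)
    nbg <- nb(gene_b)
    if (length(na) == 0L || length(nbg) == 0L) return(0)
    length(intersect(na, nbg)) / min(length(na), length(nbg))
  }, 0.0)
}
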