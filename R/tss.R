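# The binned rank transform, the tissue-specificity score (TSS), the
# Wilcoxon alternative, pseudo-tissue nulls and TSS-FDR selection.
#
# Raw Pearson correlations are not comparable across datasets (sample sizes
# and global correlation structure differ), so each correlation is replaced
# by its quantile bin among all expressed-pair correlations of its dataset.
# Negative correlations carry no evidence of coexpression and would act as
# outliers, so they are pinned to the middle bin (0.5, approximately zero
# correlation). The TSS of a link for a target tissue is the mean positive
# difference between its binned values in target-tissue datasets and those
# in all other datasets; it lives on [0, 0.5].

#' Binned rank transform of a correlation store
#'
#' For each dataset, each pair's correlation is replaced by its quantile bin
#' among all eligible pair correlations of that dataset: bin =
#' ceiling(quantile * n_bins) / n_bins, on the scale (0, 1]. Non-negative
#' correlations are floored at 0.5; negative correlations are assigned
#' exactly 0.5. With \code{n_bins = 1000} the bins are per-milles (bin 500 =
#' 0.5).
#'
#' @param store A \code{correlation_entry} or list of them.
#' @param n_bins Number of quantile bins (>= 2). Default 1000.
#' @return The input with an \code{sb} matrix (same shape as \code{corr})
#'   added to each entry.
#' @export
bin_transform <- function(store, n_bins = 1000L) {
  if (inherits(store, "correlation_entry"))
    return(bin_transform_entry(store, n_bins))
  lapply(store, bin_transform_entry, n_bins = n_bins)
}

bin_transform_entry <- function(entry, n_bins) {
  stopifnot(inherits(entry, "correlation_entry"), n_bins >= 2L)
  v <- ut_vec(entry$corr)
  q <- rank(v, ties.method = "max") / length(v)
  bin <- ceiling(q * n_bins) / n_bins
  sbv <- ifelse(v < 0, 0.5, pmax(bin, 0.5))
  sb <- entry$corr
  sb[upper.tri(sb)] <- sbv
  sb[lower.tri(sb)] <- t(sb)[lower.tri(sb)]
  diag(sb) <- NA_real_
  entry$sb <- sb
  entry$n_bins <- as.integer(n_bins)
  entry
}

#' Binned correlations of a set of links across all datasets
#'
#' Builds the links x datasets matrix of binned correlation values used by
#' the TSS and the expression model. A link is not evaluable in a dataset
#' when either gene is not expressed in that dataset's tissue (and hence
#' absent from its correlation pool); such cells get the no-coexpression
#' floor 0.5.
#'
#' @param store List of \code{bin_transform}ed correlation entries.
#' @param links Data.frame with columns \code{gene_a}, \code{gene_b}.
#' @return Numeric matrix, rows = links, columns = datasets (named by
#'   dataset_id), with attribute \code{"evaluable"} (logical matrix of the
#'   same shape).
#' @export
sb_for_links <- function(store, links) {
  n_links <- nrow(links)
  ids <- vapply(store, `[[`, "", "dataset_id")
  sb <- matrix(0.5, n_links, length(store), dimnames = list(NULL, ids))
  ev <- matrix(FALSE, n_links, length(store), dimnames = list(NULL, ids))
  for (d in seq_along(store)) {
    entry <- store[[d]]
    if (is.null(entry$sb))
      stop_fatal("store entry '%s' has no binned values; run bin_transform",
                 entry$dataset_id)
    i <- match(links$gene_a, entry$genes)
    j <- match(links$gene_b, entry$genes)
    ok <- !is.na(i) & !is.na(j)
    sb[ok, d] <- entry$sb[cbind(i[ok], j[ok])]
    ev[ok, d] <- TRUE
  }
  attr(sb, "evaluable") <- ev
  sb
}

#' Tissue-specificity score (TSS)
#'
#' TSS(link, t) = mean over all (p, q) pairs of datasets, p from the target
#' tissue and q from the rest, of the positive part of SB_p - SB_q. A link
#' whose binned correlation is consistently at the top in the target tissue
#' and at the floor elsewhere reaches the maximum 0.5; identical binned
#' values everywhere give 0.
#'
#' @param sb Numeric matrix (links x datasets) from
#'   \code{\link{sb_for_links}}, or a single link's numeric vector.
#' @param dataset_tissues Character vector of tissue labels, one per dataset
#'   column.
#' @param target Target tissue label, or an integer vector of target dataset
#'   columns (used for pseudo-tissues).
#' @return Numeric vector of TSS values in [0, 0.5], one per link.
#' @export
tss_score <- function(sb, dataset_tissues, target) {
  if (is.null(dim(sb))) sb <- matrix(sb, nrow = 1L)
  if (is.character(target)) {
    t_idx <- which(dataset_tissues == target)
    if (length(t_idx) == 0L)
      stop_fatal("no datasets for target tissue '%s'", target)
  } else {
    t_idx <- as.integer(target)
  }
  o_idx <- setdiff(seq_len(ncol(sb)), t_idx)
  if (length(o_idx) == 0L)
    stop_fatal("no non-target datasets to compare against")
  acc <- numeric(nrow(sb))
  for (p in t_idx)
    for (q in o_idx)
      acc <- acc + pmax(sb[, p] - sb[, q], 0)
  acc / (length(t_idx) * length(o_idx))
}

#' Wilcoxon rank-sum alternative to the TSS
#'
#' One-sided rank-sum p-value for the hypothesis that a link's binned
#' correlations in the target tissue are larger than in all other tissues.
#' The exact distribution is used for combined n <= 20 without ties; the
#' normal approximation with tie correction otherwise. With fewer than 2
#' datasets on either side there is no meaningful test and p = 1 is returned
#' with a warning attribute.
#'
#' @inheritParams tss_score
#' @return Numeric vector of p-values, one per link, with attribute
#'   \code{"underpowered"} = TRUE when a side had < 2 datasets.
#' @export
tss_wilcoxon <- function(sb, dataset_tissues, target) {
  if (is.null(dim(sb))) sb <- matrix(sb, nrow = 1L)
  t_idx <- if (is.character(target)) which(dataset_tissues == target)
           else as.integer(target)
  o_idx <- setdiff(seq_len(ncol(sb)), t_idx)
  if (length(t_idx) < 2L || length(o_idx) < 2L) {
    p <- rep(1, nrow(sb))
    attr(p, "underpowered") <- TRUE
    return(p)
  }
  n_comb <- length(t_idx) + length(o_idx)
  p <- vapply(seq_len(nrow(sb)), function(l) {
    x <- sb[l, t_idx]
    y <- sb[l, o_idx]
    exact <- n_comb <= 20L && !anyDuplicated(c(x, y))
    suppressWarnings(
      stats::wilcox.test(x, y, alternative = "greater",
                         exact = exact, correct = TRUE)$p.value)
  }, 0.0)
  attr(p, "underpowered") <- FALSE
  p
}

#' Draw tissue-balanced pseudo-tissues
#'
#' A pseudo-tissue is a random subset of dataset IDs with the same size as
#' the tissue it mirrors, stratified so that every real tissue contributes a
#' floor-or-ceiling share of size/T datasets (remainders assigned to tissues
#' chosen uniformly at random). Pseudo-tissue TSS distributions form the
#' null for the TSS FDR.
#'
#' @param dataset_tissues Named character vector: dataset_id -> tissue.
#' @param mirror_tissue Tissue whose dataset count the pseudo-tissues copy.
#' @param n_pseudo Number of independent draws.
#' @param seed Integer seed.
#' @return List of length \code{n_pseudo}; each element a list with
#'   \code{id} and \code{dataset_ids}.
#' @export
make_pseudo_tissues <- function(dataset_tissues, mirror_tissue,
                                n_pseudo = 30L, seed = 1L) {
  stopifnot(!is.null(names(dataset_tissues)))
  tissues <- unique(dataset_tissues)
  size <- sum(dataset_tissues == mirror_tissue)
  if (size < 1L)
    stop_fatal("mirror tissue '%s' has no datasets", mirror_tissue)
  if (size > length(dataset_tissues))
    stop_fatal("pseudo-tissue size exceeds the number of datasets")
  by_tissue <- split(names(dataset_tissues), dataset_tissues)
  n_t <- length(tissues)
  base <- size %/% n_t
  rem <- size %% n_t
  with_seed(child_seed(seed, paste0("pseudo_", mirror_tissue)), function() {
    lapply(seq_len(n_pseudo), function(i) {
      quota <- stats::setNames(rep(base, n_t), tissues)
      if (rem > 0L) {
        extra <- sample(tissues, rem)
        quota[extra] <- quota[extra] + 1L
      }
      avail <- vapply(by_tissue[tissues], length, 0L)
      short <- pmax(quota - avail, 0L)
      if (any(short > 0L)) {
        warning(sprintf(
          "pseudo-tissue for '%s': %d dataset(s) reallocated across tissues",
          mirror_tissue, sum(short)))
        quota <- pmin(quota, avail)
        spare <- avail - quota
        for (k in seq_len(sum(short))) {
          cand <- names(spare)[spare > 0L]
          pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
          quota[pick] <- quota[pick] + 1L
          spare[pick] <- spare[pick] - 1L
        }
      }
      ids <- unlist(lapply(tissues, function(t) {
        pool <- by_tissue[[t]]
        if (quota[[t]] == 0L) character(0)
        else if (length(pool) == 1L && quota[[t]] == 1L) pool
        else sample(pool, quota[[t]])
      }), use.names = FALSE)
      list(id = sprintf("pseudo_%s_%02d", mirror_tissue, i),
           dataset_ids = ids)
    })
  })
}

#' Empirical TSS false-discovery-rate curve
#'
#' FDR(tss) = (mean over pseudo-tissues of the count of pseudo TSS values
#' greater than tss) / (count of real TSS values greater than tss), capped
#' at 1. The raw curve can be non-monotone on finite data, so a running
#' minimum (from low tss upward) enforces monotone non-increase, making
#' thresholding well-defined. Where the denominator is 0 (at and above the
#' maximum real TSS) the FDR is defined as 0.
#'
#' @param real_tss Numeric vector of TSS values for the tissue's TAN links.
#' @param pseudo_tss List of numeric vectors (one per pseudo-tissue) on the
#'   same link universe, or a matrix with one column per pseudo-tissue.
#' @return Object of class \code{"tss_fdr_curve"}: list with \code{tss}
#'   (evaluation points), \code{fdr_raw}, \code{fdr} (smoothed) and
#'   \code{n_pseudo}.
#' @export
tss_fdr_curve <- function(real_tss, pseudo_tss) {
  if (is.matrix(pseudo_tss))
    pseudo_tss <- lapply(seq_len(ncol(pseudo_tss)),
                         function(j) pseudo_tss[, j])
  stopifnot(length(pseudo_tss) >= 1L)
  ts <- sort(unique(c(0, real_tss)))
  pseudo_all <- unlist(pseudo_tss, use.names = FALSE)
  n_pseudo <- length(pseudo_tss)
  num <- vapply(ts, function(t) sum(pseudo_all > t) / n_pseudo, 0.0)
  den <- vapply(ts, function(t) sum(real_tss > t), 0.0)
  raw <- ifelse(den == 0, 0, pmin(num / pmax(den, 1), 1))
  smoothed <- cummin(raw)
  structure(list(tss = ts, fdr_raw = raw, fdr = smoothed,
                 n_pseudo = n_pseudo),
            class = "tss_fdr_curve")
}

#' Evaluate a TSS-FDR curve
#'
#' @param curve A \code{\link{tss_fdr_curve}}.
#' @param tss Numeric vector of TSS values.
#' @return Smoothed FDR at each value (step function, right-continuous).
#' @export
fdr_at <- function(curve, tss) {
  idx <- findInterval(tss, curve$tss)
  out <- rep(1, length(tss))
  out[idx > 0L] <- curve$fdr[idx[idx > 0L]]
  out
}

#' TSS threshold achieving a target FDR
#'
#' @param curve A \code{\link{tss_fdr_curve}}.
#' @param fdr_target Target FDR.
#' @return The smallest TSS evaluation point with smoothed FDR <=
#'   \code{fdr_target}, or NA if none.
#' @export
tss_threshold <- function(curve, fdr_target) {
  ok <- which(curve$fdr <= fdr_target)
  if (length(ok) == 0L) return(NA_real_)
  curve$tss[ok[1L]]
}

#' Select tissue-specific links (TSNs)
#'
#' Per tissue, the TSS threshold is the smallest value whose smoothed FDR is
#' at or below the target; the tissue-specific network is the set of TAN
#' links with target-tissue TSS at or above the threshold AND TSS below
#' \code{other_max} in every other tissue (the cross-tissue filter removes
#' links that are "specific" to several tissues at once).
#'
#' @param tss_table Data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{tan_tissue} (the TAN the link belongs to), \code{tissue} (the
#'   tissue the TSS targets) and \code{tss}; one row per (TAN link, tissue).
#' @param fdr_curves Named list of \code{\link{tss_fdr_curve}} objects, one
#'   per tissue.
#' @param fdr_target Target TSS FDR. Default 0.01.
#' @param other_max TSS ceiling in non-target tissues. Default 0.4.
#' @return Object of class \code{"tsn_selection"}: named list per tissue
#'   with \code{threshold} and \code{links} (data.frame \code{gene_a},
#'   \code{gene_b}, \code{tss}).
#' @export
select_tsn <- function(tss_table, fdr_curves, fdr_target = 0.01,
                       other_max = 0.4) {
  tissues <- sort(unique(tss_table$tan_tissue))
  out <- lapply(tissues, function(t) {
    tab <- tss_table[tss_table$tan_tissue == t, , drop = FALSE]
    thr <- tss_threshold(fdr_curves[[t]], fdr_target)
    key <- pair_key(tab$gene_a, tab$gene_b)
    target_rows <- tab$tissue == t
    if (is.na(thr)) {
      warning(sprintf("tissue '%s': no TSS value reaches FDR %g; empty TSN",
                      t, fdr_target))
      sel_keys <- character(0)
    } else {
      pass_target <- key[target_rows][tab$tss[target_rows] >= thr]
      other_ok <- tapply(tab$tss[!target_rows], key[!target_rows],
                         function(v) all(v < other_max))
      # links with no other-tissue rows trivially pass the ceiling
      sel_keys <- pass_target[
        vapply(pass_target,
               function(k) is.na(other_ok[k]) || isTRUE(other_ok[[k]]),
               TRUE)]
    }
    sel <- tab[target_rows & key %in% sel_keys,
               c("gene_a", "gene_b", "tss"), drop = FALSE]
    rownames(sel) <- NULL
    list(threshold = thr, links = sel)
  })
  names(out) <- tissues
  class(out) <- "tsn_selection"
  out
}

#' @export
print.tsn_selection <- function(x, ...) {
  cat("<tsn_selection>\n")
  for (t in names(x))
    cat(sprintf("  %-10s threshold=%s  links=%d\n", t,
                format(x[[t]]$threshold, digits = 3), nrow(x[[t]]$links)))
  invisible(x)
}
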