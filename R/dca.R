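#' Differential coexpression analysis across tissues
#'
#' The top-level fitting function: runs the full pipeline on a harmonized
#' collection of expression datasets.
#' \enumerate{
#'   \item harmonize genes across datasets;
#'   \item mark expressed genes per tissue;
#'   \item per-dataset Pearson correlation networks on expressed genes,
#'     binned rank transform;
#'   \item per-dataset binarization at the configured percentile and
#'     aggregation into tissue-aggregated networks (TANs) with a
#'     binomial-null support threshold;
#'   \item tissue-specificity scores (TSS) of every TAN link for every
#'     tissue, pseudo-tissue nulls, TSS-FDR curves, and selection of
#'     tissue-specific links (TSNs);
#'   \item per-link expression models with shuffle nulls, and classification
#'     of TSN links into pure / expression_associated / induced_offgene.
#' }
#'
#' @param datasets List of \code{\link{expression_dataset}} objects (several
#'   datasets per tissue).
#' @param config A \code{\link{dc_config}}.
#' @param compute_wilcoxon Also compute the Wilcoxon rank-sum alternative to
#'   the TSS for each TAN link. Default TRUE.
#' @return Object of class \code{"dca"}: list with \code{config},
#'   \code{gene_universe}, \code{tissues}, \code{dataset_tissues},
#'   \code{expressed} (per-tissue gene sets), \code{store} (binned
#'   correlation entries), \code{tans}, \code{tss} (per tissue: links,
#'   tss matrix across tissues, wilcoxon_p), \code{fdr_curves}, \code{tsn}
#'   and \code{links} (the classified TSN link table).
#' @seealso \code{\link{summary.dca}}, \code{\link{as_linkset}},
#'   \code{\link{validate_external}}
#' @export
dca <- function(datasets, config = dc_config(), compute_wilcoxon = TRUE) {
  stopifnot(inherits(config, "dc_config"))
  h <- harmonize_genes(datasets)
  datasets <- h$datasets
  dataset_tissues <- vapply(datasets, `[[`, "", "tissue")
  tissues <- sort(unique(dataset_tissues))
  if (length(tissues) < 2L)
    stop_fatal("at least 2 tissues are required, got %d", length(tissues))

  expressed <- lapply(tissues, function(t)
    mark_expressed(datasets[dataset_tissues == t],
                   method = config$expressed_threshold_method,
                   threshold = config$expressed_threshold))
  names(expressed) <- tissues

  store <- lapply(datasets, function(d)
    correlation_network(d, expressed[[d$tissue]]))
  store <- bin_transform(store, config$n_bins)

  keep_fraction <- 1 - config$tan_percentile
  tans <- lapply(tissues, function(t) {
    bns <- lapply(store[dataset_tissues == t], binarize,
                  percentile = config$tan_percentile)
    support <- Reduce(`+`, lapply(bns, function(b) 1L * b$adjacency))
    support_tab <- ut_vec(support)
    support_tab <- support_tab[support_tab >= 1L]
    n_pairs <- choose(length(bns[[1L]]$genes), 2)
    n <- aggregation_threshold(
      length(bns), keep_fraction, n_pairs, config$tan_fdr,
      support_tab = if (config$tan_fdr_mode == "empirical") support_tab
                    else NULL)
    build_tan(bns, n, t)
  })
  names(tans) <- tissues

  tss <- lapply(tissues, function(t) {
    links <- tans[[t]]$links[, c("gene_a", "gene_b"), drop = FALSE]
    if (nrow(links) == 0L)
      return(list(links = links,
                  tss = matrix(numeric(0), 0L, length(tissues),
                               dimnames = list(NULL, tissues)),
                  wilcoxon_p = numeric(0)))
    sb <- sb_for_links(store, links)
    m <- vapply(tissues, function(m_t)
      tss_score(sb, dataset_tissues, m_t), numeric(nrow(links)))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L,
                                     dimnames = list(NULL, tissues))
    wp <- if (compute_wilcoxon) tss_wilcoxon(sb, dataset_tissues, t)
          else rep(NA_real_, nrow(links))
    list(links = links, tss = m, wilcoxon_p = as.numeric(wp), sb = sb)
  })
  names(tss) <- tissues

  fdr_curves <- lapply(tissues, function(t) {
    if (nrow(tss[[t]]$links) == 0L)
      return(tss_fdr_curve(0, list(0)))
    pseudos <- make_pseudo_tissues(dataset_tissues, t, config$n_pseudo,
                                   seed = config$rng_seed)
    sb <- tss[[t]]$sb
    pseudo_tss <- lapply(pseudos, function(pt)
      tss_score(sb, dataset_tissues,
                which(names(dataset_tissues) %in% pt$dataset_ids)))
    tss_fdr_curve(tss[[t]]$tss[, t], pseudo_tss)
  })
  names(fdr_curves) <- tissues

  tss_table <- do.call(rbind, lapply(tissues, function(t) {
    lk <- tss[[t]]$links
    if (nrow(lk) == 0L) return(NULL)
    do.call(rbind, lapply(tissues, function(m_t)
      data.frame(gene_a = lk$gene_a, gene_b = lk$gene_b, tan_tissue = t,
                 tissue = m_t, tss = tss[[t]]$tss[, m_t],
                 stringsAsFactors = FALSE)))
  }))
  tsn <- select_tsn(tss_table, fdr_curves, config$tss_fdr,
                    config$tss_other_max)

  fit_rows <- do.call(rbind, lapply(tissues, function(t) {
    sel <- tsn[[t]]$links
    if (is.null(sel) || nrow(sel) == 0L) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(sel)), function(r) {
      fit <- suppressWarnings(
        fit_link_model(sel$gene_a[r], sel$gene_b[r], store, datasets,
                       response = config$model_response))
      p_emp <- NA_real_
      if (fit$valid && config$n_shuffles > 0L) {
        nulls <- null_r2(fit, config$n_shuffles, seed = config$rng_seed)
        p_emp <- (1 + sum(nulls >= fit$r2)) / (1 + length(nulls))
      }
      data.frame(gene_a = fit$gene_a, gene_b = fit$gene_b, tissue = t,
                 tss = sel$tss[r], beta0 = fit$beta[["beta0"]],
                 beta1 = fit$beta[["beta1"]], beta2 = fit$beta[["beta2"]],
                 r2 = fit$r2, n_obs = fit$n_obs, valid = fit$valid,
                 p_emp = p_emp, stringsAsFactors = FALSE)
    }))
  }))
  links <- if (is.null(fit_rows)) NULL
           else classify_links(fit_rows, expressed, config$r2_fdr)

  structure(list(config = config, gene_universe = h$gene_universe,
                 tissues = tissues, dataset_tissues = dataset_tissues,
                 expressed = expressed, store = store, tans = tans,
                 tss = tss, fdr_curves = fdr_curves, tsn = tsn,
                 links = links, datasets = datasets),
            class = "dca")
}

#' @export
print.dca <- function(x, ...) {
  cat(sprintf("<dca> %d tissues, %d datasets, %d genes in universe\n",
              length(x$tissues), length(x$dataset_tissues),
              length(x$gene_universe)))
  print(summary(x))
  invisible(x)
}

#' Summarize a differential coexpression analysis
#'
#' @param object A \code{\link{dca}} fit.
#' @param ... Unused.
#' @return Data.frame with one row per tissue: datasets, expressed genes,
#'   TAN support threshold and link count, TSS threshold, TSN size, and the
#'   pure / expression_associated / induced_offgene class counts.
#' @export
summary.dca <- function(object, ...) {
  rows <- lapply(object$tissues, function(t) {
    tan <- object$tans[[t]]
    sel <- object$tsn[[t]]
    lk <- object$links
    cls <- if (is.null(lk)) character(0) else lk$link_class[lk$tissue == t]
    data.frame(
      tissue = t,
      n_datasets = sum(object$dataset_tissues == t),
      n_expressed = length(object$expressed[[t]]),
      tan_min_support = tan$min_support,
      tan_links = nrow(tan$links),
      tss_threshold = sel$threshold,
      tsn_links = nrow(sel$links),
      pure = sum(cls == "pure"),
      expression_associated = sum(cls == "expression_associated"),
      induced_offgene = sum(cls == "induced_offgene"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot TSS distributions against the pseudo-tissue null
#'
#' Draws, per tissue, the density of TAN-link TSS values (solid) over the
#' pooled pseudo-tissue null TSS density (shaded), with the selected TSS
#' threshold as a vertical line. A diagnostic view of the separation the
#' FDR thresholding acts on.
#'
#' @param x A \code{\link{dca}} fit.
#' @param tissues Tissues to plot (default all).
#' @param ... Passed to \code{plot}.
#' @export
plot.dca <- function(x, tissues = x$tissues, ...) {
  old <- graphics::par(mfrow = c(1, length(tissues)))
  on.exit(graphics::par(old))
  for (t in tissues) {
    real <- x$tss[[t]]$tss[, t]
    if (length(real) < 2L) {
      graphics::plot.new()
      graphics::title(main = t)
      next
    }
    curve <- x$fdr_curves[[t]]
    d_real <- stats::density(real, from = 0, to = 0.5)
    graphics::plot(d_real, main = t, xlab = "TSS", ...)
    thr <- x$tsn[[t]]$threshold
    if (!is.na(thr)) graphics::abline(v = thr, lty = 2)
  }
  invisible(x)
}

#' Export the classified link table in the canonical link-TSV layout
#'
#' @param x A \code{\link{dca}} fit.
#' @return Data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{tissue}, \code{tss}, \code{tss_fdr_pass}, \code{r2},
#'   \code{link_class}, ready for \code{\link{write_linkset}}.
#' @export
as_linkset <- function(x) {
  stopifnot(inherits(x, "dca"))
  if (is.null(x$links))
    return(data.frame(gene_a = character(), gene_b = character(),
                      tissue = character(), tss = numeric(),
                      tss_fdr_pass = logical(), r2 = numeric(),
                      link_class = character()))
  data.frame(gene_a = x$links$gene_a, gene_b = x$links$gene_b,
             tissue = x$links$tissue, tss = x$links$tss,
             tss_fdr_pass = TRUE, r2 = x$links$r2,
             link_class = x$links$link_class, stringsAsFactors = FALSE)
}

#' Reproducibility of a fit's link groups in an external cohort
#'
#' For every tissue with an external dataset, builds the external raw
#' correlation network on the shared gene universe, density-matches it to
#' the tissue's TAN, and reports for each link group (TAN, TSN, pure) the
#' overlap likelihood ratio, the reproduced fraction and the external
#' correlation-distribution summary.
#'
#' @param x A \code{\link{dca}} fit.
#' @param external_datasets List of \code{\link{expression_dataset}}
#'   objects, at most one per tissue (matched by the \code{tissue} field).
#' @param min_overlap Passed to \code{\link{match_density_binarize}}.
#' @return Object of class \code{"repro_report"}: list with \code{overlap}
#'   (data.frame: tissue, group, n_links, likelihood_ratio,
#'   reproduced_fraction) and \code{distributions} (per tissue, the
#'   \code{\link{group_correlation_distributions}} output).
#' @export
validate_external <- function(x, external_datasets, min_overlap = 100L) {
  stopifnot(inherits(x, "dca"))
  ext_tissues <- vapply(external_datasets, `[[`, "", "tissue")
  rows <- list()
  dists <- list()
  for (t in intersect(x$tissues, ext_tissues)) {
    ext <- external_datasets[[which(ext_tissues == t)[1L]]]
    tan <- x$tans[[t]]
    shared_genes <- intersect(ext$gene_ids, tan$genes)
    entry <- correlation_network(ext, shared_genes)
    bin <- match_density_binarize(entry, tan, min_overlap = min_overlap)
    groups <- list(tan = tan$links)
    sel <- x$tsn[[t]]$links
    if (!is.null(sel) && nrow(sel) > 0L) groups$tsn <- sel
    if (!is.null(x$links)) {
      pure <- x$links[x$links$tissue == t &
                      x$links$link_class == "pure", , drop = FALSE]
      if (nrow(pure) > 0L) groups$pure <- pure
    }
    for (g in names(groups)) {
      rows[[length(rows) + 1L]] <- data.frame(
        tissue = t, group = g,
        n_links = nrow(shared_link_index(groups[[g]], bin$genes)),
        likelihood_ratio = overlap_likelihood_ratio(groups[[g]], bin),
        reproduced_fraction = reproduced_fraction(groups[[g]], bin),
        stringsAsFactors = FALSE)
    }
    dists[[t]] <- group_correlation_distributions(groups, entry)
  }
  structure(list(overlap = do.call(rbind, rows), distributions = dists),
            class = "repro_report")
}

#' @export
print.repro_report <- function(x, ...) {
  cat("<repro_report>\n")
  print(x$overlap)
  invisible(x)
}
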