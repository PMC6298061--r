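# Per-link linear model of binned correlation on mean expression, the
# shuffle null for its R-squared, and classification of tissue-specific
# links into pure vs expression-associated vs expression-induced.
#
# The model for a link (i, j) across datasets k is
#   bincorr(i,j,k) = b0 + b1 * (e_ik + e_jk) + b2 * |e_ik - e_jk|
# where e_ik is gene i's mean log-expression in dataset k. b1 captures the
# predictive value of the genes' total expression, b2 of their difference;
# the fit's R-squared measures how much of the link's cross-dataset
# coexpression variation is explained by expression levels alone. The
# absolute difference keeps the model symmetric in the two genes.

ols_r2 <- function(y, s, d) {
  X <- cbind(1, s, d)
  fit <- stats::.lm.fit(X, y)
  sst <- sum((y - mean(y))^2)
  ssr <- sum(fit$residuals^2)
  r2 <- if (sst <= 0) 0 else max(0, min(1, 1 - ssr / sst))
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(beta = stats::setNames(beta, c("beta0", "beta1", "beta2")), r2 = r2)
}

#' Fit the expression model for one link
#'
#' Ordinary least squares of the link's binned correlation on the sum and
#' absolute difference of the two genes' mean expression, pooled across all
#' datasets (all tissues) where the link is evaluable — i.e. both genes are
#' expressed in the dataset's tissue, so the binned correlation is defined.
#' With fewer than 4 evaluable datasets (3 parameters + 1 df) the fit is
#' marked invalid.
#'
#' @param gene_a,gene_b Gene IDs (any order).
#' @param store List of \code{\link{bin_transform}}ed correlation entries.
#' @param datasets Named list of harmonized
#'   \code{\link{expression_dataset}} objects (same order as \code{store}).
#' @param response \code{"binned"} (default) fits the binned rank-transformed
#'   correlation; \code{"raw"} fits the raw Pearson correlation.
#' @return Object of class \code{"link_model"}: list with \code{gene_a},
#'   \code{gene_b}, \code{beta} (beta0, beta1, beta2), \code{r2},
#'   \code{n_obs}, \code{valid}, and the model frame (\code{y},
#'   \code{e_sum}, \code{e_diff}, \code{dataset_ids}).
#' @export
fit_link_model <- function(gene_a, gene_b, store, datasets,
                           response = c("binned", "raw")) {
  response <- match.arg(response)
  cp <- canonical_pairs(gene_a, gene_b)
  a <- cp$gene_a[1L]
  b <- cp$gene_b[1L]
  y <- ea <- eb <- numeric(0)
  ids <- character(0)
  for (k in seq_along(store)) {
    entry <- store[[k]]
    i <- match(a, entry$genes)
    j <- match(b, entry$genes)
    if (is.na(i) || is.na(j)) next
    d <- datasets[[entry$dataset_id]]
    y <- c(y, if (response == "binned") entry$sb[i, j] else entry$corr[i, j])
    ea <- c(ea, d$mean_expression[[a]])
    eb <- c(eb, d$mean_expression[[b]])
    ids <- c(ids, entry$dataset_id)
  }
  n_obs <- length(y)
  if (n_obs < 4L) {
    warning(sprintf("link %s|%s evaluable in only %d datasets; fit invalid",
                    a, b, n_obs))
    return(structure(list(gene_a = a, gene_b = b,
                          beta = c(beta0 = NA_real_, beta1 = NA_real_,
                                   beta2 = NA_real_),
                          r2 = NA_real_, n_obs = n_obs, valid = FALSE,
                          y = y, e_sum = ea + eb, e_diff = abs(ea - eb),
                          e_a = ea, e_b = eb, dataset_ids = ids),
                     class = "link_model"))
  }
  fit <- ols_r2(y, ea + eb, abs(ea - eb))
  structure(list(gene_a = a, gene_b = b, beta = fit$beta, r2 = fit$r2,
                 n_obs = n_obs, valid = TRUE,
                 y = y, e_sum = ea + eb, e_diff = abs(ea - eb),
                 e_a = ea, e_b = eb, dataset_ids = ids),
            class = "link_model")
}

#' @export
print.link_model <- function(x, ...) {
  cat(sprintf("<link_model %s|%s> n_obs=%d, R2=%s\n", x$gene_a, x$gene_b,
              x$n_obs,
              if (x$valid) format(x$r2, digits = 3) else "invalid"))
  if (x$valid)
    print(round(x$beta, 4))
  invisible(x)
}

#' @export
coef.link_model <- function(object, ...) object$beta

#' @export
residuals.link_model <- function(object, ...) {
  if (!object$valid) return(rep(NA_real_, object$n_obs))
  object$y - (object$beta[["beta0"]] +
              object$beta[["beta1"]] * object$e_sum +
              object$beta[["beta2"]] * object$e_diff)
}

#' Shuffle null for a link model's R-squared
#'
#' Permutes each gene's mean-expression vector independently across the
#' link's evaluable datasets and refits the model, breaking any
#' expression-correlation coupling while preserving each gene's expression
#' distribution. The resulting R-squared sample is the null against which
#' the observed R-squared is judged.
#'
#' @param model A valid \code{\link{fit_link_model}} result.
#' @param n_shuffles Number of shuffles.
#' @param seed Integer seed.
#' @return Numeric vector of \code{n_shuffles} null R-squared values.
#' @export
null_r2 <- function(model, n_shuffles, seed = 1L) {
  stopifnot(inherits(model, "link_model"))
  if (n_shuffles == 0L) return(numeric(0))
  if (!model$valid) stop_fatal("cannot build a null for an invalid fit")
  with_seed(child_seed(seed, paste0("null_r2_", model$gene_a, "_",
                                    model$gene_b)), function() {
    n <- model$n_obs
    vapply(seq_len(n_shuffles), function(s) {
      ea <- model$e_a[sample.int(n)]
      eb <- model$e_b[sample.int(n)]
      ols_r2(model$y, ea + eb, abs(ea - eb))$r2
    }, 0.0)
  })
}

#' Classify tissue-specific links
#'
#' A link's observed R-squared is compared with its shuffle null via the
#' empirical p-value (1 + #(null >= observed)) / (1 + n_shuffles);
#' Benjamini-Hochberg across all tissue-specific links at \code{r2_fdr}
#' gives \code{fdr_pass}. Classes:
#' \itemize{
#'   \item \code{induced_offgene}: at least one gene not expressed in at
#'     least one tissue (the expression-induced classes, where coexpression
#'     appears/disappears with the gene's expression state);
#'   \item \code{pure}: both genes expressed in every tissue AND the model
#'     R-squared is not significantly above its null (candidate true
#'     rewiring); links with invalid fits are never called pure;
#'   \item \code{expression_associated}: the rest (expressed everywhere but
#'     the expression model predicts the coexpression pattern).
#' }
#'
#' @param fit_table Data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{tissue}, \code{r2}, \code{valid} and \code{p_emp} (empirical
#'   p-value of the observed R-squared against its null).
#' @param expressed Named list: tissue -> character vector of expressed
#'   genes.
#' @param r2_fdr BH FDR level. Default 0.01.
#' @return The input data.frame with added columns \code{p_adj},
#'   \code{fdr_pass} and \code{link_class}.
#' @export
classify_links <- function(fit_table, expressed, r2_fdr = 0.01) {
  ft <- as.data.frame(fit_table, stringsAsFactors = FALSE)
  ft$p_adj <- stats::p.adjust(ft$p_emp, method = "BH")
  ft$fdr_pass <- !is.na(ft$p_adj) & ft$p_adj <= r2_fdr
  all_tissues <- names(expressed)
  expressed_everywhere <- vapply(seq_len(nrow(ft)), function(r) {
    all(vapply(all_tissues, function(t) {
      ft$gene_a[r] %in% expressed[[t]] && ft$gene_b[r] %in% expressed[[t]]
    }, TRUE))
  }, TRUE)
  cls <- ifelse(!expressed_everywhere, "induced_offgene",
         ifelse(ft$valid & !ft$fdr_pass, "pure", "expression_associated"))
  ft$link_class <- cls
  ft
}
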