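#' Run configuration for the differential-coexpression pipeline
#'
#' Collects the tunable constants of the analysis. The defaults reproduce the
#' published analysis settings: binary networks keep correlations above the
#' 90th percentile of each dataset; the tissue-aggregated network (TAN)
#' support threshold is chosen against a binomial null at FDR 1e-4;
#' tissue-specific links are selected at TSS FDR 0.01 with a TSS ceiling of
#' 0.4 in all other tissues; 30 pseudo-tissue sets form the TSS null; binned
#' rank transforms use 1000 bins (per-mille granularity).
#'
#' @param tan_percentile Fraction in (0,1); per-dataset binarization keeps
#'   correlations strictly above this empirical percentile. Default 0.90.
#' @param tan_fdr Target false discovery rate for TAN aggregation against the
#'   binomial null. Default 1e-4.
#' @param tan_fdr_mode \code{"empirical"} uses the observed-discovery
#'   denominator; \code{"planning"} uses the conservative pure-tail criterion
#'   P(X >= n) <= fdr (used when observed counts are unavailable).
#' @param tss_fdr Target FDR for tissue-specific link selection. Default 0.01.
#' @param tss_other_max TSS ceiling in all non-target tissues. Default 0.4.
#' @param n_pseudo Number of pseudo-tissue sets per tissue. Default 30.
#' @param n_bins Number of quantile bins for the rank transform. Default 1000.
#' @param r2_fdr FDR for calling a link's model R-squared significantly above
#'   its shuffle null. Default 0.01.
#' @param n_shuffles Number of expression shuffles for the R-squared null.
#'   Default 200.
#' @param rng_seed Integer root seed; all stochastic stages derive named child
#'   streams from it (see \code{\link{child_seed}}).
#' @param expressed_threshold_method \code{"gmm2"} (2-component Gaussian
#'   mixture on per-gene mean log-expression) or \code{"fixed"}.
#' @param expressed_threshold Numeric threshold for the \code{"fixed"} method.
#' @param model_response \code{"binned"} fits the expression model to the
#'   binned rank-transformed correlation (the default); \code{"raw"} fits the
#'   raw Pearson correlation.
#' @param enrichment_null \code{"gene_sampling"} (size-matched random gene
#'   sets) or \code{"rewire"} (degree-preserving edge rewiring).
#' @return An object of class \code{"dc_config"} (a validated list).
#' @examples
#' cfg <- dc_config(rng_seed = 1)
#' cfg$tan_percentile
#' @export
dc_config <- function(tan_percentile = 0.90,
                      tan_fdr = 1e-4,
                      tan_fdr_mode = c("empirical", "planning"),
                      tss_fdr = 0.01,
                      tss_other_max = 0.4,
                      n_pseudo = 30L,
                      n_bins = 1000L,
                      r2_fdr = 0.01,
                      n_shuffles = 200L,
                      rng_seed = 1L,
                      expressed_threshold_method = c("gmm2", "fixed"),
                      expressed_threshold = NULL,
                      model_response = c("binned", "raw"),
                      enrichment_null = c("gene_sampling", "rewire")) {
  cfg <- list(
    tan_percentile = tan_percentile,
    tan_fdr = tan_fdr,
    tan_fdr_mode = match.arg(tan_fdr_mode),
    tss_fdr = tss_fdr,
    tss_other_max = tss_other_max,
    n_pseudo = as.integer(n_pseudo),
    n_bins = as.integer(n_bins),
    r2_fdr = r2_fdr,
    n_shuffles = as.integer(n_shuffles),
    rng_seed = as.integer(rng_seed),
    expressed_threshold_method = match.arg(expressed_threshold_method),
    expressed_threshold = expressed_threshold,
    model_response = match.arg(model_response),
    enrichment_null = match.arg(enrichment_null)
  )
  validate_dc_config(cfg)
  class(cfg) <- "dc_config"
  cfg
}

validate_dc_config <- function(cfg) {
  if (!(cfg$tan_percentile > 0 && cfg$tan_percentile < 1))
    stop_fatal("tan_percentile must be in (0,1), got %g", cfg$tan_percentile)
  for (f in c("tan_fdr", "tss_fdr", "r2_fdr")) {
    v <- cfg[[f]]
    if (!(v > 0 && v <= 1))
      stop_fatal("%s must be in (0,1], got %g", f, v)
  }
  if (cfg$n_bins < 2L) stop_fatal("n_bins must be >= 2, got %d", cfg$n_bins)
  if (cfg$n_pseudo < 1L) stop_fatal("n_pseudo must be >= 1")
  if (!(cfg$tss_other_max >= 0 && cfg$tss_other_max <= 0.5))
    stop_fatal("tss_other_max must be in [0, 0.5] (the TSS scale)")
  if (cfg$expressed_threshold_method == "fixed" &&
      is.null(cfg$expressed_threshold))
    stop_fatal("expressed_threshold is required with method 'fixed'")
  invisible(cfg)
}

#' @export
print.dc_config <- function(x, ...) {
  cat("Differential-coexpression run configuration\n")
  cat(sprintf("  binarization percentile : %.2f\n", x$tan_percentile))
  cat(sprintf("  TAN aggregation FDR     : %g (%s mode)\n",
              x$tan_fdr, x$tan_fdr_mode))
  cat(sprintf("  TSS FDR / other-max     : %g / %.2f\n",
              x$tss_fdr, x$tss_other_max))
  cat(sprintf("  pseudo-tissues, bins    : %d, %d\n", x$n_pseudo, x$n_bins))
  cat(sprintf("  R2 FDR, shuffles        : %g, %d\n", x$r2_fdr, x$n_shuffles))
  cat(sprintf("  expressed-gene method   : %s\n",
              x$expressed_threshold_method))
  cat(sprintf("  rng seed                : %d\n", x$rng_seed))
  invisible(x)
}
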