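# Synthetic multi-dataset, multi-tissue expression collections with planted
# link classes, so every downstream stage has ground truth.
#
# The generator draws each dataset from a multivariate Gaussian on the log2
# scale (a Gaussian copula viewpoint: exact control over the correlation /
# mean decoupling the whole analysis rests on). Three planted link classes
# mirror the taxonomy of tissue-specific coexpression:
#   pure      - both genes highly expressed in ALL tissues, correlated only
#               in the target tissue (true rewiring);
#   induced1  - one gene expressed only in the target tissue;
#   induced2  - both genes expressed only in the target tissue.
# Constitutive coexpression modules (correlated in every tissue) populate the
# TANs with realistic non-specific links, and independent background genes
# fill out the matrix.

#' Simulation design for synthetic expression collections
#'
#' @param n_tissues Number of tissues. Default 5.
#' @param datasets_per_tissue Integer range (length-2) of datasets per tissue;
#'   the count is drawn uniformly per tissue. Default c(7, 15).
#' @param samples_per_dataset Integer range of samples per dataset, drawn
#'   uniformly per dataset. Default c(20, 120).
#' @param n_genes Total genes. Default 600.
#' @param n_planted_pure,n_planted_induced1,n_planted_induced2 Planted links
#'   per class (each link uses two dedicated genes; classes are disjoint).
#'   Defaults 20 each.
#' @param n_modules,module_size Constitutive coexpression modules (correlated
#'   at \code{rho_target} in every tissue). Defaults 5 modules of 10 genes.
#' @param rho_target Population correlation of planted links in their target
#'   tissue (and of module genes everywhere). Default 0.7.
#' @param rho_background Population correlation of all remaining pairs.
#'   Default 0.
#' @param off_mean,on_mean Log2-expression means of the not-expressed and
#'   expressed states. Defaults 4.0 and 9.0 (typical of log2 microarray
#'   intensities).
#' @param noise_sd Per-gene sampling SD in the expressed state. Default 1.0.
#' @param mean_variance_coupling In [0,1): off-state genes have their SD
#'   shrunk to \code{noise_sd * (1 - coupling)}, emulating the empirical
#'   variance-mean relationship of expression data; 0 switches the coupling
#'   off. Default 0.3.
#' @param rng_seed Integer root seed.
#' @return Object of class \code{"simulation_design"}.
#' @export
simulation_design <- function(n_tissues = 5L,
                              datasets_per_tissue = c(7L, 15L),
                              samples_per_dataset = c(20L, 120L),
                              n_genes = 600L,
                              n_planted_pure = 20L,
                              n_planted_induced1 = 20L,
                              n_planted_induced2 = 20L,
                              n_modules = 5L,
                              module_size = 10L,
                              rho_target = 0.7,
                              rho_background = 0.0,
                              off_mean = 4.0,
                              on_mean = 9.0,
                              noise_sd = 1.0,
                              mean_variance_coupling = 0.3,
                              rng_seed = 1L) {
  d <- list(n_tissues = as.integer(n_tissues),
            datasets_per_tissue = as.integer(range(datasets_per_tissue)),
            samples_per_dataset = as.integer(range(samples_per_dataset)),
            n_genes = as.integer(n_genes),
            n_planted_pure = as.integer(n_planted_pure),
            n_planted_induced1 = as.integer(n_planted_induced1),
            n_planted_induced2 = as.integer(n_planted_induced2),
            n_modules = as.integer(n_modules),
            module_size = as.integer(module_size),
            rho_target = rho_target,
            rho_background = rho_background,
            off_mean = off_mean,
            on_mean = on_mean,
            noise_sd = noise_sd,
            mean_variance_coupling = mean_variance_coupling,
            rng_seed = as.integer(rng_seed))
  stopifnot(d$n_tissues >= 2L, d$n_genes >= 4L,
            d$rho_target > 0, d$rho_target < 1,
            d$rho_background >= 0, d$rho_background < 1,
            d$noise_sd >= 0,
            d$mean_variance_coupling >= 0, d$mean_variance_coupling < 1,
            d$samples_per_dataset[1L] >= 3L)
  n_planted_genes <- 2L * (d$n_planted_pure + d$n_planted_induced1 +
                           d$n_planted_induced2) +
                     d$n_modules * d$module_size
  if (n_planted_genes > d$n_genes)
    stop_fatal("n_genes = %d too small for %d planted/module genes",
               d$n_genes, n_planted_genes)
  class(d) <- "simulation_design"
  d
}

default_tissue_names <- function(n) {
  base <- c("brain", "blood", "liver", "lung", "muscle")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("tissue%02d", seq_len(n - length(base))))
}

# Assemble the planted structure: gene names, per-class links with target
# tissues, module memberships. Deterministic given the design.
plan_structure <- function(design) {
  g <- sprintf("g%04d", seq_len(design$n_genes))
  tissues <- default_tissue_names(design$n_tissues)
  idx <- 0L
  take <- function(n) {
    out <- g[idx + seq_len(n)]
    idx <<- idx + n
    out
  }
  mk_links <- function(n, class) {
    if (n == 0L)
      return(data.frame(gene_a = character(), gene_b = character(),
                        tissue = character(), class = character(),
                        stringsAsFactors = FALSE))
    ga <- take(n)
    gb <- take(n)
    data.frame(gene_a = ga, gene_b = gb,
               tissue = tissues[((seq_len(n) - 1L) %% length(tissues)) + 1L],
               class = class, stringsAsFactors = FALSE)
  }
  pure <- mk_links(design$n_planted_pure, "pure")
  ind1 <- mk_links(design$n_planted_induced1, "induced1")
  ind2 <- mk_links(design$n_planted_induced2, "induced2")
  modules <- lapply(seq_len(design$n_modules),
                    function(i) take(design$module_size))
  background <- g[idx < seq_along(g)]
  truth <- rbind(pure, ind1, ind2)
  cp <- canonical_pairs(truth$gene_a, truth$gene_b)
  truth$gene_a <- cp$gene_a
  truth$gene_b <- cp$gene_b
  class(truth) <- c("ground_truth", "data.frame")
  list(genes = g, tissues = tissues, truth = truth,
       modules = modules, background = background)
}

# Per-tissue population correlation matrix: equicorrelated background with
# planted 2x2 blocks and module blocks overlaid.
tissue_correlation <- function(structure, design, tissue) {
  g <- structure$genes
  G <- length(g)
  sigma <- matrix(design$rho_background, G, G, dimnames = list(g, g))
  diag(sigma) <- 1
  set_block <- function(members, rho) {
    i <- match(members, g)
    sigma[i, i] <<- rho
    for (k in i) sigma[k, k] <<- 1
  }
  for (m in structure$modules) set_block(m, design$rho_target)
  tr <- structure$truth
  on_target <- tr$tissue == tissue
  for (r in which(on_target))
    set_block(c(tr$gene_a[r], tr$gene_b[r]), design$rho_target)
  sigma
}

check_psd_or_report <- function(sigma, structure, design, tissue) {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  # locate an offending block for the error message
  for (m in structure$modules) {
    i <- match(m, structure$genes)
    if (min(eigen(sigma[i, i], symmetric = TRUE,
                  only.values = TRUE)$values) < -1e-10)
      stop_fatal("correlation block for module {%s} is not PSD in tissue %s",
                 paste(m, collapse = ","), tissue)
  }
  stop_fatal("assembled correlation matrix for tissue %s is not PSD", tissue)
}

# Per-tissue mean and SD for every gene.
tissue_mean_sd <- function(structure, design, bg_means) {
  g <- structure$genes
  tissues <- structure$tissues
  mu <- matrix(NA_real_, length(g), length(tissues),
               dimnames = list(g, tissues))
  tr <- structure$truth
  for (t in tissues) {
    m <- rep(design$on_mean, length(g))
    names(m) <- g
    m[structure$background] <- bg_means[structure$background]
    off <- character(0)
    # induced1: gene_a off outside its target tissue
    i1 <- tr[tr$class == "induced1" & tr$tissue != t, , drop = FALSE]
    off <- c(off, i1$gene_a)
    # induced2: both genes off outside the target tissue
    i2 <- tr[tr$class == "induced2" & tr$tissue != t, , drop = FALSE]
    off <- c(off, i2$gene_a, i2$gene_b)
    m[off] <- design$off_mean
    mu[, t] <- m
  }
  # SD shrinks continuously with the mean between off_mean and on_mean
  frac_off <- (design$on_mean - mu) / (design$on_mean - design$off_mean)
  frac_off[frac_off < 0] <- 0
  frac_off[frac_off > 1] <- 1
  sd <- design$noise_sd * (1 - design$mean_variance_coupling * frac_off)
  list(mu = mu, sd = sd)
}

#' Simulate a multi-tissue expression collection with planted links
#'
#' Draws every dataset from a multivariate Gaussian on the log2 scale whose
#' correlation matrix is assembled block-diagonally from the planted links,
#' the constitutive modules and an equicorrelated background (guaranteeing
#' positive semi-definiteness when the blocks do not overlap). See
#' \code{\link{simulation_design}} for the planted-class semantics.
#'
#' @param design A \code{\link{simulation_design}}.
#' @return List with \code{datasets} (list of
#'   \code{\link{expression_dataset}}), \code{truth} (data.frame
#'   \code{gene_a}, \code{gene_b}, \code{tissue}, \code{class} — the planted
#'   ground truth) and \code{tissues} (tissue names).
#' @examples
#' sim <- simulate_collection(simulation_design(
#'   n_tissues = 2, datasets_per_tissue = c(3, 3),
#'   samples_per_dataset = c(20, 20), n_genes = 30,
#'   n_planted_pure = 1, n_planted_induced1 = 0, n_planted_induced2 = 0,
#'   n_modules = 1, module_size = 4, rng_seed = 7))
#' length(sim$datasets)
#' @export
simulate_collection <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  structure_ <- plan_structure(design)
  with_seed(child_seed(design$rng_seed, "simulate"), function() {
    bg_means <- stats::runif(length(structure_$background),
                             design$off_mean, design$on_mean + 2)
    names(bg_means) <- structure_$background
    ms <- tissue_mean_sd(structure_, design, bg_means)
    datasets <- list()
    for (t in structure_$tissues) {
      sigma <- tissue_correlation(structure_, design, t)
      R <- check_psd_or_report(sigma, structure_, design, t)
      k_t <- sample(seq(design$datasets_per_tissue[1L],
                        design$datasets_per_tissue[2L]), 1L)
      for (j in seq_len(k_t)) {
        n <- sample(seq(design$samples_per_dataset[1L],
                        design$samples_per_dataset[2L]), 1L)
        z <- matrix(stats::rnorm(n * length(structure_$genes)), n) %*% R
        x <- t(z) * ms$sd[, t] + ms$mu[, t]
        rownames(x) <- structure_$genes
        colnames(x) <- sprintf("s%03d", seq_len(n))
        id <- sprintf("%s_d%02d", t, j)
        datasets[[id]] <- expression_dataset(id, t, x)
      }
    }
    list(datasets = datasets, truth = structure_$truth,
         tissues = structure_$tissues)
  })
}

#' Look up the planted class of a gene pair
#'
#' @param truth The ground-truth data.frame from
#'   \code{\link{simulate_collection}}.
#' @param gene_a,gene_b Gene IDs (any order).
#' @return \code{"pure"}, \code{"induced1"}, \code{"induced2"} or
#'   \code{"background"}.
#' @export
expected_link_class <- function(truth, gene_a, gene_b) {
  key <- pair_key(gene_a, gene_b)
  tk <- pair_key(truth$gene_a, truth$gene_b)
  i <- match(key, tk)
  ifelse(is.na(i), "background", truth$class[i])
}

#' Generate synthetic annotations aligned with planted structure
#'
#' Builds a flat gene-to-term map for testing link-based enrichment: one term
#' per (planted class, tissue) holding exactly the genes of those planted
#' links (names \code{pure_<tissue>}, \code{induced_<tissue>}), plus
#' \code{n_random_terms} random gene blocks unrelated to the planted
#' structure.
#'
#' @param gene_universe Character vector of all gene IDs.
#' @param truth Ground truth from \code{\link{simulate_collection}}, or NULL
#'   for random terms only.
#' @param n_random_terms Number of random terms. Default 30.
#' @param term_size_range Size range of random terms. Default c(5, 20).
#' @param seed Integer seed.
#' @return An \code{\link{annotation_map}}.
#' @export
simulate_annotations <- function(gene_universe, truth = NULL,
                                 n_random_terms = 30L,
                                 term_size_range = c(5L, 20L),
                                 seed = 1L) {
  genes <- character(0)
  terms <- character(0)
  if (!is.null(truth) && nrow(truth) > 0L) {
    grp <- ifelse(truth$class == "pure", "pure", "induced")
    key <- paste(grp, truth$tissue, sep = "_")
    for (k in unique(key)) {
      members <- unique(c(truth$gene_a[key == k], truth$gene_b[key == k]))
      genes <- c(genes, members)
      terms <- c(terms, rep(k, length(members)))
    }
  }
  with_seed(child_seed(seed, "annotations"), function() {
    for (i in seq_len(n_random_terms)) {
      sz <- sample(seq(term_size_range[1L], term_size_range[2L]), 1L)
      members <- sample(gene_universe, min(sz, length(gene_universe)))
      genes <<- c(genes, members)
      terms <<- c(terms, rep(sprintf("random%03d", i), length(members)))
    }
    annotation_map(genes, terms)
  })
}
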