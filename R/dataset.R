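#' Construct an expression dataset
#'
#' The atomic input of the pipeline: one cohort's genes x samples matrix of
#' log-scale expression (log2 intensities or log-CPM), tagged with a dataset
#' ID and a tissue label. Expression is assumed already log-scale and
#' preprocessed; the pipeline applies no normalization beyond the rank
#' transform the method itself defines.
#'
#' @param dataset_id Character scalar.
#' @param tissue Character scalar tissue/condition label.
#' @param matrix Numeric matrix, genes as rows (rownames are gene IDs),
#'   samples as columns. At least 3 samples (Pearson correlation needs the
#'   degrees of freedom).
#' @param gene_ids Optional character vector; defaults to rownames(matrix).
#' @return An object of class \code{"expression_dataset"} with fields
#'   \code{dataset_id}, \code{tissue}, \code{gene_ids}, \code{matrix} and
#'   \code{mean_expression} (per-gene row means, the e_ik of the expression
#'   model).
#' @export
expression_dataset <- function(dataset_id, tissue, matrix, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- rownames(matrix)
  if (is.null(gene_ids)) stop_fatal("matrix must have gene IDs as rownames")
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1L]
    stop_fatal("duplicate gene ID '%s' in dataset '%s'", dup, dataset_id)
  }
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  if (ncol(m) < 3L)
    stop_fatal("dataset '%s' has %d samples; at least 3 are required",
               dataset_id, ncol(m))
  rownames(m) <- gene_ids
  structure(
    list(dataset_id = as.character(dataset_id),
         tissue = as.character(tissue),
         gene_ids = gene_ids,
         matrix = m,
         mean_expression = rowMeans(m)),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset '%s'> tissue=%s, %d genes x %d samples\n",
              x$dataset_id, x$tissue, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Build a gene-to-term annotation map
#'
#' A flat gene -> set-of-terms mapping with its inverse index. Term identity
#' is opaque to the pipeline; any flat annotation source (GO slims, pathway
#' memberships, synthetic term blocks) can be used.
#'
#' @param gene_id,term_id Character vectors (one annotation pair per element).
#' @return Object of class \code{"annotation_map"}: list with
#'   \code{gene_terms} (named list gene -> character vector of terms) and
#'   \code{term_genes} (named list term -> character vector of genes), mutual
#'   inverses.
#' @export
annotation_map <- function(gene_id, term_id) {
  stopifnot(length(gene_id) == length(term_id))
  gene_id <- as.character(gene_id)
  term_id <- as.character(term_id)
  keep <- !duplicated(paste(gene_id, term_id, sep = "\r"))
  gene_id <- gene_id[keep]
  term_id <- term_id[keep]
  structure(
    list(gene_terms = split(term_id, gene_id),
         term_genes = split(gene_id, term_id)),
    class = "annotation_map"
  )
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation_map> %d genes, %d terms\n",
              length(x$gene_terms), length(x$term_genes)))
  invisible(x)
}
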