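# Readers and writers for the on-disk TSV dialects.
#
# Expression TSV: first column "gene_id", remaining columns samples.
# Metadata TSV: columns dataset_id, tissue, filename.
# Annotation TSV: two columns gene_id, term_id.
# Link TSV: gene_a, gene_b, tissue, tss, tss_fdr_pass, r2, link_class.

#' Read a collection of expression datasets
#'
#' Reads a metadata table (columns \code{dataset_id}, \code{tissue},
#' \code{filename}) and the expression TSVs it references. Genes are kept
#' per-dataset; harmonization to the common gene universe happens later in
#' \code{\link{harmonize_genes}}.
#'
#' @param metadata_path Path to the metadata TSV.
#' @param data_dir Directory containing the referenced expression TSVs.
#' @return A list of \code{\link{expression_dataset}} objects, one per
#'   metadata row.
#' @export
read_expression_collection <- function(metadata_path, data_dir) {
  if (!file.exists(metadata_path))
    stop_fatal("metadata file not found: %s", metadata_path)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  need <- c("dataset_id", "tissue", "filename")
  if (!all(need %in% names(meta)))
    stop_fatal("metadata must have columns %s", paste(need, collapse = ", "))
  lapply(seq_len(nrow(meta)), function(i) {
    path <- file.path(data_dir, meta$filename[i])
    if (!file.exists(path))
      stop_fatal("expression file not found: %s", path)
    read_expression_tsv(path, meta$dataset_id[i], meta$tissue[i])
  })
}

#' Read one expression TSV
#'
#' @param path Path to a TSV with first column \code{gene_id} and one column
#'   per sample.
#' @param dataset_id,tissue Labels for the resulting dataset.
#' @return An \code{\link{expression_dataset}}.
#' @export
read_expression_tsv <- function(path, dataset_id, tissue) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1L] != "gene_id")
    stop_fatal("first column of %s must be 'gene_id'", path)
  genes <- as.character(tab$gene_id)
  if (anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)][1L]
    stop_fatal("duplicate gene ID '%s' in %s", dup, path)
  }
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- genes
  expression_dataset(dataset_id, tissue, m)
}

#' Write a collection of expression datasets
#'
#' Writes one expression TSV per dataset plus a metadata TSV
#' (\code{metadata.tsv}) into \code{dir}; the output round-trips through
#' \code{\link{read_expression_collection}}.
#'
#' @param datasets List of \code{\link{expression_dataset}} objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the metadata data.frame.
#' @export
write_expression_collection <- function(datasets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- data.frame(
    dataset_id = vapply(datasets, `[[`, "", "dataset_id"),
    tissue = vapply(datasets, `[[`, "", "tissue"),
    filename = paste0(vapply(datasets, `[[`, "", "dataset_id"), ".tsv"),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    tab <- data.frame(gene_id = d$gene_ids, d$matrix,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, file.path(dir, meta$filename[i]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(meta)
}

link_tsv_columns <- c("gene_a", "gene_b", "tissue", "tss", "tss_fdr_pass",
                      "r2", "link_class")

#' Write a link set to TSV
#'
#' Canonical link TSV dialect: columns \code{gene_a}, \code{gene_b},
#' \code{tissue}, \code{tss}, \code{tss_fdr_pass}, \code{r2},
#' \code{link_class}; pairs ordered so \code{gene_a < gene_b}. Missing
#' attributes are written as NA. Round-trips losslessly through
#' \code{\link{read_linkset}}.
#'
#' @param links A data.frame with at least \code{gene_a}, \code{gene_b};
#'   the remaining columns are filled with NA when absent.
#' @param path Output path.
#' @export
write_linkset <- function(links, path) {
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (nrow(links) > 0L) {
    cp <- canonical_pairs(links$gene_a, links$gene_b)
    links$gene_a <- cp$gene_a
    links$gene_b <- cp$gene_b
  }
  na_of <- list(gene_a = NA_character_, gene_b = NA_character_,
                tissue = NA_character_, tss = NA_real_, tss_fdr_pass = NA,
                r2 = NA_real_, link_class = NA_character_)
  for (col in link_tsv_columns)
    if (is.null(links[[col]]))
      links[[col]] <- rep(na_of[[col]], nrow(links))
  out <- links[, link_tsv_columns, drop = FALSE]
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_fatal("cannot write link set to %s", path)
  invisible(out)
}

#' Read a link set TSV
#'
#' @param path Path written by \code{\link{write_linkset}}.
#' @return Data.frame with the canonical link columns.
#' @export
read_linkset <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(gene_a = "character",
                                          gene_b = "character",
                                          tissue = "character",
                                          tss = "numeric",
                                          tss_fdr_pass = "logical",
                                          r2 = "numeric",
                                          link_class = "character"))
  tab[, link_tsv_columns, drop = FALSE]
}

#' Read a gene-to-term annotation TSV
#'
#' Two-column TSV (\code{gene_id}, \code{term_id}), one pair per line; a
#' GAF-reduced dialect.
#'
#' @param path Path to the annotation TSV.
#' @return An \code{\link{annotation_map}}.
#' @export
read_annotations <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(tab)))
    stop_fatal("annotation TSV must have columns gene_id, term_id")
  annotation_map(tab$gene_id, tab$term_id)
}

#' Write an annotation map to TSV
#'
#' @param annotations An \code{\link{annotation_map}}.
#' @param path Output path.
#' @export
write_annotations <- function(annotations, path) {
  genes <- rep(names(annotations$gene_terms),
               lengths(annotations$gene_terms))
  terms <- unlist(annotations$gene_terms, use.names = FALSE)
  utils::write.table(
    data.frame(gene_id = genes, term_id = terms, stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
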