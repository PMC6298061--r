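# Internal helpers shared across modules.

#' Canonicalize gene pairs
#'
#' Orders each pair lexicographically so that \code{gene_a < gene_b}. All
#' link-handling code normalizes pairs on entry; a coexpression link is an
#' unordered pair and a single orientation prevents duplicates.
#'
#' @param gene_a,gene_b Character vectors of equal length.
#' @return A data.frame with columns \code{gene_a}, \code{gene_b}.
#' @export
canonical_pairs <- function(gene_a, gene_b) {
  stopifnot(length(gene_a) == length(gene_b))
  a <- as.character(gene_a)
  b <- as.character(gene_b)
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
}

# "a|b" keys for canonical pairs; used as link identifiers throughout.
pair_key <- function(gene_a, gene_b) {
  p <- canonical_pairs(gene_a, gene_b)
  paste(p$gene_a, p$gene_b, sep = "|")
}

#' Derive a child seed from a root seed and a stream name
#'
#' All randomness in the package flows from one root seed through named
#' child streams (pseudo-tissue draws, expression shuffles, synthetic data,
#' enrichment nulls), so that independent stages are reproducible in
#' isolation and insensitive to each other's consumption of the RNG.
#'
#' @param seed Integer root seed.
#' @param name Character stream name.
#' @return An integer seed in [0, 2^31 - 1).
#' @export
child_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 69069 + h) %% 2147483647)
}

# run fun() under a local RNG state seeded by `seed`, restoring the caller's
# state afterwards
with_seed <- function(seed, fun) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  fun()
}

# upper-triangle pair index of a gene vector, as a two-column integer matrix
# (rows are pairs i < j in the order used by all pairwise vectors)
upper_pairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

# extract the upper-triangle vector of a square matrix (column-major order,
# matching upper_pairs())
ut_vec <- function(m) {
  m[upper.tri(m)]
}

stop_fatal <- function(...) stop(sprintf(...), call. = FALSE)
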