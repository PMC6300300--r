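#' Differential-expression signature matrix
#'
#' Container for an L1000-style compendium: a genes-by-samples matrix of
#' differential-expression Z-scores. Values must be finite and identifiers
#' unique; rows are landmark genes (978 in the L1000 assay), columns are
#' perturbation samples (drug treatments, gene knockdowns, controls).
#'
#' @param z numeric matrix of Z-scores, genes in rows, samples in columns.
#' @param gene_ids character vector of row identifiers; defaults to
#'   `rownames(z)`.
#' @param sample_ids character vector of column identifiers; defaults to
#'   `colnames(z)`.
#' @return An object of class `signature_matrix` with fields `gene_ids`,
#'   `sample_ids` and `z` (the matrix carries the ids as dimnames).
#' @examples
#' z <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' sm <- signature_matrix(z)
#' dim(sm$z)
#' @export
signature_matrix <- function(z, gene_ids = rownames(z),
                             sample_ids = colnames(z)) {
  if (!is.matrix(z) || !is.numeric(z))
    stop("`z` must be a numeric matrix")
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(z))
    stop(sprintf("%d gene ids for %d rows", length(gene_ids), nrow(z)))
  if (length(sample_ids) != ncol(z))
    stop(sprintf("%d sample ids for %d columns", length(sample_ids), ncol(z)))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (!all(is.finite(z)))
    stop("signature matrix contains non-finite values")
  dimnames(z) <- list(gene_ids, sample_ids)
  structure(list(gene_ids = gene_ids, sample_ids = sample_ids, z = z),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  invisible(x)
}

#' @export
dim.signature_matrix <- function(x) dim(x$z)

#' Consensus signature across replicates
#'
#' Collapses replicate signature columns into one consensus profile by the
#' element-wise mean. A single replicate is returned unchanged. Replicate
#' order does not matter.
#'
#' @param replicates numeric vector (one replicate) or a genes-by-replicates
#'   numeric matrix.
#' @return Numeric vector of the same gene dimension.
#' @examples
#' consensus_signature(cbind(c(1, 3), c(3, 5)))  # (2, 4)
#' @export
consensus_signature <- function(replicates) {
  if (is.null(dim(replicates))) {
    if (length(replicates) == 0L) stop("zero replicates supplied")
    return(replicates)
  }
  if (ncol(replicates) == 0L) stop("zero replicates supplied")
  if (ncol(replicates) == 1L) return(replicates[, 1L])
  rowMeans(replicates)
}
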