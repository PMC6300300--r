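# Genomic feature families per (drug, candidate gene, cell line):
#   f_cor     signed Pearson correlation between drug and KD signatures
#   f_PC      degree-corrected enrichment of the gene's interaction partners
#             among the KDs most correlated with the drug ("indirect")
#   f_CS      drug-vs-control correlation (cell activity; low = active)
#   f_DE_*    mean / max |Z| of the gene's partners in the drug signature
#   f_loc     cellular localization encoded as +1 / 0 / -1

FEATURE_COLUMNS <- c("f_cor", "f_PC", "f_CS", "f_DE_mean", "f_DE_max", "f_loc")

#' Pearson correlation with strict input checks
#'
#' Standard product-moment correlation, but zero-variance input is an error
#' rather than a silent `NA`: an undefined correlation entering a rank
#' aggregation would corrupt downstream orderings.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return Correlation in \[-1, 1\].
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite input")
  if (isTRUE(all.equal(stats::var(x), 0)) || isTRUE(all.equal(stats::var(y), 0)))
    stop("undefined correlation: zero-variance input")
  as.numeric(cor(x, y))
}

#' Precompute per-cell consensus signatures
#'
#' Collapses replicate samples into consensus signatures once, so repeated
#' feature computations do not redo the averaging. For every cell line the
#' cache holds a genes-by-KD-genes consensus matrix, a genes-by-drugs
#' consensus matrix and the raw control columns.
#'
#' @param sig a [signature_matrix()].
#' @param meta a [sample_meta()] table.
#' @return Object of class `consensus_cache`.
#' @export
consensus_cache <- function(sig, meta) {
  check_meta_samples(sig, meta)
  cells <- sort(unique(meta$cell_line))
  per_cell <- function(cell) {
    m <- meta[meta$cell_line == cell, , drop = FALSE]
    grp_consensus <- function(rows, group) {
      if (!nrow(rows)) return(NULL)
      zs <- sig$z[, rows$sample_id, drop = FALSE]
      cnt <- table(group)
      cons <- t(rowsum(t(zs), group = group))  # genes x groups (sums)
      sweep(cons, 2L, as.numeric(cnt[colnames(cons)]), "/")
    }
    kd_rows <- m[m$pert_type == "kd", , drop = FALSE]
    drug_rows <- m[m$pert_type == "drug", , drop = FALSE]
    ctl_rows <- m[m$pert_type == "control", , drop = FALSE]
    list(kd = grp_consensus(kd_rows, kd_rows$kd_gene),
         drug = grp_consensus(drug_rows, drug_rows$perturbagen_id),
         control = if (nrow(ctl_rows))
           sig$z[, ctl_rows$sample_id, drop = FALSE] else NULL)
  }
  out <- lapply(cells, per_cell)
  names(out) <- cells
  structure(list(cells = cells, by_cell = out, gene_ids = sig$gene_ids),
            class = "consensus_cache")
}

.cache_get <- function(cache, cell, what, id, ctx) {
  cc <- cache$by_cell[[cell]]
  if (is.null(cc)) stop("missing data for ", ctx, ": unknown cell ", cell)
  m <- cc[[what]]
  if (is.null(m) || !(id %in% colnames(m)))
    stop("missing ", what, " signature for ", ctx)
  m[, id]
}

.drug_signature <- function(cache, drug, cell)
  .cache_get(cache, cell, "drug", drug, sprintf("(%s, %s)", drug, cell))

.kd_signature <- function(cache, gene, cell)
  .cache_get(cache, cell, "kd", gene, sprintf("(%s, %s)", gene, cell))

#' Direct drug-knockdown signature correlation (f_cor)
#'
#' Signed Pearson correlation between the consensus drug-treatment signature
#' and the consensus knockdown signature of a candidate target gene in one
#' cell line. Inhibition is expected to mimic knockdown, so the sign is kept.
#'
#' @param drug,gene,cell identifiers.
#' @param sig,meta compendium and metadata (ignored when `cache` is given).
#' @param cache optional [consensus_cache()].
#' @return Correlation in \[-1, 1\].
#' @export
direct_correlation <- function(drug, gene, cell, sig = NULL, meta = NULL,
                               cache = NULL) {
  cache <- cache %||% consensus_cache(sig, meta)
  pearson_cor(.drug_signature(cache, drug, cell),
              .kd_signature(cache, gene, cell))
}

#' Knockdowns most correlated with a drug signature
#'
#' Ranks candidate KD genes by descending signed correlation with the drug's
#' consensus signature in one cell line and returns the top `X`. Ties break
#' lexicographically by gene identifier.
#'
#' @param drug,cell identifiers.
#' @param sig,meta compendium and metadata (ignored when `cache` is given).
#' @param X top-list size; the list returned has `min(X, N)` genes where `N`
#'   is the number of candidates. Default 100.
#' @param candidates candidate gene set; defaults to all KD genes in the cell.
#' @param cache optional [consensus_cache()].
#' @return Character vector of gene ids, best-correlated first.
#' @export
top_correlated_kds <- function(drug, cell, sig = NULL, meta = NULL, X = 100,
                               candidates = NULL, cache = NULL) {
  if (!is.numeric(X) || X <= 0) stop("X must be a positive integer")
  cache <- cache %||% consensus_cache(sig, meta)
  cc <- cache$by_cell[[cell]]
  if (is.null(cc) || is.null(cc$kd)) stop("no KD signatures in cell ", cell)
  kd <- cc$kd
  if (!is.null(candidates)) {
    miss <- setdiff(candidates, colnames(kd))
    if (length(miss))
      stop("missing KD signature for (", paste(head(miss, 3), collapse = ","),
           ", ", cell, ")")
    kd <- kd[, candidates, drop = FALSE]
  }
  d <- .drug_signature(cache, drug, cell)
  r <- as.vector(cor(d, kd))
  genes <- colnames(kd)
  genes[head(order(-r, genes), min(as.integer(X), length(genes)))]
}

#' Indirect correlation feature (f_PC)
#'
#' Degree-corrected enrichment of a candidate gene's interaction partners
#' among the top-`X` KDs correlated with a drug. With `k` partners in the
#' top list and `deg` partners inside the candidate frame, the fold form is
#' `(k / deg) / (Xeff / N)` where `Xeff = min(X, N)` is the realized
#' top-list size and `N` the number of candidate KD genes: the expected
#' fraction under a random top list, which corrects for hub proteins.
#' Genes without in-frame partners (or absent from the network) score 0.
#'
#' @param gene candidate gene.
#' @param network a [ppi_network()].
#' @param top_list gene ids of the top-correlated KDs (from
#'   [top_correlated_kds()]).
#' @param X nominal top-list size.
#' @param N number of candidate KD genes in the cell.
#' @param candidates candidate frame used for the degree; defaults to all
#'   network nodes.
#' @param form `"fold"` (default) for observed/expected, `"difference"` for
#'   `k/deg - Xeff/N`.
#' @return Non-negative enrichment (fold form); difference form may be
#'   negative.
#' @export
indirect_correlation <- function(gene, network, top_list, X, N,
                                 candidates = NULL,
                                 form = c("fold", "difference")) {
  form <- match.arg(form)
  if (!is.numeric(N) || N <= 0) stop("N must be positive")
  if (!is.numeric(X) || X <= 0) stop("X must be positive")
  partners <- ppi_partners(network, gene)
  if (!is.null(candidates)) partners <- intersect(partners, candidates)
  deg <- length(partners)
  if (deg == 0L) return(0)
  k <- sum(partners %in% top_list)
  expected <- min(X, N) / N
  if (form == "fold") (k / deg) / expected else k / deg - expected
}

#' Cell-selection feature (f_CS)
#'
#' Mean Pearson correlation between the drug's consensus signature and each
#' control sample of the cell. A transcriptionally active drug perturbs the
#' cell away from its baseline, so the *lowest* f_CS across cells marks the
#' most active cell line.
#'
#' @inheritParams direct_correlation
#' @return Correlation in \[-1, 1\].
#' @export
cell_selection <- function(drug, cell, sig = NULL, meta = NULL, cache = NULL) {
  cache <- cache %||% consensus_cache(sig, meta)
  cc <- cache$by_cell[[cell]]
  if (is.null(cc) || is.null(cc$control) || ncol(cc$control) == 0L)
    stop("no control samples in cell ", cell)
  d <- .drug_signature(cache, drug, cell)
  mean(as.vector(cor(d, cc$control)))
}

#' Partner differential-expression features (f_DE_mean, f_DE_max)
#'
#' Mean and maximum absolute Z-score, in the drug's consensus signature, over
#' the measured interaction partners of a candidate gene. Both are 0 when no
#' partner is among the measured genes.
#'
#' @inheritParams direct_correlation
#' @param network a [ppi_network()].
#' @return Named numeric vector `c(f_DE_mean=, f_DE_max=)`.
#' @export
partner_expression_features <- function(drug, gene, cell, network,
                                        sig = NULL, meta = NULL,
                                        cache = NULL) {
  cache <- cache %||% consensus_cache(sig, meta)
  d <- .drug_signature(cache, drug, cell)
  partners <- intersect(ppi_partners(network, gene), cache$gene_ids)
  if (!length(partners))
    return(c(f_DE_mean = 0, f_DE_max = 0))
  a <- abs(d[partners])
  c(f_DE_mean = mean(a), f_DE_max = max(a))
}

#' Cellular localization feature (f_loc)
#'
#' Encodes annotated localization as +1 (intracellular), -1 (transmembrane
#' or extracellular) or 0 (unannotated / unknown).
#'
#' @param gene gene symbol (vectorized).
#' @param locmap named character vector or data.frame with columns `gene`,
#'   `localization`; labels among `intracellular`, `transmembrane`,
#'   `extracellular`, `unknown`.
#' @return Numeric vector in \{-1, 0, 1\}.
#' @export
localization_feature <- function(gene, locmap) {
  if (is.data.frame(locmap)) {
    lm <- locmap$localization
    names(lm) <- locmap$gene
  } else lm <- locmap
  lab <- lm[gene]
  out <- numeric(length(gene))
  out[!is.na(lab) & lab == "intracellular"] <- 1
  out[!is.na(lab) & lab %in% c("transmembrane", "extracellular")] <- -1
  unname(out)
}

#' Assemble the feature table of a drug
#'
#' Computes all six features for every (candidate gene, cell) pair of a
#' drug's candidate space and returns the complete dense block, ordered by
#' gene then cell (lexicographic), one row per pair. `f_CS` depends only on
#' the cell and is replicated across genes.
#'
#' @param drug drug identifier.
#' @param space the drug's [build_candidate_space()].
#' @param sig,meta compendium and metadata.
#' @param network a [ppi_network()].
#' @param locmap localization annotation (see [localization_feature()]).
#' @param X top-list size for the indirect feature (default 100).
#' @param cache optional [consensus_cache()]; pass one when assembling many
#'   drugs against the same compendium.
#' @return `feature_table` data.frame with columns `drug`, `gene`, `cell`
#'   and the six features.
#' @export
assemble_feature_table <- function(drug, space, sig = NULL, meta = NULL,
                                   network, locmap, X = 100, cache = NULL) {
  stopifnot(inherits(space, "candidate_space"))
  cache <- cache %||% consensus_cache(sig, meta)
  genes <- space$genes
  cells <- space$cells
  N <- length(genes)
  Xeff <- min(as.integer(X), N)

  # per-gene partner index vectors, once
  partner_cand <- lapply(genes, function(g)
    which(genes %in% ppi_partners(network, g)))
  partner_meas <- lapply(genes, function(g) {
    p <- intersect(ppi_partners(network, g), cache$gene_ids)
    match(p, cache$gene_ids)
  })
  floc <- localization_feature(genes, locmap)

  blocks <- lapply(cells, function(cell) {
    cc <- cache$by_cell[[cell]]
    if (is.null(cc) || is.null(cc$kd))
      stop("missing data for (", drug, ", ", cell, "): no KD signatures")
    miss <- setdiff(genes, colnames(cc$kd))
    if (length(miss))
      stop("missing KD signature for (", drug, ", ", miss[1L], ", ", cell, ")")
    kd <- cc$kd[, genes, drop = FALSE]
    d <- .drug_signature(cache, drug, cell)
    r <- as.vector(cor(d, kd))
    fcs <- cell_selection(drug, cell, cache = cache)
    in_top <- logical(N)
    in_top[head(order(-r, genes), Xeff)] <- TRUE
    fpc <- vapply(partner_cand, function(idx) {
      deg <- length(idx)
      if (deg == 0L) 0 else (sum(in_top[idx]) / deg) / (Xeff / N)
    }, numeric(1L))
    a <- abs(d)
    de <- vapply(partner_meas, function(idx) {
      if (!length(idx)) c(0, 0) else {
        v <- a[idx]
        c(mean(v), max(v))
      }
    }, numeric(2L))
    data.frame(drug = drug, gene = genes, cell = cell,
               f_cor = r, f_PC = fpc, f_CS = fcs,
               f_DE_mean = de[1L, ], f_DE_max = de[2L, ], f_loc = floc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  out <- out[order(out$gene, out$cell), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("feature_table", "data.frame"),
            drug = drug, cells = cells, genes = genes, X = as.integer(X))
}

#' Write / read a feature table as TSV
#' @param table a `feature_table`.
#' @param path file path.
#' @return `path` (write) or the table (read).
#' @export
write_feature_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("drug", "gene", "cell", FEATURE_COLUMNS)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("feature table lacks columns: ", paste(miss, collapse = ", "))
  structure(df, class = c("feature_table", "data.frame"),
            drug = df$drug[1L], cells = sort(unique(df$cell)),
            genes = sort(unique(df$gene)))
}
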