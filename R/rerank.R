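# Structural re-ranking: reorder the genomic top-K candidates of a drug by
# externally supplied docking scores (lower = better). Actual docking is
# out of scope; scores arrive through a TSV provider interface, and a mock
# provider supports testing against synthetic truth.

#' Read a docking-score table
#'
#' Consumes the provider interface: a TSV with columns `drug`, `gene`,
#' `score` (affinity-like; lower is better). A (drug, gene) pair absent
#' from the table means "no structure available" — absence is an explicit
#' state, never zero. Any external docking run (e.g. AutoDock Vina-family
#' engines) can populate this file from receptor/ligand identifiers.
#'
#' @param path TSV path.
#' @return data.frame with columns `drug`, `gene`, `score`.
#' @export
read_docking_scores <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  miss <- setdiff(c("drug", "gene", "score"), names(df))
  if (length(miss))
    stop("docking table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(df$score))) stop("docking scores must be finite")
  df
}

#' Re-rank the genomic top-K by docking score
#'
#' Takes the top `K` candidates of a genomic ranking; candidates with a
#' docking score are sorted ascending by score (stable, so equal scores
#' preserve genomic order), and unscored (structureless) candidates are
#' appended afterwards in genomic order — structural evidence, when
#' available, dominates. No candidate is dropped or duplicated.
#'
#' @param ranked a [ranked_targets()].
#' @param scores docking-score data.frame (`gene`, `score`, optionally
#'   `drug` which is filtered on the ranking's drug); may cover any subset.
#'   `NULL` or empty degrades to the genomic order.
#' @param K size of the genomic head to re-rank (default 100).
#' @return `rerank_result` data.frame with columns `gene`, `genomic_rank`,
#'   `docking_score` (`NA` when structureless) and `final_rank`.
#' @export
rerank_top_k <- function(ranked, scores = NULL, K = 100) {
  stopifnot(inherits(ranked, "ranked_targets"))
  K <- min(as.integer(K), nrow(ranked))
  top <- ranked[seq_len(K), , drop = FALSE]
  drug <- attr(ranked, "drug")
  sc <- rep(NA_real_, K)
  if (!is.null(scores) && nrow(scores)) {
    if ("drug" %in% names(scores) && !is.na(drug))
      scores <- scores[scores$drug == drug, , drop = FALSE]
    sc <- scores$score[match(top$gene, scores$gene)]
  }
  scored <- which(!is.na(sc))
  unscored <- which(is.na(sc))
  ord <- c(scored[order(sc[scored])], unscored)
  out <- data.frame(gene = top$gene[ord], genomic_rank = top$rank[ord],
                    docking_score = sc[ord], final_rank = seq_len(K),
                    stringsAsFactors = FALSE)
  structure(out, class = c("rerank_result", "data.frame"), drug = drug)
}

#' Distribution-cutoff hit filter
#'
#' Declares hits among the scored candidates of a re-ranked list: those
#' whose docking score is strictly better (lower) than the given quantile
#' of the drug's own score distribution (default the median, i.e. a 50%
#' cutoff). The strict inequality means a lone scored candidate can never
#' certify itself; `quantile = 1` is the boundary case where every scored
#' candidate passes.
#'
#' @param result a [rerank_top_k()] result.
#' @param quantile cutoff quantile in (0, 1\]; default 0.5.
#' @return Character vector of hit genes (may be empty; warns when nothing
#'   was scored).
#' @export
cutoff_filter <- function(result, quantile = 0.5) {
  stopifnot(inherits(result, "rerank_result"),
            quantile > 0, quantile <= 1)
  sc <- result$docking_score[!is.na(result$docking_score)]
  if (!length(sc)) {
    warning("no scored candidates; empty hit set")
    return(character(0))
  }
  if (quantile >= 1) {
    hits <- !is.na(result$docking_score)
  } else {
    thr <- stats::quantile(sc, quantile, names = FALSE)  # type 7, midpoint
    hits <- !is.na(result$docking_score) & result$docking_score < thr
  }
  result$gene[hits]
}

#' Mock docking-score provider
#'
#' Test double for the docking stage. For each drug's genomic top-K, decoy
#' candidates receive scores from N(0, `noise_sd`) while the planted target
#' is drawn `margin` standard deviations lower (better); a `structureless`
#' fraction of candidates gets no score, emulating incomplete structural
#' coverage of the proteome. By default the planted target itself is always
#' scored, mirroring the evaluation subset of drugs whose known target has
#' a solved structure; set `target_always_scored = FALSE` for fully random
#' availability.
#'
#' @param rankings named list of [ranked_targets()].
#' @param truth named character vector or list mapping drug to its planted
#'   target gene.
#' @param K genomic head size (default 100).
#' @param margin target advantage in units of `noise_sd` (default 3).
#' @param noise_sd score noise standard deviation (default 1).
#' @param structureless fraction of candidates without a score (default
#'   0.3).
#' @param seed RNG seed.
#' @param target_always_scored force a score for the planted target
#'   (default `TRUE`).
#' @return data.frame with columns `drug`, `gene`, `score`.
#' @export
mock_score_provider <- function(rankings, truth, K = 100, margin = 3,
                                noise_sd = 1, structureless = 0.3, seed = 1,
                                target_always_scored = TRUE) {
  with_seed(seed, {
    rows <- lapply(names(rankings), function(d) {
      top <- head(rankings[[d]]$gene, K)
      n <- length(top)
      keep <- runif(n) >= structureless
      tgt <- as.character(truth[[d]])
      if (target_always_scored) keep[top %in% tgt] <- TRUE
      score <- rnorm(n, mean = 0, sd = noise_sd)
      score[top %in% tgt] <- rnorm(sum(top %in% tgt),
                                   mean = -margin * noise_sd, sd = noise_sd)
      data.frame(drug = d, gene = top, score = score,
                 stringsAsFactors = FALSE)[keep, , drop = FALSE]
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
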