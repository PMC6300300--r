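# Rank-based evaluation: per-drug best-target rank, top-k accuracy,
# normalized-rank ROC/AUC, a permutation random baseline, and
# hypergeometric category enrichment.

#' Best rank of a drug's known targets
#'
#' The minimum rank over the drug's known target set ("the top known
#' target"). A drug whose known targets all fall outside the candidate
#' frame is not evaluable and yields `NA` — such drugs are excluded from
#' accuracy counts rather than scored at the worst rank.
#'
#' @param ranking a [ranked_targets()].
#' @param known_targets character vector of known target genes.
#' @return Integer rank, or `NA_integer_` when not evaluable.
#' @export
best_target_rank <- function(ranking, known_targets) {
  hit <- ranking$rank[ranking$gene %in% known_targets]
  if (!length(hit)) return(NA_integer_)
  as.integer(min(hit))
}

#' Count drugs with a target in the top k
#'
#' @param best_ranks integer vector of per-drug best target ranks (`NA` =
#'   not evaluable, excluded).
#' @param k rank threshold (>= 1).
#' @return Number of drugs with best rank `<= k`.
#' @export
topk_count <- function(best_ranks, k) {
  stopifnot(k >= 1)
  sum(best_ranks <= k, na.rm = TRUE)
}

#' Mean best-target rank
#' @param best_ranks integer vector of per-drug best ranks.
#' @return Arithmetic mean over evaluable drugs.
#' @export
mean_best_rank <- function(best_ranks) {
  best_ranks <- best_ranks[!is.na(best_ranks)]
  if (!length(best_ranks)) stop("no evaluable drugs")
  mean(best_ranks)
}

#' Normalized-rank ROC curve and AUC
#'
#' The false-positive rate is the normalized rank threshold used to call
#' potential targets (the fraction of the candidate list declared positive)
#' and the true-positive rate is the fraction of drugs whose best known
#' target falls at or above that threshold. The AUC of this curve equals
#' one minus the mean normalized best rank.
#'
#' @param best_ranks per-drug best target ranks.
#' @param pool_sizes per-drug candidate pool sizes (same length; each >=
#'   the corresponding rank).
#' @param n_grid number of evenly spaced thresholds in \[0, 1\] (default
#'   1001).
#' @return List with `points` (data.frame `fpr`, `tpr`) and `auc`
#'   (trapezoid).
#' @export
roc_curve <- function(best_ranks, pool_sizes, n_grid = 1001) {
  keep <- !is.na(best_ranks)
  best_ranks <- best_ranks[keep]
  pool_sizes <- pool_sizes[keep]
  if (length(best_ranks) != length(pool_sizes))
    stop("rank/pool length mismatch")
  if (any(best_ranks > pool_sizes))
    stop("best rank exceeds pool size")
  norm <- best_ranks / pool_sizes
  grid <- seq(0, 1, length.out = n_grid)
  tpr <- vapply(grid, function(t) mean(norm <= t), numeric(1L))
  auc <- sum(diff(grid) * (head(tpr, -1) + tpr[-1]) / 2)
  list(points = data.frame(fpr = grid, tpr = tpr), auc = auc)
}

#' Random-ranking permutation baseline
#'
#' Simulates uniformly random candidate rankings: in each permutation every
#' drug's known targets receive distinct uniform ranks in `1..pool`, and
#' the number of drugs whose best target lands in the top `k` is recorded.
#' Summaries support significance calls against the random expectation.
#'
#' @param target_counts per-drug number of known targets in the frame.
#' @param pool candidate pool size (>= max target count).
#' @param k rank threshold.
#' @param n_perm number of permutations (default 20000).
#' @param seed RNG seed.
#' @param alpha tail level for the reported upper quantile (default 0.05).
#' @return List with the per-permutation `counts` and summaries `mean`,
#'   `median`, `q_upper`.
#' @export
random_baseline <- function(target_counts, pool, k, n_perm = 20000, seed = 1,
                            alpha = 0.05) {
  stopifnot(n_perm >= 1, k >= 1)
  target_counts <- as.integer(target_counts)
  if (pool < max(target_counts))
    stop("pool smaller than the largest target count")
  with_seed(seed, {
    counts <- integer(n_perm)
    for (d in seq_along(target_counts)) {
      t_d <- target_counts[d]
      hit <- vapply(seq_len(n_perm), function(i)
        min(sample.int(pool, t_d)) <= k, logical(1L))
      counts <- counts + hit
    }
    list(counts = counts, mean = mean(counts),
         median = stats::median(counts),
         q_upper = stats::quantile(counts, 1 - alpha, names = FALSE))
  })
}

#' Closed-form expectation of the random baseline
#'
#' Expected number of drugs with a target in the top `k` under uniformly
#' random rankings: for a drug with `t` targets the probability that the
#' best of `t` distinct uniform ranks is `<= k` equals
#' `1 - choose(pool-k, t) / choose(pool, t)`.
#'
#' @inheritParams random_baseline
#' @return Expected drug count.
#' @export
random_baseline_expectation <- function(target_counts, pool, k) {
  sum(vapply(target_counts, function(t)
    1 - exp(lchoose(pool - k, t) - lchoose(pool, t)), numeric(1L)))
}

#' Hypergeometric category enrichment
#'
#' Upper-tail probability of observing at least the actual overlap between
#' a hit set and a category, drawing `|hits|` genes from the universe
#' without replacement (as used for cellular-component enrichment of
#' successful vs unsuccessful targets).
#'
#' @param hit_genes character vector of hits (subset of `universe`).
#' @param category_genes category members (subset of `universe`).
#' @param universe background gene set.
#' @return P-value in (0, 1\].
#' @export
hypergeom_enrichment <- function(hit_genes, category_genes, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  hit_genes <- unique(hit_genes)
  category_genes <- unique(category_genes)
  if (!all(hit_genes %in% universe) || !all(category_genes %in% universe))
    stop("hits and category must be subsets of the universe")
  q <- length(intersect(hit_genes, category_genes))
  phyper(q - 1, length(category_genes),
         length(universe) - length(category_genes),
         length(hit_genes), lower.tail = FALSE)
}

#' Full evaluation report for a set of rankings
#'
#' @param rankings named list of [ranked_targets()].
#' @param targets named list mapping drug to known target genes.
#' @param ks top-k thresholds (default 10, 50, 100).
#' @return List with per-drug best ranks and pool sizes, `topk` counts,
#'   `mean_rank`, `auc`, `roc`, and ids of non-evaluable drugs.
#' @export
evaluation_report <- function(rankings, targets, ks = c(10, 50, 100)) {
  drugs <- names(rankings)
  best <- vapply(drugs, function(d)
    best_target_rank(rankings[[d]], targets[[d]] %||% character(0)),
    integer(1L))
  pool <- vapply(drugs, function(d) nrow(rankings[[d]]), integer(1L))
  roc <- roc_curve(best, pool)
  list(best_rank = best, pool = pool,
       not_evaluable = drugs[is.na(best)],
       topk = setNames(vapply(ks, function(k) topk_count(best, k),
                              numeric(1L)), paste0("top", ks)),
       mean_rank = mean_best_rank(best),
       auc = roc$auc, roc = roc$points)
}
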