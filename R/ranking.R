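# Per-drug target ranking: single-feature rankers with lowest-rank
# aggregation across cell lines, a logistic baseline on per-gene aggregates,
# and the two random-forest architectures (pooled "two-level" and per-drug
# "on-the-fly"), evaluated by leave-one-out cross-validation.

#' Ranked candidate targets of a drug
#'
#' @param genes candidate genes, best first.
#' @param scores scores aligned with `genes`, non-increasing.
#' @param drug drug identifier.
#' @return `ranked_targets` data.frame with columns `gene`, `score`, `rank`
#'   (1 = best); the drug id is carried as attribute `drug`.
#' @export
ranked_targets <- function(genes, scores, drug = NA_character_) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate genes in ranking")
  if (length(scores) != length(genes)) stop("score/gene length mismatch")
  if (any(diff(scores) > 1e-9)) stop("scores must be non-increasing")
  structure(data.frame(gene = genes, score = as.numeric(scores),
                       rank = seq_along(genes), stringsAsFactors = FALSE),
            class = c("ranked_targets", "data.frame"), drug = drug)
}

#' @export
print.ranked_targets <- function(x, n = 5L, ...) {
  cat(sprintf("<ranked_targets> drug %s, %d candidates; top %d:\n",
              attr(x, "drug"), nrow(x), min(n, nrow(x))))
  print.data.frame(head(as.data.frame(x), n))
  invisible(x)
}

# deterministic within-cell ranks: best value gets rank 1, ties broken
# lexicographically by gene id
.cell_ranks <- function(values, genes, descending = TRUE) {
  key <- if (descending) -values else values
  out <- integer(length(values))
  out[order(key, genes)] <- seq_along(values)
  out
}

#' Rank candidates by a single feature with lowest-rank aggregation
#'
#' Within each cell line, candidates are ranked by the feature; each gene's
#' final score is its minimum (best) rank across cells, and the final
#' ordering sorts that minimum ascending with lexicographic gene-id
#' tie-breaks. This "lowest rank across all cell lines" aggregation lets the
#' best-behaving cell line speak for each candidate.
#'
#' @param table a drug's [assemble_feature_table()].
#' @param feature one of `f_cor`, `f_PC`, `f_DE_mean`, `f_DE_max`.
#' @param direction `"desc"` (default; larger is better) or `"asc"`.
#' @return A [ranked_targets()] whose score is minus the aggregated rank.
#' @export
rank_by_feature <- function(table, feature, direction = c("desc", "asc")) {
  direction <- match.arg(direction)
  if (!feature %in% names(table)) stop("unknown feature: ", feature)
  cells <- sort(unique(table$cell))
  genes <- sort(unique(table$gene))
  minrank <- rep.int(.Machine$integer.max, length(genes))
  for (cell in cells) {
    tb <- table[table$cell == cell, , drop = FALSE]
    r <- .cell_ranks(tb[[feature]], tb$gene, direction == "desc")
    minrank <- pmin(minrank, r[match(genes, tb$gene)])
  }
  ord <- order(minrank, genes)
  ranked_targets(genes[ord], -minrank[ord], attr(table, "drug") %||% table$drug[1L])
}

#' Rank candidates by direct correlation in the most active cell
#'
#' Selects the cell line with the lowest cell-selection feature `f_CS` (the
#' drug's most transcriptionally active cell; lexicographic first on ties)
#' and ranks candidates by descending `f_cor` there alone.
#'
#' @param table a drug's [assemble_feature_table()].
#' @return A [ranked_targets()] scored by `f_cor` in the selected cell.
#' @export
rank_in_active_cell <- function(table) {
  if (!"f_CS" %in% names(table)) stop("feature table lacks f_CS")
  cells <- sort(unique(table$cell))
  cs <- vapply(cells, function(cc) table$f_CS[table$cell == cc][1L],
               numeric(1L))
  active <- cells[which.min(cs)]
  tb <- table[table$cell == active, , drop = FALSE]
  ord <- order(-tb$f_cor, tb$gene)
  ranked_targets(tb$gene[ord], tb$f_cor[ord],
                 attr(table, "drug") %||% table$drug[1L])
}

#' Build labeled training pairs with negative sampling
#'
#' Positives are (drug, known target) pairs whose target lies inside the
#' drug's candidate space; negatives are sampled uniformly from the
#' remaining candidates at `neg_ratio` negatives per positive (a full
#' negative set would swamp the forest). Drugs with no in-frame known
#' target are excluded with a warning.
#'
#' @param tables named list (by drug) of feature tables.
#' @param targets named list mapping drug to character vector of known
#'   target genes.
#' @param neg_ratio negatives sampled per positive (default 50; `Inf` uses
#'   every non-target).
#' @param seed RNG seed for the negative sample.
#' @return data.frame with columns `drug`, `gene`, `label` (1/0).
#' @export
make_training_pairs <- function(tables, targets, neg_ratio = 50, seed = 1) {
  stopifnot(!is.null(names(tables)))
  with_seed(seed, {
    out <- lapply(names(tables), function(d) {
      genes <- sort(unique(tables[[d]]$gene))
      pos <- intersect(targets[[d]] %||% character(0), genes)
      if (!length(pos)) {
        warning("drug ", d, " has no known target in its candidate space; ",
                "excluded from training", call. = FALSE)
        return(NULL)
      }
      pool <- setdiff(genes, targets[[d]])
      n_neg <- if (is.finite(neg_ratio))
        min(length(pool), ceiling(neg_ratio * length(pos))) else length(pool)
      neg <- if (n_neg < length(pool)) sample(pool, n_neg) else pool
      data.frame(drug = d, gene = c(pos, neg),
                 label = rep(c(1L, 0L), c(length(pos), length(neg))),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

# expand (drug, gene) pairs into per-(drug, gene, cell) feature rows
.level1_rows <- function(pairs, tables) {
  sp <- split(pairs, pairs$drug)
  rows <- lapply(names(sp), function(d) {
    tb <- tables[[d]]
    if (is.null(tb)) stop("no feature table for training drug ", d)
    p <- sp[[d]]
    m <- tb[tb$gene %in% p$gene,
            c("drug", "gene", "cell", FEATURE_COLUMNS), drop = FALSE]
    m$label <- p$label[match(m$gene, p$gene)]
    m
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# per-(drug, gene) aggregates of level-1 probabilities: the "best cell wins"
# summary the second forest learns from
.level2_features <- function(rows, p) {
  key <- paste(rows$drug, rows$gene, sep = "\r")
  idx <- split(seq_along(key), factor(key, levels = unique(key)))
  first <- vapply(idx, `[[`, integer(1L), 1L)
  X2 <- cbind(
    max_p = vapply(idx, function(i) max(p[i]), numeric(1L)),
    mean_p = vapply(idx, function(i) mean(p[i]), numeric(1L)),
    n_cells = lengths(idx),
    cs_min = vapply(idx, function(i) min(rows$f_CS[i]), numeric(1L)))
  rownames(X2) <- NULL
  list(drug = rows$drug[first], gene = rows$gene[first], X2 = X2)
}

# per-gene aggregates for the linear baseline: normalized min-rank of each
# ranked feature across cells, plus min f_CS and the localization value
.drug_aggregates <- function(table) {
  cells <- sort(unique(table$cell))
  genes <- sort(unique(table$gene))
  N <- length(genes)
  ranked_feats <- c("f_cor", "f_PC", "f_DE_mean", "f_DE_max")
  agg <- matrix(1, N, length(ranked_feats),
                dimnames = list(genes, paste0("nr_", ranked_feats)))
  cs_min <- rep(Inf, N)
  for (cell in cells) {
    tb <- table[table$cell == cell, , drop = FALSE]
    pos <- match(genes, tb$gene)
    for (j in seq_along(ranked_feats)) {
      r <- .cell_ranks(tb[[ranked_feats[j]]], tb$gene, TRUE)
      agg[, j] <- pmin(agg[, j], (r / N)[pos])
    }
    cs_min <- pmin(cs_min, tb$f_CS[pos])
  }
  f_loc <- table$f_loc[match(genes, table$gene)]
  data.frame(gene = genes, agg, cs_min = cs_min, f_loc = f_loc,
             stringsAsFactors = FALSE)
}

.LR_FEATURES <- c("nr_f_cor", "nr_f_PC", "nr_f_DE_mean", "nr_f_DE_max",
                  "cs_min", "f_loc")

#' Logistic-regression baseline ranker
#'
#' Linear model on per-(drug, gene) aggregates: the normalized minimum rank
#' of each ranked feature across cells, the minimum `f_CS`, and `f_loc`.
#' Aggregation happens before the linear model because a linear score cannot
#' express the min-over-cells nonlinearity itself. Classes are balanced via
#' case weights.
#'
#' @param pairs training pairs from [make_training_pairs()].
#' @param tables named list of feature tables.
#' @param seed RNG seed (kept for interface symmetry; the fit is
#'   deterministic).
#' @return A `trained_ranker` of kind `"logistic"`.
#' @export
train_logistic <- function(pairs, tables, seed = 1) {
  if (is.null(pairs) || !nrow(pairs)) stop("empty training pairs")
  sp <- split(pairs, pairs$drug)
  rows <- lapply(names(sp), function(d) {
    agg <- .drug_aggregates(tables[[d]])
    m <- agg[agg$gene %in% sp[[d]]$gene, , drop = FALSE]
    m$label <- sp[[d]]$label[match(m$gene, sp[[d]]$gene)]
    m
  })
  df <- do.call(rbind, rows)
  if (length(unique(df$label)) < 2L)
    stop("degenerate training set: single class")
  n1 <- sum(df$label == 1L)
  w <- ifelse(df$label == 1L, (nrow(df) - n1) / n1, 1)
  fit <- suppressWarnings(
    glm(reformulate(.LR_FEATURES, "label"), data = df,
        family = binomial(), weights = w))
  structure(list(kind = "logistic", fit = fit, features = .LR_FEATURES,
                 seed = seed),
            class = "trained_ranker")
}

#' Two-level random-forest ranker
#'
#' The pooled architecture: one forest over per-(drug, gene, cell) feature
#' rows from all training drugs yields a per-cell target probability; a
#' second forest over per-(drug, gene) aggregates of those probabilities
#' (max, mean, number of cells, min `f_CS`) produces the final score. The
#' aggregate set lets the model express "the best cell line wins". Drugs
#' profiled in different numbers of cells pool naturally.
#'
#' @inheritParams train_logistic
#' @param n_trees trees per forest level (default 500).
#' @param mtry,max_depth,min_node forest controls, see [random_forest()].
#' @param seed RNG seed; fits are bit-reproducible under the same seed.
#' @return A `trained_ranker` of kind `"rf_two_level"`.
#' @export
train_rf_two_level <- function(pairs, tables, n_trees = 500, mtry = NULL,
                               max_depth = 14, min_node = 10, seed = 1) {
  if (is.null(pairs) || !nrow(pairs)) stop("empty training pairs")
  with_seed(seed, {
    rows <- .level1_rows(pairs, tables)
    X1 <- as.matrix(rows[FEATURE_COLUMNS])
    f1 <- random_forest(X1, rows$label, n_trees = n_trees, mtry = mtry,
                        max_depth = max_depth, min_node = min_node)
    p1 <- predict(f1, X1)
    l2 <- .level2_features(rows, p1)
    y2 <- pairs$label[match(paste(l2$drug, l2$gene, sep = "\r"),
                            paste(pairs$drug, pairs$gene, sep = "\r"))]
    f2 <- random_forest(l2$X2, y2, n_trees = n_trees, mtry = 2,
                        max_depth = max_depth, min_node = min_node)
    structure(list(kind = "rf_two_level", level1 = f1, level2 = f2,
                   features = FEATURE_COLUMNS, n_trees = n_trees,
                   seed = seed),
              class = "trained_ranker")
  })
}

# fixed-length per-gene vectors: the per-cell features concatenated in
# canonical (sorted) cell order; errors if any gene misses a cell
.otf_features <- function(table, cells) {
  miss <- setdiff(cells, unique(table$cell))
  if (length(miss))
    stop("feature table lacks cells: ", paste(miss, collapse = ", "))
  tb <- table[table$cell %in% cells, , drop = FALSE]
  tb <- tb[order(tb$gene, tb$cell), , drop = FALSE]
  genes <- unique(tb$gene)
  cnt <- tabulate(factor(tb$gene, levels = genes))
  if (any(cnt != length(cells)))
    stop("candidate missing one cell's features (no imputation): ",
         genes[cnt != length(cells)][1L])
  fm <- as.matrix(tb[FEATURE_COLUMNS])
  X <- do.call(cbind, lapply(cells, function(cc)
    fm[tb$cell == cc, , drop = FALSE]))
  colnames(X) <- as.vector(outer(FEATURE_COLUMNS, cells, paste, sep = "."))
  rownames(X) <- genes
  X
}

#' On-the-fly (drug-specific) random-forest ranker
#'
#' Trains a single forest for one query drug on the training drugs profiled
#' in (at least) the query's cell set; features are the per-cell rows
#' restricted to the query's cells and concatenated in canonical cell order
#' into fixed-length per-gene vectors. Training drugs profiled in a superset
#' of cells are restricted, not dropped.
#'
#' @param query_drug drug the model is built for.
#' @inheritParams train_rf_two_level
#' @param tables named list of feature tables that must include the query
#'   drug (for its cell set); the query drug itself is never trained on.
#' @return A `trained_ranker` of kind `"rf_on_the_fly"`.
#' @export
train_rf_on_the_fly <- function(query_drug, pairs, tables, n_trees = 500,
                                mtry = NULL, max_depth = 14, min_node = 10,
                                seed = 1) {
  if (is.null(tables[[query_drug]]))
    stop("no feature table for query drug ", query_drug)
  cells_q <- sort(unique(tables[[query_drug]]$cell))
  sp <- split(pairs, pairs$drug)
  sp[[query_drug]] <- NULL
  elig <- names(sp)[vapply(names(sp), function(d)
    all(cells_q %in% unique(tables[[d]]$cell)), logical(1L))]
  if (length(elig) < 2L)
    stop("fewer than 2 training drugs cover the query drug's cell set {",
         paste(cells_q, collapse = ", "),
         "}; fall back to the two-level model")
  blocks <- lapply(elig, function(d) {
    X <- .otf_features(tables[[d]], cells_q)
    keep <- rownames(X) %in% sp[[d]]$gene
    list(X = X[keep, , drop = FALSE],
         y = sp[[d]]$label[match(rownames(X)[keep], sp[[d]]$gene)])
  })
  X <- do.call(rbind, lapply(blocks, `[[`, "X"))
  y <- unlist(lapply(blocks, `[[`, "y"))
  with_seed(seed, {
    f <- random_forest(X, y, n_trees = n_trees, mtry = mtry,
                       max_depth = max_depth, min_node = min_node)
    structure(list(kind = "rf_on_the_fly", forest = f, cells = cells_q,
                   query = query_drug, features = FEATURE_COLUMNS,
                   n_trees = n_trees, seed = seed),
              class = "trained_ranker")
  })
}

#' @export
print.trained_ranker <- function(x, ...) {
  cat(sprintf("<trained_ranker> kind %s (seed %s)\n", x$kind, x$seed))
  invisible(x)
}

#' Score and rank all candidates of a drug
#'
#' Applies a trained ranker to a drug's complete feature table. Candidates
#' are ordered by descending model score; ties break by descending best
#' `f_cor` across cells, then lexicographically by gene id, so the ranking
#' is always a total order.
#'
#' @param model a `trained_ranker`.
#' @param table the query drug's [assemble_feature_table()].
#' @return A [ranked_targets()].
#' @export
predict_ranking <- function(model, table) {
  stopifnot(inherits(model, "trained_ranker"))
  miss <- setdiff(c("gene", "cell", FEATURE_COLUMNS), names(table))
  if (length(miss))
    stop("feature table lacks columns: ", paste(miss, collapse = ", "))
  if (model$kind == "logistic") {
    agg <- .drug_aggregates(table)
    genes <- agg$gene
    scores <- as.numeric(predict(model$fit, newdata = agg,
                                 type = "response"))
  } else if (model$kind == "rf_two_level") {
    p1 <- predict(model$level1, as.matrix(table[FEATURE_COLUMNS]))
    l2 <- .level2_features(table, p1)
    genes <- l2$gene
    scores <- predict(model$level2, l2$X2)
  } else if (model$kind == "rf_on_the_fly") {
    X <- .otf_features(table, model$cells)
    genes <- rownames(X)
    scores <- predict(model$forest, X)
  } else stop("unknown model kind: ", model$kind)

  best_cor <- vapply(split(table$f_cor, table$gene), max, numeric(1L))
  bc <- best_cor[genes]
  ord <- order(-scores, -bc, genes)
  ranked_targets(genes[ord], scores[ord],
                 attr(table, "drug") %||% table$drug[1L])
}

#' Leave-one-out cross-validated rankings
#'
#' For each drug, a model of the requested kind is trained with that drug's
#' examples entirely held out (negatives are re-sampled per fold with a
#' seed derived as `seed + fold`), then applied to the held-out drug's full
#' candidate table. Folds whose training fails are reported in the
#' `failures` attribute and do not abort the remaining folds.
#'
#' @param tables named list (by drug) of feature tables.
#' @param targets named list mapping drug to known target genes.
#' @param model_kind `"rf_two_level"`, `"rf_on_the_fly"` or `"logistic"`.
#' @param neg_ratio negatives per positive for training pairs.
#' @param n_trees forest size (ignored for the logistic baseline).
#' @param seed pipeline seed; per-fold seeds are `seed + fold index`.
#' @param ... passed to the model constructor.
#' @return Named list of [ranked_targets()], one per drug that could be
#'   evaluated, with attribute `failures`.
#' @export
loocv <- function(tables, targets,
                  model_kind = c("rf_two_level", "rf_on_the_fly", "logistic"),
                  neg_ratio = 50, n_trees = 500, seed = 1, ...) {
  model_kind <- match.arg(model_kind)
  drugs <- names(tables)
  if (length(drugs) < 3L) stop("LOOCV needs at least 3 drugs")
  out <- vector("list", length(drugs))
  names(out) <- drugs
  failures <- character(0)
  for (i in seq_along(drugs)) {
    d <- drugs[i]
    res <- tryCatch({
      train_tables <- tables[-i]
      pairs <- suppressWarnings(
        make_training_pairs(train_tables, targets, neg_ratio = neg_ratio,
                            seed = seed + i))
      model <- switch(model_kind,
        rf_two_level = train_rf_two_level(pairs, train_tables,
                                          n_trees = n_trees,
                                          seed = seed + i, ...),
        rf_on_the_fly = train_rf_on_the_fly(d, pairs, tables,
                                            n_trees = n_trees,
                                            seed = seed + i, ...),
        logistic = train_logistic(pairs, train_tables, seed = seed + i))
      predict_ranking(model, tables[[d]])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", d, conditionMessage(res)))
    } else out[[d]] <- res
  }
  out <- Filter(Negate(is.null), out)
  attr(out, "failures") <- failures
  out
}

#' Serialize rankings to TSV
#'
#' @param rankings a [ranked_targets()] or a named list of them.
#' @param path file path.
#' @return `path` (write) or a named list of rankings (read).
#' @export
write_rankings <- function(rankings, path) {
  if (inherits(rankings, "ranked_targets")) {
    rankings <- stats::setNames(list(rankings), attr(rankings, "drug"))
  }
  df <- do.call(rbind, lapply(names(rankings), function(d)
    cbind(drug = d, as.data.frame(rankings[[d]]))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rankings
#' @export
read_rankings <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  sp <- split(df, df$drug)
  out <- lapply(names(sp), function(d) {
    b <- sp[[d]][order(sp[[d]]$rank), , drop = FALSE]
    ranked_targets(b$gene, b$score, d)
  })
  names(out) <- names(sp)
  out
}
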