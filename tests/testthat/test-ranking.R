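# hand-built feature table: values only need the columns a ranker touches
mk_table <- function(drug, genes, cells, f_cor, f_CS = 0, f_PC = 0,
                     f_DE_mean = 0, f_DE_max = 0, f_loc = 0) {
  df <- expand.grid(gene = genes, cell = cells, stringsAsFactors = FALSE)
  df <- df[order(df$gene, df$cell), ]
  df <- data.frame(drug = drug, df, stringsAsFactors = FALSE)
  df$f_cor <- f_cor
  df$f_CS <- if (length(f_CS) == length(cells))
    f_CS[match(df$cell, cells)] else f_CS
  df$f_PC <- f_PC
  df$f_DE_mean <- f_DE_mean
  df$f_DE_max <- f_DE_max
  df$f_loc <- f_loc
  rownames(df) <- NULL
  structure(df, class = c("feature_table", "data.frame"), drug = drug)
}

test_that("rank_by_feature takes each gene's best rank across cells", {
  genes <- paste0("g", 1:4)
  # rows sorted by (gene, cell); cell A order: g1 > g2 > g3 > g4,
  # cell B order: g4 > g3 > g2 > g1
  tab <- mk_table("d", genes, c("A", "B"),
                  f_cor = c(.9, .1, .7, .2, .5, .3, .3, .4))
  rk <- rank_by_feature(tab, "f_cor")
  # min ranks: g1 min(1,4)=1, g2 min(2,3)=2, g3 min(3,2)=2, g4 min(4,1)=1
  expect_identical(rk$gene, c("g1", "g4", "g2", "g3"))
  expect_identical(rk$rank, 1:4)
  expect_equal(rk$score, c(-1, -1, -2, -2))

  # single cell: identical to the per-cell ordering
  tab1 <- mk_table("d", genes, "A", f_cor = c(.9, .7, .5, .3))
  rk1 <- rank_by_feature(tab1, "f_cor")
  expect_identical(rk1$gene, genes)

  # exact ties break lexicographically
  tabt <- mk_table("d", c("b", "a"), "A", f_cor = c(.5, .5))
  rkt <- rank_by_feature(tabt, "f_cor")
  expect_identical(rkt$gene, c("a", "b"))
  expect_error(rank_by_feature(tab, "nope"), "unknown feature")
})

test_that("rank_in_active_cell selects the argmin f_CS cell", {
  genes <- paste0("g", 1:3)
  tab <- mk_table("d", genes, c("A", "B"),
                  f_cor = c(.1, .9, .2, .5, .3, .1), f_CS = c(0.9, 0.2))
  # active cell is B (f_CS 0.2); B-column f_cor: g1 .9, g2 .5, g3 .1
  rk <- rank_in_active_cell(tab)
  expect_identical(rk$gene, c("g1", "g2", "g3"))
  expect_equal(rk$score, c(.9, .5, .1))

  # all-equal f_CS -> lexicographically first cell (A)
  tab2 <- mk_table("d", genes, c("A", "B"),
                   f_cor = c(.1, .9, .2, .5, .3, .1), f_CS = 0.5)
  rk2 <- rank_in_active_cell(tab2)
  expect_identical(rk2$gene[1], "g3")  # A column: g3 .3 > g2 .2 > g1 .1

  tab3 <- mk_table("d", genes, "A", f_cor = c(.3, .2, .1))
  expect_identical(rank_in_active_cell(tab3)$gene,
                   rank_by_feature(tab3, "f_cor")$gene)
})

test_that("training pairs: counts, determinism, full-negative mode", {
  genes <- sprintf("g%03d", 1:150)
  tabs <- list(d1 = mk_table("d1", genes, "A", f_cor = 0))
  targets <- list(d1 = c("g001", "g002"))
  p <- make_training_pairs(tabs, targets, neg_ratio = 50, seed = 4)
  expect_equal(sum(p$label == 1), 2)
  expect_equal(sum(p$label == 0), 100)
  expect_false(any(targets$d1 %in% p$gene[p$label == 0]))

  p2 <- make_training_pairs(tabs, targets, neg_ratio = 50, seed = 4)
  expect_identical(p, p2)
  p3 <- make_training_pairs(tabs, targets, neg_ratio = Inf, seed = 4)
  expect_equal(sum(p3$label == 0), 148)

  expect_warning(
    make_training_pairs(tabs, list(d1 = "not-a-candidate"), seed = 1),
    "no known target")
})

test_that("logistic baseline separates a separable toy set", {
  genes <- sprintf("g%02d", 1:30)
  sep_table <- function(d, target) {
    f <- rep(-0.9, 30)
    f[match(target, genes)] <- 0.9
    mk_table(d, genes, "A", f_cor = f)
  }
  targets <- list(d1 = "g03", d2 = "g11", d3 = "g25", d4 = "g07")
  tabs <- list(d1 = sep_table("d1", "g03"), d2 = sep_table("d2", "g11"),
               d3 = sep_table("d3", "g25"), d4 = sep_table("d4", "g07"))
  pairs <- make_training_pairs(tabs[1:3], targets, neg_ratio = 10, seed = 9)
  m <- train_logistic(pairs, tabs[1:3])
  rk <- predict_ranking(m, tabs$d4)
  expect_identical(rk$gene[1], "g07")
  expect_gt(min(rk$score[rk$gene == "g07"]), max(rk$score[rk$gene != "g07"]))

  # duplicated training rows leave the decision ordering unchanged
  m_dup <- train_logistic(rbind(pairs, pairs), tabs[1:3])
  expect_identical(predict_ranking(m_dup, tabs$d4)$gene, rk$gene)

  # degenerate single-class input
  pos_only <- pairs[pairs$label == 1, ]
  expect_error(train_logistic(pos_only, tabs[1:3]), "single class")
})

test_that("label permutation drives held-out AUC to chance", {
  b <- small_benchmark()
  tabs <- small_tables()
  aucs <- vapply(1:8, function(s) {
    perm <- withr::with_seed(s, sample(names(b$targets)))
    fake <- setNames(b$targets[perm], names(b$targets))
    cv <- suppressWarnings(loocv(tabs, fake, "logistic", neg_ratio = 20,
                                 seed = s))
    evaluation_report(cv, fake)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("two-level RF pools heterogeneous cell counts and is seeded", {
  b <- small_benchmark()
  tabs <- small_tables()
  # restrict half the drugs to 2 of the 3 cells: pooling must still work
  tabs_het <- tabs
  for (d in names(tabs)[1:12]) {
    tb <- tabs[[d]]
    tabs_het[[d]] <- structure(tb[tb$cell != "CELL3", ],
                               class = class(tb), drug = d)
  }
  pairs <- make_training_pairs(tabs_het, b$targets, neg_ratio = 15, seed = 2)
  m <- train_rf_two_level(pairs, tabs_het, n_trees = 60, seed = 2)
  rk <- predict_ranking(m, tabs_het[[1]])
  expect_identical(rk$rank, seq_len(nrow(rk)))

  m2 <- train_rf_two_level(pairs, tabs_het, n_trees = 60, seed = 2)
  rk2 <- predict_ranking(m2, tabs_het[[1]])
  expect_identical(as.data.frame(rk), as.data.frame(rk2))
})

test_that("on-the-fly RF restricts to the query's cell set", {
  b <- small_benchmark()
  tabs <- small_tables()
  query <- names(tabs)[1]
  # training drugs in a cell superset are usable (restricted, not dropped)
  tabs_mix <- tabs
  for (d in names(tabs)[2:6]) {
    tb <- tabs[[d]]
    tabs_mix[[d]] <- structure(tb[tb$cell != "CELL3", ],
                               class = class(tb), drug = d)
  }
  q_tb <- tabs_mix[[query]]
  tabs_mix[[query]] <- structure(q_tb[q_tb$cell != "CELL3", ],
                                 class = class(q_tb), drug = query)
  pairs <- make_training_pairs(tabs_mix, b$targets, neg_ratio = 10, seed = 5)
  m <- train_rf_on_the_fly(query, pairs, tabs_mix, n_trees = 50, seed = 5)
  expect_identical(m$cells, c("CELL1", "CELL2"))
  rk <- predict_ranking(m, tabs_mix[[query]])
  expect_identical(rk$rank, seq_len(nrow(rk)))

  # no training drug covers the query cell set -> explicit error
  solo <- tabs_mix
  for (d in setdiff(names(solo), query)) {
    tb <- solo[[d]]
    solo[[d]] <- structure(tb[tb$cell == "CELL1", ], class = class(tb),
                           drug = d)
  }
  full_q <- tabs[[query]]  # query back at 3 cells
  solo[[query]] <- full_q
  expect_error(train_rf_on_the_fly(query, pairs, solo, n_trees = 10),
               "two-level")
})

test_that("prediction ties cascade score -> best f_cor -> gene id", {
  b <- small_benchmark()
  tabs <- small_tables()
  pairs <- make_training_pairs(tabs, b$targets, neg_ratio = 10, seed = 3)
  m <- train_logistic(pairs, tabs)
  m$fit$coefficients[] <- 0  # constant model: everything ties at 0.5
  rk <- predict_ranking(m, tabs[[2]])
  tb <- tabs[[2]]
  best_cor <- vapply(split(tb$f_cor, tb$gene), max, numeric(1))
  expected <- names(best_cor)[order(-best_cor, names(best_cor))]
  expect_identical(rk$gene, expected)
})

test_that("incomplete feature rows are refused, not imputed", {
  b <- small_benchmark()
  tabs <- small_tables()
  pairs <- make_training_pairs(tabs, b$targets, neg_ratio = 10, seed = 7)
  m <- train_rf_on_the_fly(names(tabs)[1], pairs, tabs, n_trees = 30,
                           seed = 7)
  broken <- tabs[[1]][-5, ]  # drop one (gene, cell) row
  expect_error(predict_ranking(m, broken), "no imputation")
  expect_error(predict_ranking(m, tabs[[1]][, -4]), "lacks columns")
})

test_that("LOOCV holds each drug out of its own fold", {
  b <- small_benchmark()
  tabs <- small_tables()[1:6]
  assign(".loocv_seen", list(), envir = globalenv())
  suppressMessages(trace(".level1_rows", where = asNamespace("targetrank"),
    tracer = quote(assign(".loocv_seen",
                          c(get(".loocv_seen", envir = globalenv()),
                            list(unique(pairs$drug))), envir = globalenv())),
    print = FALSE))
  on.exit({
    suppressMessages(untrace(".level1_rows",
                             where = asNamespace("targetrank")))
    rm(".loocv_seen", envir = globalenv())
  })
  cv <- loocv(tabs, b$targets, "rf_two_level", neg_ratio = 10,
              n_trees = 20, seed = 6)
  expect_length(attr(cv, "failures"), 0)
  expect_length(cv, 6)
  drugs <- names(tabs)
  folds <- get(".loocv_seen", envir = globalenv())
  expect_length(folds, 6)
  for (i in seq_along(drugs)) {
    expect_false(drugs[i] %in% folds[[i]])
  }
  # each ranking covers the drug's full candidate space
  for (d in drugs)
    expect_setequal(cv[[d]]$gene, unique(tabs[[d]]$gene))
})

test_that("rankings serialize and re-rank idempotently", {
  b <- small_benchmark()
  tabs <- small_tables()
  rks <- lapply(tabs[1:3], rank_by_feature, feature = "f_cor")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rankings(rks, path)
  back <- read_rankings(path)
  for (d in names(rks)) {
    expect_identical(back[[d]]$gene, rks[[d]]$gene)
    expect_identical(back[[d]]$rank, rks[[d]]$rank)
  }
  expect_error(ranked_targets(c("a", "b"), c(0.1, 0.5)), "non-increasing")
  expect_error(ranked_targets(c("a", "a"), c(1, 0)), "duplicate")
})
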