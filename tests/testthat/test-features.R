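# helper: one-cell compendium with fully controlled drug/control columns
fixed_compendium <- function(drug_z, ctl_z, kd_z, genes = NULL) {
  genes <- genes %||% sprintf("g%02d", seq_along(drug_z))
  z <- cbind(KD_g01_A_r1 = kd_z, TRT_d_A = drug_z)
  colnames_extra <- character(0)
  meta <- data.frame(
    sample_id = c("KD_g01_A_r1", "TRT_d_A"),
    perturbagen_id = c("shg01", "d"),
    pert_type = c("kd", "drug"),
    cell_line = "A", kd_gene = c("g01", ""))
  if (!is.null(ctl_z)) {
    ctl_z <- as.matrix(ctl_z)
    colnames(ctl_z) <- sprintf("CTL_A_%d", seq_len(ncol(ctl_z)))
    z <- cbind(z, ctl_z)
    meta <- rbind(meta, data.frame(
      sample_id = colnames(ctl_z), perturbagen_id = "DMSO",
      pert_type = "control", cell_line = "A", kd_gene = ""))
  }
  rownames(z) <- genes
  list(sig = signature_matrix(z), meta = sample_meta(meta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pearson_cor matches hand values and rejects degenerate input", {
  expect_equal(pearson_cor(1:4, 1:4), 1.0)
  expect_equal(pearson_cor(1:4, -(1:4)), -1.0)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 2, 3, 5)), 0.9827,
               tolerance = 1e-4)
  expect_error(pearson_cor(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(pearson_cor(1:3, 1:4), "length mismatch")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("pearson_cor agrees with the textbook formula on random pairs", {
  set.seed(99)
  for (i in 1:100) {
    x <- rnorm(20)
    y <- rnorm(20)
    expect_equal(pearson_cor(x, y), pearson_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("direct correlation: identity, projection-orthogonal, scale", {
  set.seed(5)
  kd <- rnorm(12)
  cmp <- fixed_compendium(drug_z = kd, ctl_z = NULL, kd_z = kd)
  expect_equal(direct_correlation("d", "g01", "A", cmp$sig, cmp$meta), 1.0)

  x <- rnorm(12)
  x_orth <- x - (cov(x, kd) / var(kd)) * kd
  cmp2 <- fixed_compendium(drug_z = x_orth, ctl_z = NULL, kd_z = kd)
  expect_equal(direct_correlation("d", "g01", "A", cmp2$sig, cmp2$meta), 0,
               tolerance = 1e-12)

  cmp3 <- fixed_compendium(drug_z = 0.8 * kd, ctl_z = NULL, kd_z = kd)
  expect_equal(direct_correlation("d", "g01", "A", cmp3$sig, cmp3$meta), 1.0)

  expect_error(direct_correlation("d", "g99", "A", cmp$sig, cmp$meta),
               "missing kd signature")
})

test_that("top_correlated_kds sorts, caps at the pool and breaks ties", {
  cmp <- tiny_compendium()
  cache <- consensus_cache(cmp$sig, cmp$meta)
  top_all <- top_correlated_kds("drugX", "A", X = 100, cache = cache,
                                candidates = cmp$kd_genes)
  expect_setequal(top_all, cmp$kd_genes)
  top1 <- top_correlated_kds("drugX", "A", X = 1, cache = cache,
                             candidates = cmp$kd_genes)
  expect_identical(top1, top_all[1])
  expect_error(top_correlated_kds("drugX", "A", X = 0, cache = cache),
               "positive")

  # exact tie: duplicated KD consensus -> lexicographic gene order
  z <- cmp$sig$z
  dup <- z[, "KD_g02_A_r1"]
  z[, "KD_g03_A_r1"] <- dup
  z[, "KD_g03_A_r2"] <- z[, "KD_g02_A_r2"]
  sig2 <- signature_matrix(z)
  cache2 <- consensus_cache(sig2, cmp$meta)
  top2 <- top_correlated_kds("drugX", "A", X = 3, cache = cache2,
                             candidates = cmp$kd_genes)
  expect_lt(match("g02", top2), match("g03", top2))
})

test_that("indirect correlation matches the fold-enrichment rule", {
  net <- toy_network()
  cands <- c("a", "b", "c", "d", "H", paste0("x", 1:15))
  expect_equal(indirect_correlation("H", net, top_list = c("a", "b", "x1",
                                                           "x2", "x3"),
                                    X = 5, N = 20, candidates = cands), 2.0)
  expect_equal(indirect_correlation("x1", net, top_list = c("a", "b"),
                                    X = 5, N = 20, candidates = cands), 0)
  expect_equal(indirect_correlation("H", net,
                                    top_list = c("a", "b", "c", "d", "x1"),
                                    X = 5, N = 20, candidates = cands),
               20 / 5)
  expect_equal(indirect_correlation("absent-gene", net, top_list = "a",
                                    X = 5, N = 20, candidates = cands), 0)
  expect_error(indirect_correlation("H", net, "a", X = 5, N = 0), "positive")
  # difference form
  expect_equal(indirect_correlation("H", net, top_list = c("a", "b", "x1",
                                                           "x2", "x3"),
                                    X = 5, N = 20, candidates = cands,
                                    form = "difference"), 0.5 - 0.25)
})

test_that("cell selection averages drug-control correlations", {
  set.seed(7)
  kd <- rnorm(12)
  ctl <- rnorm(12)
  cmp <- fixed_compendium(drug_z = ctl, ctl_z = ctl, kd_z = kd)
  expect_equal(cell_selection("d", "A", cmp$sig, cmp$meta), 1.0)

  x <- rnorm(12)
  x_orth <- x - (cov(x, ctl) / var(ctl)) * ctl
  cmp2 <- fixed_compendium(drug_z = x_orth, ctl_z = ctl, kd_z = kd)
  expect_equal(cell_selection("d", "A", cmp2$sig, cmp2$meta), 0,
               tolerance = 1e-12)

  drug <- rnorm(12)
  ctl2 <- cbind(rnorm(12), rnorm(12))
  cmp3 <- fixed_compendium(drug_z = drug, ctl_z = ctl2, kd_z = kd)
  expect_equal(cell_selection("d", "A", cmp3$sig, cmp3$meta),
               mean(c(pearson_oracle(drug, ctl2[, 1]),
                      pearson_oracle(drug, ctl2[, 2]))))

  expect_error(cell_selection("d", "A", cmp$sig,
                              sample_meta(cmp$meta[cmp$meta$pert_type !=
                                                     "control", ])),
               "no control")
})

test_that("partner expression features take |Z| then mean/max", {
  # H has exactly the three measured partners a, b, c here
  net <- ppi_network(rbind(c("H", "a"), c("H", "b"), c("H", "c")))
  drug_z <- rep(0, 10)
  genes <- c("a", "b", "c", "d", "H", paste0("f", 1:5))
  drug_z[1:3] <- c(-3, 1, 2)
  kd <- rnorm(10)
  cmp <- fixed_compendium(drug_z = drug_z, ctl_z = NULL, kd_z = kd,
                          genes = genes)
  got <- partner_expression_features("d", "H", "A", net, cmp$sig, cmp$meta)
  expect_equal(unname(got), c(2, 3))

  # gene with no measured partners
  got0 <- partner_expression_features("d", "f1", "A", net, cmp$sig, cmp$meta)
  expect_equal(unname(got0), c(0, 0))

  # single partner with negative Z
  net2 <- ppi_network(rbind(c("f1", "a")))
  drug_z2 <- rep(0, 10)
  drug_z2[1] <- -4
  cmp2 <- fixed_compendium(drug_z = drug_z2, ctl_z = NULL, kd_z = kd,
                           genes = genes)
  expect_equal(unname(partner_expression_features("d", "f1", "A", net2,
                                                  cmp2$sig, cmp2$meta)),
               c(4, 4))
})

test_that("localization encoding is +1 / -1 / 0", {
  locmap <- data.frame(gene = c("in1", "tm1", "ex1", "un1"),
                       localization = c("intracellular", "transmembrane",
                                        "extracellular", "unknown"))
  expect_equal(localization_feature(c("in1", "tm1", "ex1", "un1", "new"),
                                    locmap),
               c(1, -1, -1, 0, 0))
})

test_that("feature table is a complete, deterministic block", {
  cmp <- tiny_compendium()
  net <- toy_network()
  locmap <- data.frame(gene = c("g01", "g02"),
                       localization = c("intracellular", "transmembrane"))
  space <- build_candidate_space(cmp$meta, "drugX")
  tab <- assemble_feature_table("drugX", space, cmp$sig, cmp$meta,
                                network = net, locmap = locmap, X = 2)
  expect_equal(nrow(tab), 3 * 2)
  expect_true(all(is.finite(as.matrix(tab[targetrank:::FEATURE_COLUMNS]))))
  # f_CS depends only on the cell
  expect_equal(length(unique(tab$f_CS[tab$cell == "A"])), 1L)
  # deterministic under permuted inputs
  perm_s <- sample(ncol(cmp$sig$z))
  perm_g <- sample(nrow(cmp$sig$z))
  sig2 <- signature_matrix(cmp$sig$z[perm_g, perm_s])
  meta2 <- sample_meta(as.data.frame(cmp$meta)[sample(nrow(cmp$meta)), ])
  tab2 <- assemble_feature_table("drugX", space, sig2, meta2,
                                 network = net, locmap = locmap, X = 2)
  expect_equal(as.data.frame(tab), as.data.frame(tab2))
})

test_that("feature ranges hold on a generated benchmark (property)", {
  tabs <- small_tables()
  for (tab in tabs[1:5]) {
    expect_true(all(tab$f_cor >= -1 & tab$f_cor <= 1))
    expect_true(all(tab$f_CS >= -1 & tab$f_CS <= 1))
    expect_true(all(tab$f_PC >= 0))
    expect_true(all(tab$f_DE_mean >= 0 & tab$f_DE_mean <= tab$f_DE_max))
    expect_true(all(tab$f_loc %in% c(-1, 0, 1)))
  }
})

test_that("feature tables round-trip through TSV", {
  tab <- small_tables()[[1]]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab), tolerance = 1e-9,
               ignore_attr = TRUE)
})
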