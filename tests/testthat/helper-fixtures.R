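# Small in-code fixtures shared across test files.

# tiny deterministic compendium: 2 cells, 3 KD genes (2 replicates each),
# 2 drugs, 2 controls per cell, 10 landmark genes
tiny_compendium <- function(seed = 101) {
  set.seed(seed)
  genes <- sprintf("g%02d", 1:10)
  cells <- c("A", "B")
  kd_genes <- c("g01", "g02", "g03")
  cols <- list()
  meta <- list()
  for (cc in cells) {
    for (g in kd_genes) {
      for (r in 1:2) {
        id <- sprintf("KD_%s_%s_r%d", g, cc, r)
        z <- rnorm(10)
        z[match(g, genes)] <- -5
        cols[[id]] <- z
        meta[[id]] <- data.frame(sample_id = id,
                                 perturbagen_id = paste0("sh", g),
                                 pert_type = "kd", cell_line = cc,
                                 kd_gene = g)
      }
    }
    for (d in c("drugX", "drugY")) {
      id <- sprintf("TRT_%s_%s", d, cc)
      cols[[id]] <- rnorm(10)
      meta[[id]] <- data.frame(sample_id = id, perturbagen_id = d,
                               pert_type = "drug", cell_line = cc,
                               kd_gene = "")
    }
    for (r in 1:2) {
      id <- sprintf("CTL_%s_%d", cc, r)
      cols[[id]] <- rnorm(10)
      meta[[id]] <- data.frame(sample_id = id, perturbagen_id = "DMSO",
                               pert_type = "control", cell_line = cc,
                               kd_gene = "")
    }
  }
  z <- do.call(cbind, cols)
  rownames(z) <- genes
  list(sig = signature_matrix(z),
       meta = sample_meta(do.call(rbind, meta)),
       genes = genes, cells = cells, kd_genes = kd_genes)
}

# star + chain toy network: H hub of 4; chain g01-g02-g03
toy_network <- function() {
  ppi_network(rbind(c("H", "a"), c("H", "b"), c("H", "c"), c("H", "d"),
                    c("g01", "g02"), c("g02", "g03")))
}

# textbook Pearson formula, independent of stats::cor
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# small synthetic benchmark reused by several test files (cached per session)
small_benchmark <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_genes = 240, n_kd_genes = 80, n_cells = 3,
                               n_drugs = 24, n_replicates = 2, seed = 2024)
      cache <<- generate_benchmark(cfg)
    }
    cache
  }
})

small_tables <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- benchmark_feature_tables(small_benchmark(), X = 20)
    cache
  }
})

best_ranks_of <- function(rankings, targets) {
  vapply(names(rankings), function(d)
    best_target_rank(rankings[[d]], targets[[d]]), integer(1L))
}
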