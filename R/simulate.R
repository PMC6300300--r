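# Synthetic L1000-like benchmark generator. Plants drug-target structure of
# two kinds: "direct" drugs whose treatment signature is an attenuated copy
# of the target's knockdown consensus, and "indirect" drugs whose signature
# instead tracks the mean knockdown consensus of the target's interaction
# partners (the pathway-level dissociation the indirect feature exploits).
# All randomness flows from one seed through fixed per-stage offsets.

.SEED_NET <- 11L
.SEED_KD <- 23L
.SEED_TRUTH <- 37L
.SEED_DRUGS <- 53L
.SEED_CONTROLS <- 71L
.SEED_LOC <- 89L

#' Simulation configuration
#'
#' Parameters of the synthetic compendium. Defaults describe the standard
#' benchmark world: a 978-landmark-gene assay, 500 knocked-down genes in 4
#' cell lines, 200 drugs, direct effect strength 0.8 and perturbation noise
#' 0.5 (Z-score units).
#'
#' @param n_genes landmark dimension (default 978).
#' @param n_kd_genes number of genes with knockdown profiles (default 500);
#'   they occupy the first landmark slots so a knockdown's self-effect is
#'   measurable.
#' @param n_cells number of cell lines (default 4).
#' @param n_drugs number of drugs (default 200).
#' @param n_controls_per_cell control samples per cell (default 5).
#' @param direct_strength alpha in \[0, 1\]: weight of the target knockdown
#'   consensus in an active direct-mode drug signature (default 0.8).
#' @param indirect_strength beta in \[0, 1\]: attenuation of knockdown
#'   effects on network neighbours, and the weight of the neighbour-mean
#'   consensus for indirect-mode drugs (default 0.5).
#' @param noise_sd sigma: independent Gaussian noise on perturbation
#'   signatures, Z-score units (default 0.5).
#' @param baseline_sd per-(cell, gene) baseline shift scale (default 0.3;
#'   0 disables cell identity).
#' @param self_effect Z-score of a knockdown at its own transcript
#'   (default -5, i.e. strong silencing).
#' @param activity_prob probability a drug is transcriptionally active in a
#'   given cell (default 0.75; at least one active cell is enforced).
#' @param mode_mix fraction of direct-mode drugs (default 0.5).
#' @param attachment_m preferential-attachment degree of the synthetic
#'   interaction network (default 2).
#' @param n_replicates knockdown replicates per (gene, cell) (default 2).
#' @param seed master seed; stage streams are derived from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 978, n_kd_genes = 500, n_cells = 4,
                              n_drugs = 200, n_controls_per_cell = 5,
                              direct_strength = 0.8, indirect_strength = 0.5,
                              noise_sd = 0.5, baseline_sd = 0.3,
                              self_effect = -5, activity_prob = 0.75,
                              mode_mix = 0.5, attachment_m = 2,
                              n_replicates = 2, seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_kd_genes = as.integer(n_kd_genes),
              n_cells = as.integer(n_cells), n_drugs = as.integer(n_drugs),
              n_controls_per_cell = as.integer(n_controls_per_cell),
              direct_strength = direct_strength,
              indirect_strength = indirect_strength, noise_sd = noise_sd,
              baseline_sd = baseline_sd, self_effect = self_effect,
              activity_prob = activity_prob, mode_mix = mode_mix,
              attachment_m = as.integer(attachment_m),
              n_replicates = as.integer(n_replicates),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes > 0, n_kd_genes >= 3, n_kd_genes <= n_genes,
              n_cells > 0, n_drugs >= 0, n_controls_per_cell > 0,
              n_replicates > 0, attachment_m >= 1,
              direct_strength >= 0, direct_strength <= 1,
              indirect_strength >= 0, indirect_strength <= 1,
              activity_prob >= 0, activity_prob <= 1,
              mode_mix >= 0, mode_mix <= 1,
              noise_sd >= 0, baseline_sd >= 0)
  })
  structure(cfg, class = "simulation_config")
}

.kd_gene_names <- function(cfg) sprintf("G%04d", seq_len(cfg$n_kd_genes))
.landmark_names <- function(cfg)
  c(.kd_gene_names(cfg),
    sprintf("L%04d", seq_len(cfg$n_genes - cfg$n_kd_genes) + cfg$n_kd_genes))
.cell_names <- function(cfg) sprintf("CELL%d", seq_len(cfg$n_cells))

#' Generate a scale-free-like interaction network
#'
#' Preferential attachment over the knockdown genes: the first two nodes are
#' connected, and each subsequent node attaches to `min(m, existing)`
#' distinct earlier nodes with probability proportional to their degree.
#' With `m = 2` this yields exactly `2n - 3` edges and a connected graph.
#'
#' @param config a [simulation_config()].
#' @return A [ppi_network()] over the knockdown genes.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_kd_genes
  m <- config$attachment_m
  genes <- .kd_gene_names(config)
  with_seed(config$seed + .SEED_NET, {
    deg <- integer(n)
    from <- integer(0)
    to <- integer(0)
    deg[1:2] <- 1L
    from <- 1L
    to <- 2L
    for (i in seq_len(n)[-(1:2)]) {
      k <- min(m, i - 1L)
      tgt <- sample.int(i - 1L, k, prob = deg[seq_len(i - 1L)])
      from <- c(from, rep.int(i, k))
      to <- c(to, tgt)
      deg[i] <- k
      deg[tgt] <- deg[tgt] + 1L
    }
    ppi_network(cbind(genes[from], genes[to]))
  })
}

#' Generate knockdown signatures
#'
#' Per (knockdown gene, cell, replicate): a strong negative Z at the gene's
#' own landmark slot, attenuated effects (`indirect_strength` times the
#' self-effect) at its network neighbours' slots, a per-(cell, gene)
#' baseline shift shared with every sample of that cell, and independent
#' Gaussian noise.
#'
#' @param network the knockdown-gene [ppi_network()].
#' @param config a [simulation_config()].
#' @return List with `sig` ([signature_matrix()]), `meta`
#'   ([sample_meta()]), `baseline` (genes x cells matrix) and `effects`
#'   (genes x KD-genes pure effect matrix).
#' @export
generate_kd_signatures <- function(network, config) {
  stopifnot(inherits(config, "simulation_config"))
  genes <- .landmark_names(config)
  kd_genes <- .kd_gene_names(config)
  cells <- .cell_names(config)
  G <- config$n_genes

  effects <- matrix(0, G, length(kd_genes),
                    dimnames = list(genes, kd_genes))
  for (g in kd_genes) {
    effects[g, g] <- config$self_effect
    nb <- ppi_partners(network, g)
    effects[nb, g] <- config$indirect_strength * config$self_effect
  }

  with_seed(config$seed + .SEED_KD, {
    baseline <- matrix(rnorm(G * config$n_cells, 0, config$baseline_sd),
                       G, config$n_cells, dimnames = list(genes, cells))
    rep_idx <- rep(seq_along(kd_genes), each = config$n_replicates)
    blocks <- lapply(cells, function(cc) {
      z <- effects[, rep_idx, drop = FALSE] + baseline[, cc] +
        rnorm(G * length(rep_idx), 0, config$noise_sd)
      colnames(z) <- sprintf("KD_%s_%s_r%d", kd_genes[rep_idx], cc,
                             rep(seq_len(config$n_replicates),
                                 times = length(kd_genes)))
      z
    })
    z <- do.call(cbind, blocks)
    meta <- sample_meta(data.frame(
      sample_id = colnames(z),
      perturbagen_id = paste0("sh", rep(kd_genes[rep_idx],
                                        times = length(cells))),
      pert_type = "kd",
      cell_line = rep(cells, each = length(rep_idx)),
      kd_gene = rep(kd_genes[rep_idx], times = length(cells)),
      stringsAsFactors = FALSE))
    list(sig = signature_matrix(z, genes, colnames(z)), meta = meta,
         baseline = baseline, effects = effects)
  })
}

#' Generate the planted truth
#'
#' Assigns each drug a planted target (uniform over knockdown genes), a
#' mode (direct with probability `mode_mix`, else indirect) and a
#' non-empty active cell set (each cell active with `activity_prob`; one
#' active cell is forced when the draw is empty).
#'
#' @param config a [simulation_config()].
#' @return data.frame with columns `drug`, `target`, `mode`,
#'   `active_cells` (comma-separated).
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  kd_genes <- .kd_gene_names(config)
  cells <- .cell_names(config)
  if (config$n_drugs == 0L) {
    warning("n_drugs = 0: empty drug set")
    return(data.frame(drug = character(0), target = character(0),
                      mode = character(0), active_cells = character(0)))
  }
  with_seed(config$seed + .SEED_TRUTH, {
    drugs <- sprintf("DRUG%03d", seq_len(config$n_drugs))
    target <- sample(kd_genes, config$n_drugs, replace = TRUE)
    mode <- ifelse(runif(config$n_drugs) < config$mode_mix,
                   "direct", "indirect")
    active <- vapply(seq_len(config$n_drugs), function(i) {
      on <- runif(config$n_cells) < config$activity_prob
      # a drug inactive everywhere is unobservable; force one active cell
      # unless activity was explicitly switched off entirely
      if (!any(on) && config$activity_prob > 0)
        on[sample.int(config$n_cells, 1L)] <- TRUE
      paste(cells[on], collapse = ",")
    }, character(1L))
    data.frame(drug = drugs, target = target, mode = mode,
               active_cells = active, stringsAsFactors = FALSE)
  })
}

#' Generate drug-treatment and control signatures
#'
#' An active direct-mode drug in a cell is `alpha` times the target's
#' knockdown consensus plus noise; an active indirect-mode drug is `beta`
#' times the mean consensus of the target's network neighbours plus noise
#' (zero direct term, producing the clean direct/indirect dissociation).
#' In inactive cells the drug signature is control-like: baseline plus
#' unit-variance noise, as are the control samples themselves.
#'
#' @param kd a [generate_kd_signatures()] bundle.
#' @param truth a [generate_truth()] table.
#' @param network the knockdown [ppi_network()].
#' @param config a [simulation_config()].
#' @return List with `sig` and `meta` covering drug and control samples.
#' @export
generate_drug_signatures <- function(kd, truth, network, config) {
  stopifnot(inherits(config, "simulation_config"))
  cells <- .cell_names(config)
  G <- config$n_genes
  bad <- setdiff(truth$target, colnames(kd$effects))
  if (length(bad))
    stop("truth references unknown gene: ", paste(bad, collapse = ", "))

  cache <- consensus_cache(kd$sig, kd$meta)
  active_sets <- strsplit(truth$active_cells, ",", fixed = TRUE)

  drug_part <- with_seed(config$seed + .SEED_DRUGS, {
    cols <- list()
    ids <- character(0)
    cell_of <- character(0)
    drug_of <- character(0)
    for (i in seq_len(nrow(truth))) {
      tgt <- truth$target[i]
      nb <- ppi_partners(network, tgt)
      for (cc in cells) {
        if (cc %in% active_sets[[i]]) {
          cons <- cache$by_cell[[cc]]$kd
          base <- if (truth$mode[i] == "direct") {
            config$direct_strength * cons[, tgt]
          } else {
            config$indirect_strength *
              rowMeans(cons[, nb, drop = FALSE])
          }
          z <- base + rnorm(G, 0, config$noise_sd)
        } else {
          z <- kd$baseline[, cc] + rnorm(G, 0, 1)
        }
        cols[[length(cols) + 1L]] <- z
        ids <- c(ids, sprintf("TRT_%s_%s", truth$drug[i], cc))
        cell_of <- c(cell_of, cc)
        drug_of <- c(drug_of, truth$drug[i])
      }
    }
    list(z = if (length(cols)) do.call(cbind, cols) else
           matrix(numeric(0), G, 0),
         ids = ids, cell = cell_of, drug = drug_of)
  })

  ctl_part <- with_seed(config$seed + .SEED_CONTROLS, {
    nc <- config$n_controls_per_cell
    z <- do.call(cbind, lapply(cells, function(cc)
      kd$baseline[, cc] + matrix(rnorm(G * nc), G, nc)))
    ids <- as.vector(vapply(cells, function(cc)
      sprintf("CTL_%s_%d", cc, seq_len(nc)), character(nc)))
    list(z = z, ids = ids, cell = rep(cells, each = nc))
  })

  z <- cbind(drug_part$z, ctl_part$z)
  ids <- c(drug_part$ids, ctl_part$ids)
  colnames(z) <- ids
  meta <- sample_meta(data.frame(
    sample_id = ids,
    perturbagen_id = c(drug_part$drug,
                       rep("DMSO", length(ctl_part$ids))),
    pert_type = rep(c("drug", "control"),
                    c(length(drug_part$ids), length(ctl_part$ids))),
    cell_line = c(drug_part$cell, ctl_part$cell),
    kd_gene = "",
    stringsAsFactors = FALSE))
  list(sig = signature_matrix(z, kd$sig$gene_ids, ids), meta = meta)
}

#' Generate a complete synthetic benchmark
#'
#' Runs the full generator: network, knockdown compendium, planted truth,
#' drug and control signatures, a random localization map and the
#' drug-to-target annotation implied by the truth. The result feeds every
#' pipeline stage without touching disk; [write_benchmark()] emits the
#' on-disk input set (truth in a separate file).
#'
#' @param config a [simulation_config()].
#' @return List with `signatures`, `meta`, `network`, `truth`, `targets`
#'   (named list), `locmap` and `config`.
#' @export
generate_benchmark <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  network <- generate_network(config)
  kd <- generate_kd_signatures(network, config)
  truth <- generate_truth(config)
  dr <- generate_drug_signatures(kd, truth, network, config)
  z <- cbind(kd$sig$z, dr$sig$z)
  sig <- signature_matrix(z, kd$sig$gene_ids, colnames(z))
  meta <- sample_meta(rbind(as.data.frame(kd$meta), as.data.frame(dr$meta)))
  locmap <- with_seed(config$seed + .SEED_LOC, {
    data.frame(gene = .kd_gene_names(config),
               localization = sample(
                 c("intracellular", "transmembrane", "extracellular",
                   "unknown"),
                 config$n_kd_genes, replace = TRUE,
                 prob = c(0.5, 0.2, 0.1, 0.2)),
               stringsAsFactors = FALSE)
  })
  targets <- setNames(as.list(truth$target), truth$drug)
  list(signatures = sig, meta = meta, network = network, truth = truth,
       targets = targets, locmap = locmap, config = config)
}

#' Write a benchmark bundle to disk
#'
#' Emits the formats the readers consume: `signatures.gct` (GCT 1.2),
#' `sample_meta.tsv`, `ppi.tsv`, `targets.tsv`, `localization.tsv`, and the
#' withheld `truth.tsv`.
#'
#' @param bundle a [generate_benchmark()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gct(bundle$signatures, p("signatures.gct"))
  write_sample_meta(bundle$meta, p("sample_meta.tsv"))
  write.table(bundle$network$edges, p("ppi.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(drug = rep(names(bundle$targets),
                                    lengths(bundle$targets)),
                         target = unlist(bundle$targets)),
              p("targets.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$locmap, p("localization.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(bundle$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Assemble feature tables for all drugs of a benchmark
#'
#' Convenience wrapper: builds a shared [consensus_cache()], derives each
#' drug's candidate space and assembles its feature table.
#'
#' @param bundle a [generate_benchmark()] result (or any list with
#'   `signatures`, `meta`, `network`, `locmap`).
#' @param X top-list size for the indirect feature (default 100).
#' @param drugs drugs to process; defaults to all drugs in the metadata.
#' @return Named list of feature tables.
#' @export
benchmark_feature_tables <- function(bundle, X = 100, drugs = NULL) {
  meta <- bundle$meta
  drugs <- drugs %||%
    sort(unique(meta$perturbagen_id[meta$pert_type == "drug"]))
  cache <- consensus_cache(bundle$signatures, meta)
  out <- lapply(drugs, function(d) {
    space <- build_candidate_space(meta, d)
    assemble_feature_table(d, space, network = bundle$network,
                           locmap = bundle$locmap, X = X, cache = cache)
  })
  names(out) <- drugs
  out
}
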