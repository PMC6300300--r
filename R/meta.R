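#' Sample metadata table
#'
#' Validates per-sample metadata for a signature compendium. Each row
#' describes one profiled sample: the perturbagen applied (`perturbagen_id`,
#' a drug identifier or an shRNA construct), the perturbation type
#' (`pert_type`, one of `drug`, `kd`, `control`), the cell line, and for
#' knockdowns the silenced gene (`kd_gene`).
#'
#' @param df data.frame with columns `sample_id`, `perturbagen_id`,
#'   `pert_type`, `cell_line`, `kd_gene`.
#' @return The validated data.frame with class `sample_meta`.
#' @export
sample_meta <- function(df) {
  req <- c("sample_id", "perturbagen_id", "pert_type", "cell_line", "kd_gene")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing metadata columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (cc in req) df[[cc]] <- as.character(df[[cc]])
  df$kd_gene[is.na(df$kd_gene)] <- ""
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$pert_type), c("drug", "kd", "control"))
  if (length(bad))
    stop("unknown pert_type: ", paste(bad, collapse = ", "))
  no_gene <- df$pert_type == "kd" & !nzchar(df$kd_gene)
  if (any(no_gene))
    stop("kd rows lacking kd_gene: sample ",
         paste(df$sample_id[no_gene], collapse = ", "))
  stray <- df$pert_type != "kd" & nzchar(df$kd_gene)
  if (any(stray))
    stop("kd_gene set on non-kd rows: sample ",
         paste(df$sample_id[stray], collapse = ", "))
  class(df) <- c("sample_meta", "data.frame")
  df
}

#' Read sample metadata from TSV
#'
#' @param path TSV with a header row and the columns documented in
#'   [sample_meta()].
#' @return A validated `sample_meta` data.frame.
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", na.strings = NULL)
  sample_meta(df)
}

#' Write sample metadata to TSV
#' @param meta a `sample_meta` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_meta <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# check that metadata samples exist as signature columns
check_meta_samples <- function(sig, meta) {
  miss <- setdiff(meta$sample_id, sig$sample_ids)
  if (length(miss))
    stop("metadata samples absent from signature matrix: ",
         paste(head(miss, 5L), collapse = ", "))
  invisible(TRUE)
}

#' Candidate target space of a drug
#'
#' Determines, for one drug, the cell lines and candidate target genes over
#' which features can be assembled as a complete block. `cells` are the cell
#' lines where the drug was profiled and at least one knockdown exists;
#' `genes` are the genes with knockdown signatures in *every* one of those
#' cells (intersection policy), so that the feature table is a dense
#' genes-by-cells block.
#'
#' @param meta a [sample_meta()] table.
#' @param drug perturbagen identifier of the drug.
#' @return Object of class `candidate_space` with fields `drug`, `cells`,
#'   `genes` (both sorted).
#' @export
build_candidate_space <- function(meta, drug) {
  stopifnot(is.character(drug), length(drug) == 1L)
  drug_rows <- meta$pert_type == "drug" & meta$perturbagen_id == drug
  if (!any(drug_rows)) stop("unknown drug: ", drug)
  kd_rows <- meta$pert_type == "kd"
  cells <- sort(intersect(unique(meta$cell_line[drug_rows]),
                          unique(meta$cell_line[kd_rows])))
  if (!length(cells))
    stop("drug ", drug, " has no profiled cell line with knockdowns")
  by_cell <- split(meta$kd_gene[kd_rows], meta$cell_line[kd_rows])
  genes <- sort(Reduce(intersect, lapply(by_cell[cells], unique)))
  if (!length(genes))
    stop("no candidate gene has knockdowns in all cells of drug ", drug)
  structure(list(drug = drug, cells = cells, genes = genes),
            class = "candidate_space")
}

#' @export
print.candidate_space <- function(x, ...) {
  cat(sprintf("<candidate_space> drug %s: %d candidate genes x %d cells\n",
              x$drug, length(x$genes), length(x$cells)))
  invisible(x)
}
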