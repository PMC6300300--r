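#' Read a drug-to-known-target annotation table
#'
#' TSV with columns `drug` and `target` (one row per pair) or `targets`
#' (comma-separated). Evaluation uses the best-ranked member of each drug's
#' target set.
#'
#' @param path TSV path.
#' @return Named list mapping drug to character vector of target genes.
#' @export
read_drug_targets <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character")
  if (all(c("drug", "target") %in% names(df))) {
    return(lapply(split(df$target, df$drug), unique))
  }
  if (all(c("drug", "targets") %in% names(df))) {
    sp <- strsplit(df$targets, ",", fixed = TRUE)
    out <- lapply(sp, function(v) unique(trimws(v)))
    names(out) <- df$drug
    return(out)
  }
  stop("expected columns drug+target or drug+targets")
}

#' Read a gene localization table
#'
#' TSV with columns `gene` and `localization` (labels `intracellular`,
#' `transmembrane`, `extracellular`, `unknown`; one label per gene).
#'
#' @param path TSV path.
#' @return data.frame usable as `locmap` in [localization_feature()].
#' @export
read_localization <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character")
  miss <- setdiff(c("gene", "localization"), names(df))
  if (length(miss))
    stop("localization table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene))
    stop("multiple localization labels for: ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  ok <- c("intracellular", "transmembrane", "extracellular", "unknown")
  bad <- setdiff(unique(df$localization), ok)
  if (length(bad))
    stop("unknown localization labels: ", paste(bad, collapse = ", "))
  df
}
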