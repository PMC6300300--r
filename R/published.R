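# Bundled evaluation benchmarks from the published validation study: the
# per-drug best-target ranks of 29 FDA-approved drugs profiled in seven
# cell lines under each ranking method, and the per-cell-group top-k counts
# of the two random-forest architectures on the extended 152-drug panel.

#' Published 29-drug validation rankings
#'
#' Best-known-target rank per drug and per ranking method on the bundled
#' validation panel: 29 FDA-approved drugs profiled in seven cell lines
#' whose known targets are among 2634 knocked-down genes. Methods: a random
#' ranking draw, each single feature (`dir`, `ind`, `cs`, `de_max`,
#' `de_mean`), the logistic baseline (`lr`) and the random forest (`rf`).
#' The `targets` column carries each drug's known target set
#' (comma-separated); `n_targets` is its size.
#'
#' @return data.frame with one row per drug.
#' @export
published_validation_ranks <- function() {
  path <- system.file("extdata", "validation_ranks_7cell.tsv",
                      package = "targetrank", mustWork = TRUE)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  df$n_targets <- lengths(strsplit(df$targets, ",", fixed = TRUE))
  df
}

#' Published random-forest counts by cell-line group
#'
#' Top-100/top-50 drug counts of the on-the-fly and two-level forests on
#' the extended 152-drug panel, split by the number of cell lines each drug
#' was profiled in (7, 6, 5, 4), plus the printed overall row (`all`).
#'
#' @return data.frame with columns `model`, `n_cells`, `n_drugs`, `top100`,
#'   `top50`.
#' @export
published_cellgroup_counts <- function() {
  path <- system.file("extdata", "rf_cellgroup_counts.tsv",
                      package = "targetrank", mustWork = TRUE)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
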