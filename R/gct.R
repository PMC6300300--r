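#' Read a GCT 1.2 signature matrix
#'
#' Parses the tab-separated GCT 1.2 text dialect: a `#1.2` version line, a
#' `<rows>\t<columns>` dimension line, a header row starting with
#' `NAME\tDescription` followed by sample identifiers, then one data row per
#' gene. Gene and sample order is preserved; the Description column is
#' ignored on input.
#'
#' @param path path to a GCT file.
#' @return A [signature_matrix()].
#' @seealso [write_gct()]
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("malformed GCT (line 1): file has fewer than 3 lines")
  if (trimws(lines[1L]) != "#1.2")
    stop("malformed GCT header (line 1): expected '#1.2', got '",
         lines[1L], "'")
  dims <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
  ng <- suppressWarnings(as.integer(dims[1L]))
  ns <- suppressWarnings(as.integer(dims[2L]))
  if (length(dims) < 2L || is.na(ng) || is.na(ns))
    stop("malformed GCT header (line 2): expected '<genes>\\t<samples>'")

  hdr <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  if (length(hdr) != ns + 2L)
    stop(sprintf(
      "GCT dimension mismatch: header declares %d samples, column row has %d",
      ns, length(hdr) - 2L))
  sample_ids <- hdr[-(1:2)]

  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  if (length(body) != ng)
    stop(sprintf(
      "GCT dimension mismatch: header declares %d data rows, found %d",
      ng, length(body)))

  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != ns + 2L)) {
    bad <- which(nf != ns + 2L)[1L]
    stop(sprintf(
      "GCT dimension mismatch at data row %d: expected %d fields, found %d",
      bad, ns + 2L, nf[bad]))
  }
  gene_ids <- vapply(fields, `[[`, character(1L), 1L)
  z <- matrix(NA_real_, ng, ns)
  for (i in seq_len(ng)) {
    vals <- suppressWarnings(as.numeric(fields[[i]][-(1:2)]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1L]
      stop(sprintf("non-numeric value at data row %d, sample column %d: '%s'",
                   i, j, fields[[i]][j + 2L]))
    }
    z[i, ] <- vals
  }
  signature_matrix(z, gene_ids, sample_ids)
}

#' Write a GCT 1.2 signature matrix
#'
#' @param sig a [signature_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(sig, path) {
  stopifnot(inherits(sig, "signature_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2",
               paste(length(sig$gene_ids), length(sig$sample_ids), sep = "\t"),
               paste(c("NAME", "Description", sig$sample_ids),
                     collapse = "\t")), con)
  df <- data.frame(NAME = sig$gene_ids, Description = sig$gene_ids,
                   sig$z, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
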