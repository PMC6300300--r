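#' Protein-protein interaction network
#'
#' Builds an undirected interaction network from a two-column edge list of
#' gene symbols (BioGRID/HPRD style). Self-loops are dropped and duplicate
#' edges (in either orientation) collapsed; construction is delegated to
#' \pkg{igraph} and the result cached as an adjacency list for fast partner
#' lookups. Gene symbols are case-sensitive and not alias-resolved.
#'
#' @param edges two-column character matrix or data.frame of gene pairs.
#' @return Object of class `ppi_network` with fields `nodes` (sorted),
#'   `edges` (canonical two-column matrix) and `adj` (named adjacency list).
#' @export
ppi_network <- function(edges) {
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  mode(edges) <- "character"
  edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
  if (nrow(edges) == 0L) {
    return(structure(list(nodes = character(0),
                          edges = matrix(character(0), 0, 2),
                          adj = list()),
                     class = "ppi_network"))
  }
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  adj <- igraph::as_adj_list(g)
  nodes <- igraph::V(g)$name
  adj <- lapply(adj, function(v) sort(nodes[as.integer(v)]))
  names(adj) <- nodes
  ord <- order(nodes)
  el <- igraph::as_edgelist(g)
  el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  structure(list(nodes = nodes[ord],
                 edges = el[order(el[, 1L], el[, 2L]), , drop = FALSE],
                 adj = adj[nodes[ord]]),
            class = "ppi_network")
}

#' Read a protein interaction network from an edge-list TSV
#'
#' @param path TSV whose first two columns are interacting gene symbols;
#'   extra columns are ignored.
#' @param header does the file carry a header row? Default `FALSE`.
#' @param on_empty `"error"` (default) or `"warn"` when the file yields no
#'   edges.
#' @return A [ppi_network()].
#' @export
read_ppi <- function(path, header = FALSE, on_empty = c("error", "warn")) {
  on_empty <- match.arg(on_empty)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(read.delim(path, sep = "\t", header = header,
                            colClasses = "character"),
                 error = function(e) data.frame())
  if (nrow(df) == 0L || ncol(df) < 2L) {
    msg <- paste0("empty interaction network in ", path)
    if (on_empty == "error") stop(msg) else warning(msg)
    return(ppi_network(matrix(character(0), 0, 2)))
  }
  ppi_network(df)
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Interaction partners of a gene
#' @param network a [ppi_network()].
#' @param gene gene symbol.
#' @return Character vector of partners (empty if the gene is absent).
#' @export
ppi_partners <- function(network, gene) {
  network$adj[[gene]] %||% character(0)
}

#' Node degree
#' @param network a [ppi_network()].
#' @param genes gene symbols; defaults to all nodes.
#' @return Named integer vector of partner counts (0 for absent genes).
#' @export
ppi_degree <- function(network, genes = network$nodes) {
  out <- vapply(genes, function(g) length(network$adj[[g]]), integer(1L))
  names(out) <- genes
  out
}
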