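#' Interactome: an undirected simple graph of gene symbols
#'
#' Light wrapper around an undirected \pkg{igraph} graph. Self-loops and
#' duplicate (including reversed) edges are removed at construction; the
#' counts of dropped records are kept so preprocessing is auditable.
#'
#' @param edges two-column character matrix or data.frame of symbol pairs.
#' @return An object of class \code{interactome} with elements
#'   \code{graph} (igraph), \code{n_dropped_self}, \code{n_dropped_dup}.
#' @export
interactome <- function(edges) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L) stop("edge table needs two columns")
  edges <- matrix(as.character(edges[, 1:2]), ncol = 2L)
  self <- edges[, 1L] == edges[, 2L]
  n_self <- sum(self)
  edges <- edges[!self, , drop = FALSE]
  # canonical orientation so A-B and B-A collapse to one record
  flip <- edges[, 1L] > edges[, 2L]
  edges[flip, ] <- edges[flip, c(2L, 1L)]
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  edges <- edges[!dup, , drop = FALSE]
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  structure(
    list(graph = g, n_dropped_self = n_self, n_dropped_dup = n_dup),
    class = "interactome"
  )
}

#' Read an interactome from a two-column edge list
#'
#' Accepts whitespace- or tab-delimited files with at least two columns
#' (extra columns ignored). A header line is detected when its first two
#' tokens match common column names (\code{from}, \code{to}, \code{source},
#' \code{target}, \code{gene}, \code{gene1}, \code{gene2}, \code{node1},
#' \code{node2}, \code{protein1}, \code{protein2}, \code{symbol1},
#' \code{symbol2}, \code{interactor_a}, \code{interactor_b}).
#'
#' @param path path to the edge-list file.
#' @return An \code{\link{interactome}}.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty edge-list file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  short <- which(lengths(toks) < 2L)
  if (length(short) > 0L) {
    stop("single-column row at line ", short[1L], " of ", path)
  }
  header_words <- c(
    "from", "to", "source", "target", "gene", "gene1", "gene2",
    "node1", "node2", "protein1", "protein2", "symbol1", "symbol2",
    "interactor_a", "interactor_b"
  )
  first <- tolower(toks[[1L]][1:2])
  if (all(first %in% header_words)) {
    toks <- toks[-1L]
    if (length(toks) == 0L) stop("edge-list file has a header but no data: ", path)
  }
  edges <- t(vapply(toks, function(x) x[1:2], character(2L)))
  net <- interactome(edges)
  if (net$n_dropped_self + net$n_dropped_dup > 0L) {
    ns_log("read_edge_list", "dropped %d self-loop and %d duplicate record(s)",
           net$n_dropped_self, net$n_dropped_dup)
  }
  net
}

#' Write an interactome back to a two-column TSV edge list
#'
#' @param net an \code{\link{interactome}}.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net$graph)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("interactome: %d nodes, %d edges\n", n_nodes(x), n_edges(x)))
  invisible(x)
}

#' Node and edge counts of an interactome
#' @param net an \code{\link{interactome}}.
#' @export
n_nodes <- function(net) igraph::vcount(net$graph)

#' @rdname n_nodes
#' @export
n_edges <- function(net) igraph::ecount(net$graph)

#' Gene symbols present in an interactome
#' @param net an \code{\link{interactome}}.
#' @export
interactome_genes <- function(net) igraph::V(net$graph)$name

#' Read a gene list (one symbol per line)
#'
#' Blank lines are skipped, duplicates removed preserving first occurrence.
#' @param path file with one gene symbol per line.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}
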