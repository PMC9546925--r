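#' Topological metrics of the subnetwork induced by a gene set
#'
#' The genes are mapped onto the interactome (absent genes are ignored
#' with a logged count), the induced subgraph is extracted, and three
#' metrics are returned: the size of the largest connected component
#' (LCC), the number of edges inside the LCC, and the total number of
#' induced edges. The empty induced graph gives (0, 0, 0).
#'
#' @param net an \code{\link{interactome}}.
#' @param genes gene symbols.
#' @return Named numeric vector \code{c(lcc_size, lcc_edges, total_edges)}.
#' @export
subnetwork_metrics <- function(net, genes) {
  present <- intersect(unique(genes), interactome_genes(net))
  n_missing <- length(unique(genes)) - length(present)
  if (n_missing > 0L)
    ns_log("subnetwork_metrics", "%d gene(s) not in the interactome ignored",
           n_missing)
  if (length(present) == 0L)
    return(c(lcc_size = 0, lcc_edges = 0, total_edges = 0))
  sub <- igraph::induced_subgraph(net$graph, present)
  comp <- igraph::components(sub)
  lcc_id <- which.max(comp$csize)
  lcc <- igraph::induced_subgraph(sub, which(comp$membership == lcc_id))
  c(lcc_size = max(comp$csize),
    lcc_edges = igraph::ecount(lcc),
    total_edges = igraph::ecount(sub))
}

# logarithmic degree bins: {0}, {1}, {2}, {3,4}, {5..8}, {9..16}, ...
.degree_bin <- function(d, binning = c("log", "exact")) {
  binning <- match.arg(binning)
  if (binning == "exact") return(d)
  ifelse(d == 0L, -1L, floor(log2(d)))
}

#' Draw a random gene set matching size and degree distribution
#'
#' Returns a uniformly random set of interactome genes with the same size
#' and the same per-degree-bin counts as the input set. Degrees are
#' binned logarithmically (bin edges doubling: 1, 2, 3-4, 5-8, ...), the
#' standard practice for heavy-tailed interactomes; \code{binning =
#' "exact"} matches each degree exactly instead. Sampling is without
#' replacement within each bin and may return members of the original set
#' unless \code{exclude_original}.
#'
#' @param net an \code{\link{interactome}}.
#' @param genes gene set to match (must map into the network).
#' @param binning \code{"log"} (default) or \code{"exact"}.
#' @param exclude_original forbid genes of the original set (default FALSE).
#' @return Character vector of sampled gene symbols.
#' @export
degree_preserving_sample <- function(net, genes, binning = c("log", "exact"),
                                     exclude_original = FALSE) {
  binning <- match.arg(binning)
  deg <- igraph::degree(net$graph)
  genes <- intersect(unique(genes), names(deg))
  if (length(genes) == 0L) stop("no input gene maps into the interactome")
  bins <- .degree_bin(deg, binning)
  need <- table(bins[genes])
  pool_names <- names(deg)
  if (exclude_original) pool_names <- setdiff(pool_names, genes)
  out <- character(0L)
  for (b in names(need)) {
    avail <- pool_names[bins[pool_names] == as.numeric(b)]
    if (length(avail) < need[[b]])
      stop("degree bin ", b, " holds ", length(avail), " node(s) but ",
           need[[b]], " are required; use coarser bins")
    out <- c(out, sample(avail, need[[b]], replace = FALSE))
  }
  out
}

#' Significance of a gene set as an interactome module
#'
#' Builds null distributions of the three subnetwork metrics (LCC size,
#' LCC edges, total edges) over \code{n_rep} degree-matched random gene
#' sets, z-scores the observed metrics against them, and reports the
#' one-sided upper-tail normal-approximation p value for each, together
#' with the add-one-smoothed empirical p (fraction of null draws at or
#' above the observed value). A null with zero spread gives an undefined
#' z (NA) and the empirical p only.
#'
#' @param net an \code{\link{interactome}}.
#' @param genes gene set to test.
#' @param n_rep number of random draws (default 1000).
#' @param seed RNG seed (report is bit-reproducible given it).
#' @param binning degree-matching mode, see \code{\link{degree_preserving_sample}}.
#' @param exclude_original forbid original genes in the null draws.
#' @return data.frame of class \code{module_significance_report}: one row
#'   per metric with \code{observed}, \code{random_mean}, \code{random_sd},
#'   \code{z}, \code{p_normal}, \code{p_empirical}.
#' @export
module_significance <- function(net, genes, n_rep = 1000L, seed = 1L,
                                binning = c("log", "exact"),
                                exclude_original = FALSE) {
  binning <- match.arg(binning)
  stopifnot(n_rep >= 1L)
  if (n_rep < 100L)
    warning("n_rep < 100: null distributions will be noisy")
  obs <- subnetwork_metrics(net, genes)

  set.seed(seed)
  null <- matrix(0, nrow = n_rep, ncol = 3L,
                 dimnames = list(NULL, names(obs)))
  for (i in seq_len(n_rep)) {
    rnd <- degree_preserving_sample(net, genes, binning, exclude_original)
    sub <- igraph::induced_subgraph(net$graph, rnd)
    comp <- igraph::components(sub)
    lcc_id <- which.max(comp$csize)
    in_lcc <- comp$membership == lcc_id
    el <- igraph::as_edgelist(sub, names = FALSE)
    null[i, ] <- c(max(comp$csize),
                   sum(in_lcc[el[, 1L]] & in_lcc[el[, 2L]]),
                   nrow(el))
  }

  mu <- colMeans(null)
  sig <- apply(null, 2L, stats::sd)
  z <- ifelse(sig > 0, (obs - mu) / sig, NA_real_)
  p_norm <- ifelse(is.na(z), NA_real_, stats::pnorm(z, lower.tail = FALSE))
  p_emp <- (1 + colSums(sweep(null, 2L, obs, `>=`))) / (n_rep + 1)

  structure(
    data.frame(metric = names(obs), observed = unname(obs),
               random_mean = unname(mu), random_sd = unname(sig),
               z = unname(z), p_normal = unname(p_norm),
               p_empirical = unname(p_emp),
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("module_significance_report", "data.frame"),
    n_rep = n_rep, seed = seed, binning = binning
  )
}

#' @export
print.module_significance_report <- function(x, ...) {
  cat(sprintf("module significance (%d degree-matched draws, %s bins):\n",
              attr(x, "n_rep"), attr(x, "binning")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
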