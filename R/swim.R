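#' Differential expression between case and control samples
#'
#' Per-gene two-sided Welch t-test on log-scale values, with BH false
#' discovery rate across all tested genes. \code{logFC} is the case minus
#' control mean on the log scale (log2 assumed for the linear fold
#' change). A gene is retained when \code{FDR <= fdr_threshold} and its
#' linear fold-change magnitude \code{max(FC, 1/FC) >= fc_threshold};
#' with the default \code{fc_threshold = 1} the fold-change filter keeps
#' every gene, so retention is driven by the FDR alone.
#'
#' @param expr an \code{\link{expr_set}} (log-scale values assumed).
#' @param fc_threshold linear fold-change magnitude cutoff (default 1).
#' @param fdr_threshold BH FDR cutoff (default 0.001).
#' @param keep_all when TRUE return every tested gene with a
#'   \code{retained} flag; when FALSE (default) only retained genes.
#' @return data.frame of class \code{deg_table}: \code{gene},
#'   \code{mean_case}, \code{mean_control}, \code{logFC}, \code{p},
#'   \code{FDR}, \code{direction}, \code{retained}.
#' @export
differential_expression <- function(expr, fc_threshold = 1,
                                    fdr_threshold = 0.001,
                                    keep_all = FALSE) {
  stopifnot(inherits(expr, "expr_set"))
  case <- expr$group == "case"
  ctrl <- expr$group == "control"
  n1 <- sum(case); n2 <- sum(ctrl)
  if (n1 < 2L || n2 < 2L) stop("both groups need at least 2 samples")

  v1 <- expr$values[, case, drop = FALSE]
  v2 <- expr$values[, ctrl, drop = FALSE]
  m1 <- rowMeans(v1); m2 <- rowMeans(v2)
  s1 <- rowSums((v1 - m1)^2) / (n1 - 1)
  s2 <- rowSums((v2 - m2)^2) / (n2 - 1)

  se2 <- s1 / n1 + s2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  # Welch-Satterthwaite df
  df <- se2^2 / ((s1 / n1)^2 / (n1 - 1) + (s2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  p[se2 == 0] <- 1  # flat gene in both groups: no evidence
  fdr <- stats::p.adjust(p, method = "BH")

  lfc <- m1 - m2
  lin_fc_mag <- 2^abs(lfc)
  retained <- fdr <= fdr_threshold & lin_fc_mag >= fc_threshold

  tab <- data.frame(
    gene = rownames(expr$values), mean_case = m1, mean_control = m2,
    logFC = lfc, p = p, FDR = fdr,
    direction = ifelse(lfc > 0, "up", "down"),
    retained = retained, stringsAsFactors = FALSE, row.names = NULL
  )
  if (!keep_all) tab <- tab[tab$retained, , drop = FALSE]
  structure(tab, class = c("deg_table", "data.frame"),
            fc_threshold = fc_threshold, fdr_threshold = fdr_threshold,
            n_tested = nrow(expr$values))
}

# signed Pearson correlation among genes over the chosen samples
.gene_correlations <- function(expr, genes, samples = c("case", "all")) {
  samples <- match.arg(samples)
  keep <- if (samples == "case") expr$group == "case" else rep(TRUE, ncol(expr$values))
  v <- expr$values[genes, keep, drop = FALSE]
  if (ncol(v) < 3L) stop("need at least 3 samples to estimate correlations")
  stats::cor(t(v))
}

#' Largest-component fraction of the thresholded correlation network
#'
#' For each candidate threshold the network over the DEG genes is built by
#' keeping pairs with \code{|r| > threshold}, and the fraction of the DEG
#' genes falling in the largest connected component is reported (isolated
#' genes count in the denominator). Used to pick a correlation threshold
#' that keeps the network connected yet sparse.
#'
#' @param expr an \code{\link{expr_set}}.
#' @param deg_genes gene symbols to correlate.
#' @param thresholds numeric vector of |r| thresholds.
#' @param samples correlate over \code{"case"} samples (default) or \code{"all"}.
#' @return data.frame with columns \code{threshold}, \code{lcc_fraction}.
#' @export
connectivity_profile <- function(expr, deg_genes, thresholds,
                                 samples = c("case", "all")) {
  if (length(thresholds) == 0L) stop("empty threshold list")
  if (length(deg_genes) < 2L) stop("need at least 2 genes")
  r <- .gene_correlations(expr, deg_genes, samples)
  n <- nrow(r)
  a <- abs(r); diag(a) <- 0
  frac <- vapply(thresholds, function(th) {
    adj <- a > th
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    max(igraph::components(g)$csize) / n
  }, numeric(1L))
  data.frame(threshold = thresholds, lcc_fraction = frac)
}

#' Build the gene co-expression network at a percentile threshold
#'
#' Signed Pearson correlations are computed between all DEG pairs; the
#' edge threshold is the given percentile of the \code{|r|} distribution
#' over all unordered pairs (linear interpolation, \code{quantile} type 7,
#' so the cut is bit-reproducible), and an edge is kept when
#' \code{|r| > threshold}. Genes left without any edge are dropped from
#' the node set.
#'
#' @param expr an \code{\link{expr_set}}.
#' @param deg_genes DEG gene symbols (network node candidates).
#' @param percentile percentile of |r| in (0, 100); default 83.
#' @param samples correlate over \code{"case"} samples (default) or \code{"all"}.
#' @return Object of class \code{corr_network}: \code{graph} (igraph with
#'   signed \code{weight}), \code{threshold}, \code{percentile},
#'   \code{cors} (signed correlation matrix over retained nodes).
#' @export
build_correlation_network <- function(expr, deg_genes, percentile = 83,
                                      samples = c("case", "all")) {
  stopifnot(percentile > 0, percentile < 100)
  deg_genes <- intersect(rownames(expr$values), unique(deg_genes))
  if (length(deg_genes) < 2L) stop("need at least 2 genes in the matrix")
  r <- .gene_correlations(expr, deg_genes, samples)
  absr <- abs(r[upper.tri(r)])
  threshold <- unname(stats::quantile(absr, probs = percentile / 100, type = 7))

  adj <- abs(r) > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::E(g)$weight <- r[igraph::as_edgelist(g, names = FALSE)]
  keep <- igraph::degree(g) > 0
  g <- igraph::induced_subgraph(g, which(keep))
  nodes <- igraph::V(g)$name
  structure(
    list(graph = g, threshold = threshold, percentile = percentile,
         cors = r[nodes, nodes, drop = FALSE]),
    class = "corr_network"
  )
}

#' @export
print.corr_network <- function(x, ...) {
  cat(sprintf("corr_network: %d nodes, %d edges (|r| > %.4f, %gth percentile)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$threshold, x$percentile))
  invisible(x)
}

#' Cluster the co-expression network by k-means
#'
#' Each node is represented by its row of signed correlations to all
#' network nodes, and the rows are partitioned with k-means. When \code{k}
#' is missing it is chosen by the elbow of the within-cluster dispersion
#' curve over k = 2..10 (largest distance of the curve to the chord
#' joining its endpoints).
#'
#' @param net a \code{corr_network}.
#' @param k number of clusters; chosen by the elbow rule when NULL.
#' @param seed RNG seed for k-means initialization (deterministic labels).
#' @return Named integer vector of cluster labels, one per network node.
#' @export
cluster_network <- function(net, k = NULL, seed = 1L) {
  stopifnot(inherits(net, "corr_network"))
  feats <- net$cors
  n <- nrow(feats)
  if (n < 2L) stop("network too small to cluster")
  if (!is.null(k) && k > n) stop("k exceeds the node count")

  # k = n means singleton clusters; kmeans itself cannot seed n centres
  if (!is.null(k) && k == n)
    return(setNames(seq_len(n), rownames(feats)))
  km_at <- function(kk) {
    set.seed(seed)
    stats::kmeans(feats, centers = kk, nstart = 10L, iter.max = 100L)
  }
  if (is.null(k)) {
    ks <- 2:min(10L, n - 1L)
    wss <- vapply(ks, function(kk) km_at(kk)$tot.withinss, numeric(1L))
    if (length(ks) == 1L) {
      k <- ks
    } else {
      # elbow: point furthest from the chord between the curve's endpoints
      x <- (ks - ks[1L]) / diff(range(ks))
      y <- (wss - wss[length(wss)]) / (wss[1L] - wss[length(wss)] + 1e-12)
      d <- abs(y - (1 - x)) / sqrt(2)
      k <- ks[which.max(d)]
    }
    ns_log("cluster_network", "elbow rule selected k = %d", k)
  }
  fit <- km_at(k)
  setNames(as.integer(fit$cluster), rownames(feats))
}

#' Average Pearson correlation between each hub and its neighbours
#'
#' A hub is a network node of degree greater than 5. Its APCC is the mean
#' of the signed correlations carried by its incident edges (i.e. between
#' its expression profile and those of its nearest neighbours). Non-hubs
#' are absent from the output.
#'
#' @param net a \code{corr_network}.
#' @param hub_degree minimum degree strictly exceeded by hubs (default 5).
#' @return Named numeric vector of APCC values, hubs only.
#' @export
compute_apcc <- function(net, hub_degree = 5L) {
  g <- net$graph
  deg <- igraph::degree(g)
  hubs <- names(deg)[deg > hub_degree]
  vapply(setNames(hubs, hubs), function(h) {
    inc <- igraph::incident(g, h)
    mean(inc$weight)
  }, numeric(1L))
}

#' Date / party / fight-club hub classification
#'
#' Hubs (degree > 5) are classified by their average neighbour
#' correlation: fight-club for negative APCC, party for APCC at or above
#' the party boundary (default 0.5), date otherwise. Nodes with degree
#' of 5 or less are non-hubs regardless of APCC.
#'
#' @param apcc named APCC vector (from \code{\link{compute_apcc}}).
#' @param degree named degree vector for all nodes.
#' @param hub_degree hub cutoff (degree strictly greater; default 5).
#' @param party_boundary APCC boundary between date and party hubs.
#' @return Named character vector over all nodes with values in
#'   \code{"date"}, \code{"party"}, \code{"fight-club"}, \code{"non-hub"}.
#' @export
classify_hubs <- function(apcc, degree, hub_degree = 5L, party_boundary = 0.5) {
  cls <- setNames(rep("non-hub", length(degree)), names(degree))
  hubs <- names(degree)[degree > hub_degree]
  for (h in hubs) {
    a <- apcc[[h]]
    cls[h] <- if (a < 0) "fight-club" else if (a >= party_boundary) "party" else "date"
  }
  cls
}

#' Heat cartography: within-module degree and clusterphobic coefficient
#'
#' For node i with degree \eqn{k_i} and \eqn{\kappa_i} links inside its
#' own cluster: the within-module degree
#' \eqn{z_i = (\kappa_i - \bar\kappa_{c(i)}) / \sigma_{\kappa_{c(i)}}}
#' (0 when the cluster's \eqn{\kappa} values have zero spread) measures
#' local hubness, and the clusterphobic coefficient
#' \eqn{K_{\pi,i} = 1 - (\kappa_i / k_i)^2} measures how much the node
#' reaches outside its cluster (0 = fully internal, 1 = fully external).
#'
#' @param net a \code{corr_network}.
#' @param labels named cluster labels over all network nodes.
#' @return data.frame of class \code{node_cartography}: \code{gene},
#'   \code{cluster}, \code{degree}, \code{kappa}, \code{z}, \code{Kpi}.
#' @export
compute_cartography <- function(net, labels) {
  g <- net$graph
  nodes <- igraph::V(g)$name
  if (!all(nodes %in% names(labels))) stop("every network node needs a cluster label")
  labels <- labels[nodes]
  deg <- igraph::degree(g)[nodes]

  el <- igraph::as_edgelist(g)
  internal <- labels[el[, 1L]] == labels[el[, 2L]]
  kappa <- setNames(numeric(length(nodes)), nodes)
  if (any(internal)) {
    cnt <- table(c(el[internal, 1L], el[internal, 2L]))
    kappa[names(cnt)] <- as.numeric(cnt)
  }

  z <- setNames(numeric(length(nodes)), nodes)
  for (cl in unique(labels)) {
    idx <- names(labels)[labels == cl]
    mu <- mean(kappa[idx]); sig <- stats::sd(kappa[idx])
    z[idx] <- if (is.na(sig) || sig == 0) 0 else (kappa[idx] - mu) / sig
  }
  kpi <- 1 - (kappa / deg)^2

  structure(
    data.frame(gene = nodes, cluster = as.integer(labels), degree = as.integer(deg),
               kappa = as.integer(kappa), z = z, Kpi = kpi,
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("node_cartography", "data.frame")
  )
}

#' Call switch genes from the annotated cartography
#'
#' Switch genes are fight-club hubs (negative APCC) that interact mainly
#' outside their own cluster: \code{Kpi > kpi_threshold} (default 0.8)
#' while not being local hubs, \code{z < z_threshold} (default 2.5).
#'
#' @param cartography a \code{node_cartography} with a \code{class} column
#'   (see \code{\link{swim_analysis}}), or the plain cartography plus
#'   \code{hub_class}.
#' @param hub_class named character classes when not already a column.
#' @param kpi_threshold clusterphobic cutoff (default 0.8).
#' @param z_threshold within-module degree cutoff (default 2.5).
#' @return Character vector of switch gene symbols (sorted).
#' @export
call_switch_genes <- function(cartography, hub_class = NULL,
                              kpi_threshold = 0.8, z_threshold = 2.5) {
  tab <- cartography
  if (!("class" %in% names(tab))) {
    if (is.null(hub_class)) stop("hub classes missing")
    tab$class <- hub_class[tab$gene]
  }
  sw <- tab$class == "fight-club" & tab$Kpi > kpi_threshold & tab$z < z_threshold
  sort(tab$gene[sw])
}

#' Full switch-gene analysis of a case/control expression set
#'
#' Convenience wrapper chaining DEG calling, correlation-network
#' construction, k-means clustering, APCC hub classification, heat
#' cartography and switch calling with the module defaults.
#'
#' @param expr an \code{\link{expr_set}}.
#' @param fc_threshold,fdr_threshold DEG thresholds.
#' @param percentile correlation-threshold percentile.
#' @param k number of clusters (NULL = elbow rule).
#' @param samples correlation population (\code{"case"} or \code{"all"}).
#' @param kpi_threshold,z_threshold switch cutoffs.
#' @param seed RNG seed for clustering.
#' @return List with \code{deg}, \code{network}, \code{labels},
#'   \code{apcc}, \code{cartography} (with \code{class}, \code{APCC},
#'   \code{is_switch} columns), \code{switch_genes}.
#' @export
swim_analysis <- function(expr, fc_threshold = 1, fdr_threshold = 0.001,
                          percentile = 83, k = NULL,
                          samples = c("case", "all"),
                          kpi_threshold = 0.8, z_threshold = 2.5,
                          seed = 1L) {
  samples <- match.arg(samples)
  deg <- differential_expression(expr, fc_threshold, fdr_threshold)
  ns_log("swim", "%d DEGs at FC >= %g, FDR <= %g",
         nrow(deg), fc_threshold, fdr_threshold)
  if (nrow(deg) < 3L) stop("fewer than 3 DEGs; cannot build a correlation network")
  net <- build_correlation_network(expr, deg$gene, percentile, samples)
  ns_log("swim", "correlation network: %d nodes, %d edges (threshold %.4f)",
         igraph::vcount(net$graph), igraph::ecount(net$graph), net$threshold)
  labels <- cluster_network(net, k = k, seed = seed)
  apcc <- compute_apcc(net)
  cls <- classify_hubs(apcc, igraph::degree(net$graph))
  carto <- compute_cartography(net, labels)
  carto$APCC <- unname(apcc[carto$gene])
  carto$class <- unname(cls[carto$gene])
  switch_genes <- call_switch_genes(carto, kpi_threshold = kpi_threshold,
                                    z_threshold = z_threshold)
  carto$is_switch <- carto$gene %in% switch_genes
  ns_log("swim", "%d clusters, %d hubs, %d switch genes",
         length(unique(labels)), length(apcc), length(switch_genes))
  list(deg = deg, network = net, labels = labels, apcc = apcc,
       cartography = carto, switch_genes = switch_genes)
}
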