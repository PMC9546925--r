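#' Filter switch genes by regulation direction and cluster membership
#'
#' Keeps switch genes with the requested direction of differential
#' expression and, under \code{cluster_rule = "majority"}, restricts to
#' the single cluster containing the most switch genes of that direction
#' (the co-regulated, co-clustered subset); \code{cluster_rule = "all"}
#' disables the cluster filter, and an integer rule names a cluster
#' explicitly.
#'
#' @param cartography a \code{node_cartography} with \code{is_switch} and
#'   \code{cluster} columns (see \code{\link{swim_analysis}}).
#' @param deg_table a \code{deg_table} supplying the \code{direction}.
#' @param direction \code{"up"}, \code{"down"} or \code{"both"}.
#' @param cluster_rule \code{"majority"}, \code{"all"}, or a cluster id.
#' @return Character vector of switch candidate genes (may be empty, with
#'   a warning).
#' @export
filter_switch_candidates <- function(cartography, deg_table,
                                     direction = c("up", "down", "both"),
                                     cluster_rule = "majority") {
  direction <- match.arg(direction)
  sw <- cartography[cartography$is_switch, , drop = FALSE]
  dir_of <- setNames(deg_table$direction, deg_table$gene)
  sw$direction <- dir_of[sw$gene]
  if (direction != "both")
    sw <- sw[!is.na(sw$direction) & sw$direction == direction, , drop = FALSE]
  if (nrow(sw) == 0L) {
    warning("no switch gene matches direction '", direction, "'")
    return(character(0L))
  }
  if (identical(cluster_rule, "majority")) {
    counts <- table(sw$cluster)
    top <- names(counts)[which.max(counts)]
    sw <- sw[sw$cluster == as.integer(top), , drop = FALSE]
  } else if (!identical(cluster_rule, "all")) {
    sw <- sw[sw$cluster == as.integer(cluster_rule), , drop = FALSE]
    if (nrow(sw) == 0L) warning("no switch gene in cluster ", cluster_rule)
  }
  sort(sw$gene)
}

#' Intersect bounded network candidates with switch candidates
#'
#' Plain set intersection with the seed genes excluded, returned in
#' deterministic lexicographic order.
#'
#' @param diamond_set bounded DIAMOnD candidate genes.
#' @param switch_set switch candidate genes.
#' @param seeds seed genes to exclude.
#' @return Sorted character vector: the disease gene signature.
#' @export
intersect_candidates <- function(diamond_set, switch_set, seeds = character(0L)) {
  sort(setdiff(intersect(diamond_set, switch_set), seeds))
}

#' Run the full disease-signature pipeline
#'
#' Executes the stages in order: DIAMOnD expansion on the interactome,
#' seed enrichment and sliding-window boundary selection, switch-gene
#' detection on the expression data, intersection of the two candidate
#' sets, and degree-preserving validation of the assembled module
#' (seeds plus signature). Per-stage counts are logged; every RNG-bearing
#' stage draws from the single master \code{seed}.
#'
#' @param net an \code{\link{interactome}} (or edge-list path).
#' @param seeds seed gene symbols (or path, one per line).
#' @param expr an \code{\link{expr_set}}.
#' @param collection a gene-set collection (or GMT path).
#' @param n_iter DIAMOnD iterations (default 500).
#' @param window sliding-window size; NULL = number of in-network seeds.
#' @param enrich_alpha adjusted-p threshold for seed-enriched terms (0.05).
#' @param boundary_p sliding-window significance threshold (0.01).
#' @param fc_threshold,fdr_threshold DEG thresholds (1, 0.001).
#' @param percentile correlation-threshold percentile (83).
#' @param k cluster count (NULL = elbow rule).
#' @param direction,cluster_rule switch-candidate filter settings.
#' @param n_rep randomization replicates for module validation (1000).
#' @param seed master RNG seed.
#' @param out_dir optional directory; when given, every intermediate
#'   table is written as TSV.
#' @return Object of class \code{disease_signature}: \code{seeds},
#'   \code{ranking}, \code{boundary}, \code{diamond_candidates},
#'   \code{swim} (full swim_analysis result), \code{switch_candidates},
#'   \code{signature}, \code{assembled_module}, \code{significance}.
#' @export
run_pipeline <- function(net, seeds, expr, collection,
                         n_iter = 500L, window = NULL,
                         enrich_alpha = 0.05, boundary_p = 0.01,
                         fc_threshold = 1, fdr_threshold = 0.001,
                         percentile = 83, k = NULL,
                         direction = "up", cluster_rule = "majority",
                         n_rep = 1000L, seed = 1L, out_dir = NULL) {
  if (is.character(net)) net <- read_edge_list(net)
  if (is.character(seeds) && length(seeds) == 1L && file.exists(seeds))
    seeds <- read_gene_list(seeds)
  if (is.character(collection)) collection <- read_gmt(collection)
  if (length(seeds) == 0L) stop("stage diamond: no seed genes supplied")

  in_net <- intersect(seeds, interactome_genes(net))
  ns_log("pipeline", "%d/%d seeds map into the interactome",
         length(in_net), length(seeds))

  ranking <- tryCatch(run_diamond(net, seeds, n_iter = n_iter),
                      error = function(e) stop("stage diamond: ",
                                               conditionMessage(e)))
  ns_log("pipeline", "DIAMOnD ranked %d candidates", nrow(ranking))

  background <- intersect(interactome_genes(net), unique(unlist(collection)))
  terms <- tryCatch(
    seed_enriched_terms(in_net, collection, background, alpha = enrich_alpha),
    error = function(e) stop("stage boundary: ", conditionMessage(e)))
  enriched_genes <- unique(unlist(collection[terms]))
  window <- window %||% length(in_net)
  report <- sliding_window_significance(ranking, enriched_genes, window,
                                        background)
  boundary <- select_module_boundary(report, threshold = boundary_p)
  ns_log("pipeline", "%d seed-enriched terms; boundary at iteration %d",
         length(terms), boundary)
  diamond_candidates <- head(ranking$gene, boundary)

  swim <- tryCatch(
    swim_analysis(expr, fc_threshold, fdr_threshold, percentile, k = k,
                  seed = seed),
    error = function(e) stop("stage swim: ", conditionMessage(e)))

  switch_candidates <- filter_switch_candidates(swim$cartography, swim$deg,
                                                direction = direction,
                                                cluster_rule = cluster_rule)
  ns_log("pipeline", "%d switch candidates after direction/cluster filter",
         length(switch_candidates))

  signature <- intersect_candidates(diamond_candidates, switch_candidates,
                                    seeds = seeds)
  assembled <- sort(union(in_net, signature))
  ns_log("pipeline", "signature of %d genes; assembled module of %d genes",
         length(signature), length(assembled))

  significance <- module_significance(net, assembled, n_rep = n_rep,
                                      seed = seed)

  res <- structure(
    list(seeds = sort(in_net), ranking = ranking,
         boundary_report = report, boundary = boundary,
         diamond_candidates = diamond_candidates,
         enriched_terms = terms, swim = swim,
         switch_candidates = switch_candidates,
         signature = signature, assembled_module = assembled,
         significance = significance),
    class = "disease_signature"
  )
  .check_signature_invariants(res)
  if (!is.null(out_dir)) .write_signature_artifacts(res, out_dir)
  res
}

# contract of the result object, asserted after every run
.check_signature_invariants <- function(res) {
  stopifnot(
    all(res$signature %in% res$diamond_candidates),
    all(res$signature %in% res$switch_candidates),
    length(intersect(res$signature, res$seeds)) == 0L,
    all(res$seeds %in% res$assembled_module)
  )
  invisible(res)
}

.write_signature_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(as.data.frame(res$ranking), "diamond_ranking.tsv")
  w(as.data.frame(res$boundary_report), "boundary_report.tsv")
  w(as.data.frame(res$swim$deg), "deg_table.tsv")
  el <- igraph::as_edgelist(res$swim$network$graph)
  w(data.frame(gene1 = el[, 1L], gene2 = el[, 2L],
               r = igraph::E(res$swim$network$graph)$weight),
    "correlation_network.tsv")
  w(res$swim$cartography, "cartography.tsv")
  w(as.data.frame(res$significance), "module_significance.tsv")
  writeLines(res$signature, file.path(out_dir, "signature.txt"))
  writeLines(res$assembled_module, file.path(out_dir, "assembled_module.txt"))
  invisible(out_dir)
}

#' @export
print.disease_signature <- function(x, ...) {
  cat("disease signature pipeline result\n")
  cat(sprintf("  seeds in network:    %d\n", length(x$seeds)))
  cat(sprintf("  ranked candidates:   %d (boundary at %d)\n",
              nrow(x$ranking), x$boundary))
  cat(sprintf("  switch candidates:   %d\n", length(x$switch_candidates)))
  cat(sprintf("  signature genes:     %d\n", length(x$signature)))
  cat(sprintf("  assembled module:    %d genes (LCC p = %.3g)\n",
              length(x$assembled_module),
              x$significance$p_normal[x$significance$metric == "lcc_size"]))
  invisible(x)
}
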