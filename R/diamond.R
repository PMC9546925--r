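#' Connectivity significance of a candidate protein
#'
#' Upper-tail hypergeometric probability that a node of degree \code{k}
#' has \code{ks} or more links to the current seed/module set: with
#' \code{N} proteins in the interactome of which \code{s} are seeds,
#' \deqn{p = P(X \ge k_s), \quad X \sim \mathrm{Hypergeom}(N, s, k).}
#' Computed through \code{phyper(..., lower.tail = FALSE)}, which works in
#' log space and is stable far into the tail.
#'
#' @param N interactome size (population).
#' @param s current number of seed/module proteins (successes).
#' @param k candidate's total degree (draws).
#' @param ks candidate's links to the seed/module set.
#' @return \code{P(X >= ks)}, a probability in \eqn{[0, 1]}.
#' @export
connectivity_significance <- function(N, s, k, ks) {
  if (ks > k) stop("ks cannot exceed k")
  if (s > N) stop("s cannot exceed N")
  if (ks < 0 || k < 0) stop("k and ks must be non-negative")
  if (k > N - 1) stop("degree k cannot exceed N - 1")
  if (ks == 0) return(1)
  stats::phyper(ks - 1, m = s, n = N - s, k = k, lower.tail = FALSE)
}

#' Iterative disease-module expansion by connectivity significance
#'
#' DIAMOnD-style ranking: at every iteration the connectivity significance
#' is computed for each node outside the growing module that has at least
#' one link to it; the most significant node (lowest p) is admitted and
#' counted as a seed from the next iteration on. Ties are broken by larger
#' \code{ks}, then lexicographic gene symbol, so identical inputs always
#' give identical rankings.
#'
#' Seeds absent from the interactome are dropped with a logged warning.
#' The seed weight \code{alpha} multiplies the contribution of the
#' original seeds (links to them count \code{alpha} times, and the
#' population is enlarged accordingly); the default \code{alpha = 1} is
#' plain seed counting.
#'
#' @param net an \code{\link{interactome}}.
#' @param seeds character vector of seed gene symbols.
#' @param n_iter number of expansion iterations (default 500).
#' @param alpha seed weight (default 1).
#' @return A \code{data.frame} of class \code{diamond_ranking} with
#'   columns \code{iteration}, \code{gene}, \code{degree},
#'   \code{links_to_module}, \code{p_value}.
#' @export
run_diamond <- function(net, seeds, n_iter = 500L, alpha = 1) {
  stopifnot(inherits(net, "interactome"), n_iter >= 1L)
  g <- net$graph
  all_genes <- igraph::V(g)$name
  in_net <- intersect(seeds, all_genes)
  if (length(in_net) == 0L) stop("no seed gene maps into the interactome")
  if (length(in_net) < length(seeds))
    warning(length(seeds) - length(in_net),
            " seed gene(s) absent from the interactome were dropped")

  N0 <- length(all_genes)
  deg <- igraph::degree(g)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  adj <- lapply(adj, function(v) v$name)
  names(adj) <- all_genes

  is_seed0 <- setNames(rep(FALSE, N0), all_genes)
  is_seed0[in_net] <- TRUE
  in_module <- is_seed0

  # links into the module, split by original-seed vs admitted-candidate
  # endpoints so the seed weight can differ
  ks_seed <- setNames(numeric(N0), all_genes)
  ks_cand <- setNames(numeric(N0), all_genes)
  for (s in in_net) {
    nb <- adj[[s]]
    ks_seed[nb] <- ks_seed[nb] + 1
  }

  s0 <- length(in_net)
  N_eff <- N0 + s0 * (alpha - 1)

  out_iter <- integer(n_iter); out_gene <- character(n_iter)
  out_deg <- integer(n_iter); out_ks <- numeric(n_iter)
  out_p <- numeric(n_iter)
  n_done <- 0L

  for (it in seq_len(n_iter)) {
    s_eff <- s0 * alpha + (it - 1L)
    cand <- names(which(!in_module & (ks_seed + ks_cand) > 0))
    if (length(cand) == 0L) {
      warning("candidate pool exhausted after ", n_done,
              " iteration(s); ranking truncated")
      break
    }
    ks_eff <- alpha * ks_seed[cand] + ks_cand[cand]
    k_eff <- deg[cand] + (alpha - 1) * ks_seed[cand]
    p <- stats::phyper(ks_eff - 1, m = s_eff, n = N_eff - s_eff,
                       k = k_eff, lower.tail = FALSE)
    # min p, then max ks, then lexicographic symbol
    ord <- order(p, -ks_eff, cand)
    best <- ord[1L]
    gene <- cand[best]

    n_done <- it
    out_iter[it] <- it
    out_gene[it] <- gene
    out_deg[it] <- deg[[gene]]
    out_ks[it] <- ks_seed[[gene]] + ks_cand[[gene]]
    out_p[it] <- p[best]

    in_module[gene] <- TRUE
    nb <- adj[[gene]]
    ks_cand[nb] <- ks_cand[nb] + 1
  }

  idx <- seq_len(n_done)
  structure(
    data.frame(iteration = out_iter[idx], gene = out_gene[idx],
               degree = out_deg[idx], links_to_module = out_ks[idx],
               p_value = out_p[idx], stringsAsFactors = FALSE),
    class = c("diamond_ranking", "data.frame"),
    seeds_in_network = sort(in_net)
  )
}

#' Seeds that were actually used by a DIAMOnD run
#' @param ranking a \code{diamond_ranking}.
#' @export
diamond_seeds <- function(ranking) attr(ranking, "seeds_in_network")
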