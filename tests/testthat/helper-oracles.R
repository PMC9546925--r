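# Independent oracles: explicit enumeration / closed forms, kept free of
# any package internals so they can arbitrate the implementation.

# upper-tail hypergeometric by explicit enumeration of all outcomes
enum_hyper_tail <- function(N, s, k, ks) {
  hi <- min(k, s)
  if (ks > hi) return(0)
  if (ks <= 0) return(1)
  sum(vapply(ks:hi, function(i) {
    choose(s, i) * choose(N - s, k - i)
  }, numeric(1L))) / choose(N, k)
}

# BH step-up: p * m / rank, cumulative minimum from the largest p down
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# textbook two-pass Pearson correlation
pearson_two_pass <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# hand-built correlation network for cartography/APCC unit tests
make_corr_net <- function(edges, weights) {
  g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
  igraph::E(g)$weight <- weights
  nodes <- igraph::V(g)$name
  structure(
    list(graph = g, threshold = NA_real_, percentile = NA_real_,
         cors = matrix(NA_real_, length(nodes), length(nodes),
                       dimnames = list(nodes, nodes))),
    class = "corr_network"
  )
}

# small expression set with given case/control matrices
make_expr <- function(case, ctrl, genes = NULL) {
  genes <- genes %||% sprintf("g%02d", seq_len(nrow(case)))
  v <- cbind(case, ctrl)
  rownames(v) <- genes
  colnames(v) <- c(sprintf("ca%02d", seq_len(ncol(case))),
                   sprintf("co%02d", seq_len(ncol(ctrl))))
  expr_set(v, group = c(rep("case", ncol(case)), rep("control", ncol(ctrl))))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
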