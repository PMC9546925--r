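#' Generate a sparse interactome with a planted dense module
#'
#' The background is an Erdos-Renyi graph with the requested mean degree;
#' a chosen set of \code{module_size} nodes is additionally wired among
#' itself with probability \code{module_density}, planting a community
#' that is denser than its surroundings (the situation a disease module
#' is assumed to create in the real interactome).
#'
#' @param n_nodes number of genes.
#' @param mean_degree expected background degree.
#' @param module_size planted module size (0 = plain random graph).
#' @param module_density within-module wiring probability; must exceed
#'   the background edge probability.
#' @param seed RNG seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return List with \code{net} (an \code{\link{interactome}}) and
#'   \code{truth} (list with \code{planted_module}).
#' @export
generate_interactome <- function(n_nodes = 600L, mean_degree = 4,
                                 module_size = 40L, module_density = 0.5,
                                 seed = 1L) {
  stopifnot(module_size <= n_nodes, n_nodes >= 2L)
  p_bg <- mean_degree / (n_nodes - 1)
  if (module_size > 0L && (module_density <= p_bg || module_density > 1))
    stop("module_density must lie in (background density, 1]")
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_nodes))
  g <- igraph::sample_gnp(n_nodes, p_bg)
  igraph::V(g)$name <- genes

  module <- character(0L)
  if (module_size > 0L) {
    module <- sort(sample(genes, module_size))
    pairs <- t(utils::combn(module, 2L))
    keep <- stats::runif(nrow(pairs)) < module_density
    if (any(keep))
      g <- igraph::add_edges(g, t(pairs[keep, , drop = FALSE]))
  }
  g <- igraph::simplify(g)
  el <- igraph::as_edgelist(g)
  list(net = interactome(el), truth = list(planted_module = module))
}

#' Generate a case/control expression matrix with planted structure
#'
#' Emulates the statistical structure switch-gene detection assumes:
#' co-expression blocks sharing a latent factor, differentially expressed
#' genes with specified log-fold-changes, and "connector" genes whose
#' profile is the negative of a mixture of two or more block factors --
#' so their correlation-network neighbours span blocks and correlate
#' negatively with them. Additive per-gene batch shifts (and optional
#' batch scaling) are applied last.
#'
#' Gene roles are assigned deterministically: connector genes are the
#' ones named in \code{connector_genes}; block genes are the first
#' \code{sum(block_sizes)} remaining names; \code{extra_deg_n} pure-noise
#' genes follow; the rest are unstructured nulls. A block gene with
#' loading \eqn{a} is \eqn{a f_b + \sigma \epsilon} around its baseline;
#' its planted block correlation is therefore
#' \eqn{a_i a_j / \sqrt{(a_i^2+\sigma^2)(a_j^2+\sigma^2)}}.
#'
#' @param gene_names character vector of gene symbols (namespace shared
#'   with the interactome when used in the full pipeline).
#' @param n_case,n_control samples per group.
#' @param n_batches number of batches (samples assigned round-robin
#'   within each group, so batches are balanced).
#' @param block_sizes sizes of the co-expression blocks.
#' @param block_loading range (lo, hi) of per-gene factor loadings.
#' @param block_lfc log-fold-change planted on every block gene.
#' @param connector_genes genes built as anti-correlated connectors.
#' @param connector_blocks how many blocks each connector mixes (>= 2).
#' @param connector_lfc log-fold-change planted on connectors; must be
#'   non-zero when connectors exist (connectors are DEGs by construction).
#' @param extra_deg_n,extra_deg_lfc pure-noise genes given a planted shift.
#' @param noise_sd per-gene noise standard deviation (> 0).
#' @param connector_noise noise sd of connector profiles.
#' @param batch_shift_sd sd of the per-gene additive shift of each
#'   non-reference batch.
#' @param batch_scale multiplicative scale per batch (recycled).
#' @param seed RNG seed.
#' @return List with \code{expr} (an \code{\link{expr_set}}) and
#'   \code{truth}: \code{planted_degs} (named lfc vector),
#'   \code{planted_clusters} (gene -> block), \code{planted_connectors},
#'   \code{batch_effects} (per-batch shift vectors and scales).
#' @export
generate_expression <- function(gene_names, n_case, n_control,
                                n_batches = 2L,
                                block_sizes = c(50L, 50L),
                                block_loading = c(0.6, 1.1),
                                block_lfc = 0,
                                connector_genes = character(0L),
                                connector_blocks = 2L,
                                connector_lfc = 1,
                                extra_deg_n = 0L, extra_deg_lfc = 0,
                                noise_sd = 1, connector_noise = 0.2,
                                batch_shift_sd = 0, batch_scale = 1,
                                seed = 1L) {
  if (noise_sd <= 0) stop("noise_sd must be positive")
  n_blocks <- length(block_sizes)
  if (length(connector_genes) > 0L) {
    if (connector_blocks < 2L || connector_blocks > n_blocks)
      stop("each connector must mix between 2 and length(block_sizes) blocks")
    if (connector_lfc == 0)
      stop("connectors are planted DEGs; connector_lfc must be non-zero")
    if (!all(connector_genes %in% gene_names))
      stop("connector_genes must be drawn from gene_names")
  }
  n_genes <- length(gene_names)
  if (sum(block_sizes) + length(connector_genes) + extra_deg_n > n_genes)
    stop("roles exceed the number of genes")

  set.seed(seed)
  n_s <- n_case + n_control
  sample_ids <- c(sprintf("case_%03d", seq_len(n_case)),
                  sprintf("ctrl_%03d", seq_len(n_control)))
  group <- c(rep("case", n_case), rep("control", n_control))
  batch <- paste0("b", c((seq_len(n_case) - 1L) %% n_batches + 1L,
                         (seq_len(n_control) - 1L) %% n_batches + 1L))

  pool <- setdiff(gene_names, connector_genes)
  block_genes <- vector("list", n_blocks)
  off <- 0L
  for (b in seq_len(n_blocks)) {
    block_genes[[b]] <- pool[(off + 1L):(off + block_sizes[b])]
    off <- off + block_sizes[b]
  }
  extra_deg <- if (extra_deg_n > 0L) pool[(off + 1L):(off + extra_deg_n)] else character(0L)

  # latent block factors, one value per sample
  factors <- matrix(stats::rnorm(n_blocks * n_s), nrow = n_blocks)
  baseline <- stats::setNames(stats::runif(n_genes, 5, 9), gene_names)
  v <- matrix(stats::rnorm(n_genes * n_s, sd = noise_sd), nrow = n_genes,
              dimnames = list(gene_names, sample_ids))

  clusters <- stats::setNames(integer(0L), character(0L))
  for (b in seq_len(n_blocks)) {
    gs <- block_genes[[b]]
    loadings <- stats::runif(length(gs), block_loading[1L], block_loading[2L])
    v[gs, ] <- v[gs, , drop = FALSE] + outer(loadings, factors[b, ])
    clusters[gs] <- b
  }
  conn_mix <- list()
  for (g in connector_genes) {
    mix <- sort(sample(seq_len(n_blocks), connector_blocks))
    prof <- -colSums(factors[mix, , drop = FALSE]) / sqrt(connector_blocks)
    v[g, ] <- prof + stats::rnorm(n_s, sd = connector_noise)
    conn_mix[[g]] <- mix
  }

  lfc <- c(
    stats::setNames(rep(block_lfc, sum(block_sizes)), unlist(block_genes)),
    stats::setNames(rep(connector_lfc, length(connector_genes)), connector_genes),
    stats::setNames(rep(extra_deg_lfc, length(extra_deg)), extra_deg)
  )
  lfc <- lfc[lfc != 0]
  if (length(lfc) > 0L)
    v[names(lfc), group == "case"] <- v[names(lfc), group == "case", drop = FALSE] + lfc

  v <- v + baseline

  batch_scale <- rep_len(batch_scale, n_batches)
  shifts <- list()
  for (b in seq_len(n_batches)) {
    bn <- paste0("b", b)
    sh <- if (b == 1L || batch_shift_sd == 0) {
      stats::setNames(rep(0, n_genes), gene_names)
    } else {
      stats::setNames(stats::rnorm(n_genes, sd = batch_shift_sd), gene_names)
    }
    j <- batch == bn
    if (any(j)) {
      centred <- v[, j, drop = FALSE] - rowMeans(v[, j, drop = FALSE])
      v[, j] <- centred * batch_scale[b] + rowMeans(v[, j, drop = FALSE]) + sh
    }
    shifts[[bn]] <- list(shift = sh, scale = batch_scale[b])
  }

  truth <- list(
    planted_degs = lfc,
    planted_clusters = clusters,
    planted_connectors = connector_genes,
    connector_blocks = conn_mix,
    batch_effects = shifts
  )
  list(expr = expr_set(v, group = group, batch = batch), truth = truth)
}

#' Generate a gene-set collection with one term covering the planted module
#'
#' The first term holds the planted module together with the seed genes
#' (so the seeds are enriched in it and module members count as
#' biologically annotated); the remaining terms are random draws from the
#' full gene universe, giving the enrichment background broad coverage.
#'
#' @param genes full gene universe.
#' @param planted genes of the planted term (module plus seeds).
#' @param n_random number of random decoy terms.
#' @param term_size size of each decoy term.
#' @param seed RNG seed.
#' @return A \code{gene_set_collection}.
#' @export
generate_gene_sets <- function(genes, planted, n_random = 19L,
                               term_size = 40L, seed = 1L) {
  set.seed(seed)
  sets <- c(
    list(PLANTED_PATHWAY = sort(unique(planted))),
    stats::setNames(
      lapply(seq_len(n_random), function(i) sort(sample(genes, term_size))),
      sprintf("RANDOM_%02d", seq_len(n_random))
    )
  )
  structure(sets, class = "gene_set_collection")
}

#' Generate a complete synthetic input bundle with planted ground truth
#'
#' Builds a coherent scenario for the end-to-end pipeline: an interactome
#' with a planted dense module, seed genes drawn from that module, an
#' expression matrix in the same gene namespace whose planted connectors
#' are module members that are not seeds (the recoverable overlap), and a
#' gene-set collection in which the seeds are enriched. Every pipeline
#' stage can be scored against the returned truth without external data.
#'
#' @param preset currently \code{"paper-small"}: 600-gene interactome
#'   (mean degree 10, 30-gene module at density 0.35 -- module degrees
#'   stay inside degree bins the background populates, so degree-matched
#'   null draws have real choice), 15 seeds, 10 overlap connectors,
#'   60+60 samples in 2 batches, two 50-gene co-expression blocks,
#'   planted log-fold-change 1.5 at unit noise.
#' @param seed master RNG seed.
#' @param out_dir optional; when given, the bundle is written as
#'   \code{edges.tsv}, \code{seeds.txt}, \code{expr.tsv}, \code{meta.tsv},
#'   \code{sets.gmt} and \code{truth.json}.
#' @return List with \code{net}, \code{seeds}, \code{expr},
#'   \code{collection}, \code{truth} (including \code{planted_overlap},
#'   the genes the full pipeline should recover).
#' @export
generate_bundle <- function(preset = "paper-small", seed = 1L, out_dir = NULL) {
  preset <- match.arg(preset)
  si <- generate_interactome(n_nodes = 600L, mean_degree = 10,
                             module_size = 30L, module_density = 0.35,
                             seed = seed)
  set.seed(seed + 1L)
  module <- si$truth$planted_module
  seeds <- sort(sample(module, 15L))
  overlap <- sort(sample(setdiff(module, seeds), 10L))

  se <- generate_expression(
    gene_names = interactome_genes(si$net),
    n_case = 60L, n_control = 60L, n_batches = 2L,
    block_sizes = c(50L, 50L), block_loading = c(0.6, 1.1),
    block_lfc = 1.5,
    connector_genes = overlap, connector_blocks = 2L, connector_lfc = 1.5,
    extra_deg_n = 60L, extra_deg_lfc = 1.5,
    noise_sd = 1, batch_shift_sd = 1,
    seed = seed + 2L
  )
  collection <- generate_gene_sets(
    genes = interactome_genes(si$net),
    planted = union(module, seeds),
    n_random = 19L, term_size = 40L, seed = seed + 3L
  )
  truth <- c(si$truth, se$truth,
             list(seeds = seeds, planted_overlap = overlap))
  bundle <- list(net = si$net, seeds = seeds, expr = se$expr,
                 collection = collection, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_edge_list(bundle$net, file.path(out_dir, "edges.tsv"))
    writeLines(seeds, file.path(out_dir, "seeds.txt"))
    write_expression_tsv(bundle$expr, file.path(out_dir, "expr.tsv"),
                         file.path(out_dir, "meta.tsv"))
    write_gmt(collection, file.path(out_dir, "sets.gmt"))
    jsonlite::write_json(
      list(planted_module = module, seeds = seeds,
           planted_overlap = overlap,
           planted_connectors = truth$planted_connectors,
           planted_degs = as.list(truth$planted_degs)),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  bundle
}
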