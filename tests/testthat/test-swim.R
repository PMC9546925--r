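test_that("flat genes are never called differentially expressed", {
  set.seed(12)
  case <- matrix(rnorm(40), 4, 10)
  ctrl <- case + 0  # identical group means gene-wise by construction
  es <- make_expr(case, ctrl)
  tab <- differential_expression(es, keep_all = TRUE)
  expect_true(all(abs(tab$logFC) < 1e-12))
  expect_false(any(tab$retained))
  expect_true(all(tab$FDR >= tab$p - 1e-15))
  expect_error(differential_expression(make_expr(case[, 1, drop = FALSE], ctrl)),
               "at least 2 samples")
})

test_that("Welch test matches t.test gene-wise", {
  set.seed(33)
  case <- matrix(rnorm(60, sd = rep(c(1, 3), each = 30)), nrow = 6)
  ctrl <- matrix(rnorm(72), nrow = 6)
  es <- make_expr(case, ctrl)
  tab <- differential_expression(es, keep_all = TRUE)
  for (i in seq_len(6)) {
    tt <- t.test(case[i, ], ctrl[i, ])
    expect_equal(tab$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("planted shifts are recovered with near-zero false positives", {
  b <- generate_expression(sprintf("g%04d", 1:1050), n_case = 100L,
                           n_control = 100L, n_batches = 1L,
                           block_sizes = integer(0L),
                           extra_deg_n = 50L, extra_deg_lfc = 2,
                           noise_sd = 1, seed = 42L)
  tab <- differential_expression(b$expr, fdr_threshold = 0.001)
  planted <- names(b$truth$planted_degs)
  expect_gte(length(intersect(tab$gene, planted)), 48L)  # >= 95 % recovery
  expect_lte(length(setdiff(tab$gene, planted)), 2L)
})

test_that("fold-change threshold 1 on log-scale data keeps every gene", {
  set.seed(8)
  case <- matrix(rnorm(40, mean = 5), 4, 10)
  ctrl <- matrix(rnorm(40, mean = 5), 4, 10)
  es <- make_expr(case, ctrl)
  t1 <- differential_expression(es, fc_threshold = 1, fdr_threshold = 1,
                                keep_all = TRUE)
  expect_true(all(t1$retained))
  expect_identical(t1$direction, ifelse(t1$logFC > 0, "up", "down"))
})

test_that("connectivity profile spans complete graph to singletons", {
  set.seed(55)
  b <- generate_expression(sprintf("g%02d", 1:12), n_case = 30L, n_control = 4L,
                           block_sizes = integer(0L), seed = 55L)
  genes <- rownames(b$expr$values)
  prof <- connectivity_profile(b$expr, genes, thresholds = c(0, 1))
  expect_equal(prof$lcc_fraction[1L], 1)          # |r| > 0: complete graph
  expect_equal(prof$lcc_fraction[2L], 1 / 12)     # |r| > 1: all singletons
  expect_error(connectivity_profile(b$expr, genes, numeric(0L)), "empty")

  # two perfectly correlated genes among three at a high threshold
  v <- rbind(g1 = c(1, 2, 3, 4, 5), g2 = c(2, 4, 6, 8, 10),
             g3 = c(5, 1, 4, 2, 3))
  colnames(v) <- paste0("s", 1:5)
  es <- expr_set(v, group = c(rep("case", 4), "control"))
  p <- connectivity_profile(es, rownames(v), 0.9, samples = "all")
  expect_equal(p$lcc_fraction, 2 / 3)
})

test_that("correlation network honours the percentile threshold convention", {
  set.seed(77)
  b <- generate_expression(sprintf("g%03d", 1:60), n_case = 40L, n_control = 5L,
                           block_sizes = c(20L, 20L), block_loading = c(0.7, 1),
                           seed = 77L)
  genes <- rownames(b$expr$values)
  net <- build_correlation_network(b$expr, genes, percentile = 83)
  r <- cor(t(b$expr$values[genes, b$expr$group == "case"]))
  expect_equal(net$threshold,
               unname(quantile(abs(r[upper.tri(r)]), 0.83, type = 7)),
               tolerance = 1e-12)
  w <- igraph::E(net$graph)$weight
  expect_true(all(abs(w) > net$threshold))
  expect_true(all(igraph::degree(net$graph) > 0))  # isolated genes dropped

  # edge weights are signed Pearson correlations (two-pass oracle)
  el <- igraph::as_edgelist(net$graph)
  vc <- b$expr$values[, b$expr$group == "case"]
  for (i in sample(nrow(el), 5L)) {
    expect_equal(w[i], pearson_two_pass(vc[el[i, 1L], ], vc[el[i, 2L], ]),
                 tolerance = 1e-12)
  }

  # strong negative correlation still makes an edge (absolute-value rule)
  v <- rbind(a = c(1, 2, 3, 4, 6), b = -c(1, 2, 3, 4.2, 5.8), c = c(2, 0, 1, 0, 2))
  colnames(v) <- paste0("s", 1:5)
  es <- expr_set(v, group = c(rep("case", 4), "control"))
  n2 <- build_correlation_network(es, rownames(v), percentile = 60,
                                  samples = "all")
  eids <- igraph::as_edgelist(n2$graph)
  expect_true(any(apply(eids, 1L, setequal, y = c("a", "b"))))
})

test_that("edge set is invariant to sample and gene ordering", {
  set.seed(10)
  b <- generate_expression(sprintf("g%03d", 1:40), n_case = 30L, n_control = 4L,
                           block_sizes = c(15L, 15L), seed = 10L)
  genes <- rownames(b$expr$values)
  key <- function(net) {
    e <- igraph::as_edgelist(net$graph)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  n1 <- build_correlation_network(b$expr, genes, 80)
  perm_s <- sample(ncol(b$expr$values))
  es2 <- expr_set(b$expr$values[sample(nrow(b$expr$values)), perm_s],
                  group = b$expr$group[perm_s], batch = b$expr$batch[perm_s])
  n2 <- build_correlation_network(es2, genes, 80)
  expect_identical(key(n1), key(n2))
})

test_that("k-means recovers planted blocks and behaves at the extremes", {
  b <- generate_expression(sprintf("g%03d", 1:46), n_case = 60L, n_control = 4L,
                           block_sizes = c(20L, 20L), block_loading = c(0.8, 1.1),
                           seed = 14L)
  genes <- names(b$truth$planted_clusters)
  net <- build_correlation_network(b$expr, genes, percentile = 40)
  labels <- cluster_network(net, k = 2L, seed = 3L)
  truth <- b$truth$planted_clusters[names(labels)]
  agree <- max(mean((labels == 1L) == (truth == 1L)),
               mean((labels == 1L) == (truth == 2L)))
  expect_gte(agree, 0.95)

  expect_error(cluster_network(net, k = length(labels) + 50L), "exceeds")
  # k = node count: singleton clusters
  sing <- cluster_network(net, k = length(labels), seed = 3L)
  expect_equal(length(unique(sing)), length(sing))
  # determinism under a fixed seed
  expect_identical(labels, cluster_network(net, k = 2L, seed = 3L))
})

test_that("APCC limits and symmetric mean follow the closed forms", {
  edges <- cbind("h", paste0("n", 1:6))
  net_neg <- make_corr_net(edges, rep(-1, 6L))
  expect_equal(unname(compute_apcc(net_neg)["h"]), -1)
  net_pos <- make_corr_net(edges, rep(1, 6L))
  expect_equal(unname(compute_apcc(net_pos)["h"]), 1)
  net_mix <- make_corr_net(edges, c(0.9, 0.9, 0.9, -0.9, -0.9, -0.9))
  expect_equal(unname(compute_apcc(net_mix)["h"]), 0)
  # degree-5 node is not a hub: absent from the APCC output
  net5 <- make_corr_net(cbind("h", paste0("n", 1:5)), rep(0.5, 5L))
  expect_length(compute_apcc(net5), 0L)
})

test_that("hub classes follow the APCC boundaries and the degree cutoff", {
  deg <- c(a = 8L, b = 5L, c = 9L, d = 7L)
  apcc <- c(a = -0.3, b = -0.9, c = 0.9, d = 0.2)
  cls <- classify_hubs(apcc, deg)
  expect_identical(unname(cls["a"]), "fight-club")
  expect_identical(unname(cls["b"]), "non-hub")   # degree 5 boundary
  expect_identical(unname(cls["c"]), "party")
  expect_identical(unname(cls["d"]), "date")
})

test_that("cartography closed forms: Kpi limits and zero-variance z", {
  # triangle cluster 1 + triangle cluster 2, plus one bridge-only node
  edges <- rbind(c("a1", "a2"), c("a2", "a3"), c("a1", "a3"),
                 c("b1", "b2"), c("b2", "b3"), c("b1", "b3"),
                 c("x", "a1"), c("x", "b1"))
  net <- make_corr_net(edges, rep(0.9, nrow(edges)))
  labels <- c(a1 = 1L, a2 = 1L, a3 = 1L, b1 = 2L, b2 = 2L, b3 = 2L, x = 3L)
  carto <- compute_cartography(net, labels)
  rownames(carto) <- carto$gene
  expect_equal(carto["a2", "Kpi"], 0)       # all edges internal
  expect_equal(carto["x", "Kpi"], 1)        # all edges external
  # clusters with constant kappa: z = 0 throughout, and z sums to 0
  expect_equal(carto$z, rep(0, 7L))
  expect_true(all(carto$Kpi >= 0 & carto$Kpi <= 1))
  expect_true(all(carto$kappa <= carto$degree))
  expect_error(compute_cartography(net, labels[-1L]), "cluster label")
})

test_that("z sums to zero within clusters when kappa varies", {
  set.seed(91)
  b <- generate_expression(sprintf("g%03d", 1:50), n_case = 40L, n_control = 4L,
                           block_sizes = c(20L, 20L), seed = 91L)
  net <- build_correlation_network(b$expr, rownames(b$expr$values), 70)
  labels <- cluster_network(net, k = 2L, seed = 1L)
  carto <- compute_cartography(net, labels)
  expect_true(all(is.finite(carto$z)))
  for (cl in unique(carto$cluster)) {
    zc <- carto$z[carto$cluster == cl]
    if (sd(carto$kappa[carto$cluster == cl]) > 0)
      expect_lt(abs(sum(zc)), 1e-8)
  }
})

test_that("switch calling needs fight-club class, high Kpi and low z", {
  carto <- data.frame(
    gene = c("s", "p", "f"),
    cluster = 1L, degree = 10L, kappa = 1L,
    z = c(1.0, 0.5, 0.5), Kpi = c(0.9, 0.9, 0.5),
    class = c("fight-club", "party", "fight-club"),
    stringsAsFactors = FALSE
  )
  expect_identical(call_switch_genes(carto), "s")
})

test_that("planted connectors are called switch; planted hubs are not", {
  genes <- sprintf("g%03d", 1:300)
  conn <- sprintf("g%03d", 291:300)
  b <- generate_expression(genes, n_case = 60L, n_control = 60L,
                           block_sizes = c(50L, 50L),
                           block_loading = c(0.6, 1.1), block_lfc = 1.5,
                           connector_genes = conn, connector_lfc = 1.5,
                           extra_deg_n = 60L, extra_deg_lfc = 1.5,
                           noise_sd = 1, seed = 19L)
  res <- swim_analysis(b$expr, k = 3L, seed = 19L)
  called <- res$switch_genes
  expect_gte(length(intersect(called, conn)), 9L)  # >= 90 % recovery
  hubs <- names(res$apcc)
  false_calls <- setdiff(intersect(called, hubs), conn)
  expect_lte(length(false_calls), max(1L, floor(0.05 * length(setdiff(hubs, conn)))))
  # APCC of planted connectors is negative by construction
  expect_gte(sum(res$apcc[intersect(conn, hubs)] < 0), 9L)
})
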