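test_that("edge-list reading collapses duplicates, reverses and self-loops", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "C\tC", "A\tB"), f)
  net <- read_edge_list(f)
  expect_equal(n_nodes(net), 2L)
  expect_equal(n_edges(net), 1L)
  expect_setequal(interactome_genes(net), c("A", "B"))

  # path of 4 distinct edges on 5 nodes, with a header line
  writeLines(c("from\tto", "a\tb", "b\tc", "c\td", "d\te"), f)
  net2 <- read_edge_list(f)
  expect_equal(n_nodes(net2), 5L)
  expect_equal(n_edges(net2), 4L)
})

test_that("edge-list reading rejects empty and malformed files", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0L), f)
  expect_error(read_edge_list(f), "empty")
  writeLines(c("A\tB", "C"), f)
  expect_error(read_edge_list(f), "line 2")
})

test_that("write/read round trip reproduces node and edge sets", {
  f <- withr::local_tempfile(fileext = ".tsv")
  net <- generate_interactome(n_nodes = 60L, mean_degree = 4,
                              module_size = 0L, seed = 11L)$net
  write_edge_list(net, f)
  back <- read_edge_list(f)
  expect_setequal(interactome_genes(back), interactome_genes(net))
  el <- function(x) {
    e <- igraph::as_edgelist(x$graph)
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  expect_identical(el(back), el(net))
})

test_that("probe collapsing averages probes per gene, in lexicographic order", {
  v <- rbind(p1 = c(1, 5), p2 = c(3, 7), p3 = c(10, 20), p4 = c(0, 0),
             p5 = c(3, 3), p6 = c(6, 6))
  colnames(v) <- c("s1", "s2")
  pm <- c(p1 = "Gb", p2 = "Gb", p3 = "Ga", p4 = "Gc", p5 = "Gc", p6 = "Gc")
  es <- collapse_probes(v, pm, group = c("case", "control"))
  expect_identical(rownames(es$values), c("Ga", "Gb", "Gc"))
  expect_equal(unname(es$values["Gb", ]), c(2, 6))   # mean of two probes
  expect_equal(unname(es$values["Ga", ]), c(10, 20)) # single probe copied
  expect_equal(unname(es$values["Gc", "s1"]), 3)     # mean of 0, 3, 6

  # unmapped probes dropped with a logged count; none mappable is an error
  pm2 <- c(p1 = "G1")
  expect_message(collapse_probes(v[1:2, ], pm2, group = c("case", "control")),
                 "dropped 1")
  expect_error(collapse_probes(v, c(px = "G"), group = c("case", "control")),
               "no probe")
})

test_that("probe collapsing is invariant to probe-row order", {
  set.seed(4)
  v <- matrix(rnorm(12), nrow = 6,
              dimnames = list(paste0("p", 1:6), c("s1", "s2")))
  pm <- setNames(rep(c("GA", "GB", "GC"), each = 2L), rownames(v))
  a <- collapse_probes(v, pm, group = c("case", "control"))
  b <- collapse_probes(v[sample(6), ], pm, group = c("case", "control"))
  expect_equal(a$values, b$values)
})

test_that("batch merging intersects genes and concatenates samples", {
  va <- matrix(1, 3, 2, dimnames = list(c("A", "B", "C"), c("x1", "x2")))
  vb <- matrix(2, 3, 3, dimnames = list(c("B", "C", "D"), c("y1", "y2", "y3")))
  a <- expr_set(va, group = c("case", "control"))
  b <- expr_set(vb, group = c("case", "case", "control"))
  m <- merge_batches(a, b)
  expect_identical(rownames(m$values), c("B", "C"))
  expect_equal(ncol(m$values), 5L)
  expect_identical(m$batch, c("batch1", "batch1", rep("batch2", 3L)))

  vc <- matrix(0, 2, 2, dimnames = list(c("X", "Y"), c("z1", "z2")))
  cc <- expr_set(vc, group = c("case", "control"))
  expect_error(merge_batches(a, cc), "no gene symbols shared")

  # identical gene lists: everything retained
  m2 <- merge_batches(a, expr_set(va + 1, group = a$group) |>
                        (\(e) {colnames(e$values) <- c("w1", "w2"); e})())
  expect_identical(rownames(m2$values), c("A", "B", "C"))
})

test_that("batch correction removes additive and multiplicative batch structure", {
  set.seed(21)
  n <- 50L
  genes <- sprintf("g%03d", 1:200)
  b1 <- matrix(rnorm(200 * n, sd = 1), nrow = 200, dimnames = list(genes, sprintf("a%02d", 1:n)))
  shift <- 2
  b2 <- matrix(rnorm(200 * n, sd = 1) + shift, nrow = 200,
               dimnames = list(genes, sprintf("b%02d", 1:n)))
  es <- expr_set(cbind(b1, b2) + 6,
                 group = rep(c("case", "control"), n),
                 batch = rep(c("b1", "b2"), each = n))

  batch_diff <- function(out) {
    rowMeans(out$values[, out$batch == "b1"]) -
      rowMeans(out$values[, out$batch == "b2"])
  }
  raw <- batch_diff(es)

  # location-scale standardization equalizes per-batch gene means exactly
  out_std <- batch_correct(es, method = "standardize")
  expect_identical(dim(out_std$values), dim(es$values))
  expect_identical(out_std$group, es$group)
  expect_gt(mean(abs(batch_diff(out_std)) < 0.1), 0.95)

  # empirical Bayes removes the common shift; per-gene residuals stay
  # within sampling noise (EB shrinkage does not zero them exactly)
  out_eb <- batch_correct(es, method = "eb")
  d <- batch_diff(out_eb)
  expect_identical(dim(out_eb$values), dim(es$values))
  expect_lt(abs(mean(d)), 0.05)
  expect_gt(mean(abs(d) < 0.5), 0.95)
  expect_lt(sd(d), sd(raw - mean(raw)) + 0.05)
})

test_that("batch correction handles degenerate inputs per contract", {
  v <- matrix(rnorm(40), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  single <- expr_set(v, group = rep(c("case", "control"), 5))
  expect_identical(batch_correct(single)$values, single$values)

  uneven <- expr_set(v, group = rep(c("case", "control"), 5),
                     batch = c(rep("b1", 9), "b2"))
  expect_error(batch_correct(uneven), "at least 2 samples")

  # constant gene within a batch: location-only pass-through with warning
  v2 <- v
  v2[1, 1:5] <- 3
  zv <- expr_set(v2, group = rep(c("case", "control"), 5),
                 batch = rep(c("b1", "b2"), each = 5))
  expect_warning(out <- batch_correct(zv, method = "standardize"),
                 "zero variance")
  expect_equal(dim(out$values), dim(v2))
  expect_true(all(is.finite(out$values)))
})

test_that("GMT reading parses terms, dedupes genes, rejects bad lines", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tA\tB\tA", "T2\tdesc\tC"), f)
  gs <- read_gmt(f)
  expect_length(gs, 2L)
  expect_setequal(gs$T1, c("A", "B"))

  writeLines(c("T1\tdesc"), f)
  expect_error(read_gmt(f), "fewer than 3")
  writeLines(c("T1\td\tA", "T1\td\tB"), f)
  expect_error(read_gmt(f), "duplicate term")
})

test_that("expression TSV round trip preserves values and labels", {
  b <- generate_expression(sprintf("g%02d", 1:20), n_case = 4L, n_control = 4L,
                           block_sizes = integer(0L), seed = 5L)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_tsv(b$expr, f1, f2)
  back <- read_expression_tsv(f1, f2)
  expect_equal(back$values, b$expr$values, tolerance = 1e-12)
  expect_identical(back$group, b$expr$group)
  expect_identical(back$batch, b$expr$batch)
})
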