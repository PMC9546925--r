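#!/usr/bin/env Rscript
# Stage 3: detect switch genes in the case/control expression data.
#
# After ComBat batch correction, DEGs (Welch t, BH FDR <= 0.001) define a
# co-expression network thresholded at the 83rd percentile of |r|; the
# network is clustered by k-means on the correlation rows, hubs are
# classified by their average neighbour correlation (APCC), and switch
# genes are the fight-club hubs (APCC < 0) that connect mostly outside
# their own cluster (Kpi > 0.8) without being local hubs (z < 2.5).

suppressPackageStartupMessages(library(netsig))

SEED <- 7L
expr <- read_expression_tsv("results/bundle/expr.tsv", "results/bundle/meta.tsv")
expr <- batch_correct(expr, method = "eb")

res <- swim_analysis(expr, fc_threshold = 1, fdr_threshold = 0.001,
                     percentile = 83, k = 3L, seed = SEED)

write.table(as.data.frame(res$deg), "results/deg_table.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
el <- igraph::as_edgelist(res$network$graph)
write.table(data.frame(gene1 = el[, 1], gene2 = el[, 2],
                       r = igraph::E(res$network$graph)$weight),
            "results/correlation_network.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(res$cartography, "results/cartography.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

up_switch <- filter_switch_candidates(res$cartography, res$deg,
                                      direction = "up",
                                      cluster_rule = "majority")
writeLines(up_switch, "results/switch_candidates.txt")

message(nrow(res$deg), " DEGs; network of ",
        igraph::vcount(res$network$graph), " nodes at |r| > ",
        sprintf("%.3f", res$network$threshold))
message(length(res$switch_genes), " switch genes; ",
        length(up_switch), " up-regulated in the majority cluster")
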