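#!/usr/bin/env Rscript
# Stage 2: rank candidate disease genes by connectivity significance and
# bound the list with the sliding-window biological criterion.
#
# Candidates are admitted one per iteration by the lowest hypergeometric
# upper-tail probability of their links into the growing module. The
# boundary is the last iteration at which the window of recent candidates
# is still enriched (p <= 0.01) for the seed-associated annotations.

suppressPackageStartupMessages(library(netsig))

net <- read_edge_list("results/bundle/edges.tsv")
seeds <- read_gene_list("results/bundle/seeds.txt")
collection <- read_gmt("results/bundle/sets.gmt")

ranking <- run_diamond(net, seeds, n_iter = 100L)
write.table(as.data.frame(ranking), "results/diamond_ranking.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

background <- intersect(interactome_genes(net), unique(unlist(collection)))
terms <- seed_enriched_terms(seeds, collection, background, alpha = 0.05)
enriched_genes <- unique(unlist(collection[terms]))
report <- sliding_window_significance(ranking, enriched_genes,
                                      window = length(seeds),
                                      background = background)
boundary <- select_module_boundary(report, threshold = 0.01)
write.table(as.data.frame(report), "results/boundary_report.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(head(ranking$gene, boundary), "results/diamond_candidates.txt")

message("ranked ", nrow(ranking), " candidates; ",
        length(terms), " seed-enriched term(s)")
message("biological criterion bounds the list at iteration ", boundary)
message("connectivity significance of kept candidates: ",
        sprintf("%.2e .. %.2e", min(ranking$p_value[seq_len(boundary)]),
                max(ranking$p_value[seq_len(boundary)])))
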