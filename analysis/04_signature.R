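#!/usr/bin/env Rscript
# Stage 4: intersect the two candidate sets into the disease signature
# and validate that seeds + signature form a significant interactome
# module against degree-preserving random gene sets.

suppressPackageStartupMessages(library(netsig))

SEED <- 7L
net <- read_edge_list("results/bundle/edges.tsv")
seeds <- read_gene_list("results/bundle/seeds.txt")
diamond_candidates <- read_gene_list("results/diamond_candidates.txt")
switch_candidates <- read_gene_list("results/switch_candidates.txt")

signature <- intersect_candidates(diamond_candidates, switch_candidates,
                                  seeds = seeds)
assembled <- sort(union(intersect(seeds, interactome_genes(net)), signature))
writeLines(signature, "results/signature.txt")
writeLines(assembled, "results/assembled_module.txt")

report <- module_significance(net, assembled, n_rep = 1000L, seed = SEED)
write.table(as.data.frame(report), "results/module_significance.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

truth <- jsonlite::read_json("results/bundle/truth.json", simplifyVector = TRUE)
recovered <- intersect(signature, truth$planted_overlap)

message("signature: ", length(signature), " genes (",
        paste(signature, collapse = ", "), ")")
message("planted-overlap recovery: ", length(recovered), "/",
        length(truth$planted_overlap))
lcc <- report[report$metric == "lcc_size", ]
message(sprintf(
  "assembled module: %d genes, LCC %d (null %.1f +/- %.1f, z = %.2f, p = %.2g)",
  length(assembled), lcc$observed, lcc$random_mean, lcc$random_sd,
  lcc$z, lcc$p_normal))
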