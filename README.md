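# netsig — disease gene signatures from interactome and co-expression networks

`netsig` implements a network-medicine pipeline that enlarges a set of
known disease genes (seeds) into a validated disease module by combining
two complementary sources of evidence:

1. **Topological evidence** from the protein–protein interactome:
   candidates are ranked by *connectivity significance* — for a protein
   of degree *k* with *k*ₛ links to the current seed set of size *s* in an
   interactome of *N* proteins,

   p = P(X ≥ kₛ),  X ~ Hypergeometric(N, s, k),

   and the lowest-p protein is admitted to the module at every iteration
   (DIAMOnD-style expansion). The open-ended ranking is bounded by a
   *biological criterion*: a window of recent candidates slides along the
   ranking, and the last iteration at which the window is still enriched
   (hypergeometric p ≤ 0.01) for the seeds' own functional annotations
   defines the cutoff.

2. **Phenotype-specific evidence** from case/control expression data:
   differentially expressed genes (Welch t-test, BH FDR) define a
   co-expression network thresholded at a percentile of |Pearson r|;
   the network is clustered by k-means on the correlation rows, hubs
   (degree > 5) are classified by their average neighbour correlation
   (APCC) into date / party / *fight-club* classes, and **switch genes**
   are the fight-club hubs (APCC < 0) with high clusterphobic coefficient
   K<sub>π</sub> = 1 − (κ/k)² > 0.8 and low within-module degree
   z < 2.5 — anti-correlated connectors between co-expression modules.

The signature is the intersection of the bounded interactome candidates
with the direction- and cluster-filtered switch genes. Seeds plus
signature are then validated as an interactome module: the size of the
largest connected component (LCC), its edge count and the total induced
edge count are z-scored against 1,000 random gene sets drawn with the
same size and (log-binned) degree distribution, expecting upper-tail
p ≤ 0.05.

Because the published analyses of this kind depend on large external
snapshots (a curated interactome, GEO expression series, a pathway
database), the package ships a first-class synthetic-data module that
generates all inputs with planted ground truth — a dense interactome
module, expression blocks, planted DEGs and anti-correlated connector
genes — so every stage, and the end-to-end pipeline, is scored against
known truth.

## Worked example

The `analysis/` directory holds the four-stage workflow on the synthetic
study bundle (each script is a thin driver over exported functions):

```sh
Rscript analysis/01_simulate.R      # inputs with planted truth
Rscript analysis/02_diamond.R      # candidate ranking + boundary
Rscript analysis/03_switch_genes.R # DEGs, correlation network, switch genes
Rscript analysis/04_signature.R    # intersection + module validation
```

which prints (seed 7):

```
interactome: 600 genes, 3326 interactions
seeds: 15 (all inside the 30-gene planted module)
...
ranked 100 candidates; 1 seed-enriched term(s)
biological criterion bounds the list at iteration 25
170 DEGs; network of 143 nodes at |r| > 0.332
13 switch genes; 10 up-regulated in the majority cluster
signature: 10 genes (G0123, G0192, G0249, G0305, G0327, G0368, G0420, G0436, G0493, G0539)
planted-overlap recovery: 10/10
assembled module: 25 genes, LCC 25 (null 15.5 +/- 3.2, z = 2.94, p = 0.0017)
```

The 10-gene signature is exactly the planted overlap — the module genes
that were also built into the expression data as anti-correlated
connectors — and the assembled module (15 seeds + 10 recovered genes) is
fully connected in the interactome while degree-matched random sets
reach an LCC of only ~15.5 of 25 genes.

The same run is available in one call:

```r
library(netsig)
b <- generate_bundle(seed = 7)
res <- run_pipeline(b$net, b$seeds, batch_correct(b$expr), b$collection,
                    n_iter = 100, k = 3, seed = 7)
print(res)
```

For real data, `read_edge_list()`, `read_expression_tsv()`,
`read_gene_list()` and `read_gmt()` load the standard plain-text formats
(two-column edge list, expression + metadata TSV, one-symbol-per-line
seeds, GMT), and `collapse_probes()` / `merge_batches()` /
`batch_correct()` cover probe-level preprocessing.

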