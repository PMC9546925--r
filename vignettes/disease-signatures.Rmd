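---
title: "Detecting disease gene signatures with netsig: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting disease gene signatures with netsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsig)
```

# The problem

Disease-associated genes are not scattered randomly over the human
interactome: they tend to interact with each other and to occupy a
common network neighbourhood (a *disease module*), and they tend to
share cellular functions. `netsig` operationalizes this view for the
common situation where a disease has (i) a list of established
associated genes (from OMIM / GWAS), (ii) a protein–protein interaction
network, and (iii) case/control expression profiles: it proposes new
candidate disease genes supported simultaneously by interactome
topology, by functional similarity to the seeds, and by a distinctive
role in the phenotype-specific co-expression network, then checks that
the enlarged gene set really behaves like a module.

# The model, stage by stage

## Connectivity-significance expansion

Let the interactome have $N$ proteins and let $s_0$ seeds be known. For
a candidate protein with degree $k$ of which $k_s$ links point into the
current seed/module set of size $s$, the connectivity significance is
the hypergeometric upper tail

$$p = \sum_{i = k_s}^{\min(k, s)}
  \frac{\binom{s}{i}\binom{N-s}{k-i}}{\binom{N}{k}} .$$

`run_diamond()` admits the lowest-$p$ candidate at each iteration and
recounts $s \to s+1$, producing a ranked candidate list with the
per-iteration $(k, k_s, p)$ record. Two points the procedure leaves
open are fixed as follows:

* **Links counted against the growing module.** Once admitted, a
  candidate counts as a seed for subsequent iterations ($k_s$ measures
  links to seeds *plus* previously admitted candidates). Some variants
  count links to original seeds only; the growing-module convention
  matches the iterative description the method is usually given.
* **Tie-breaking.** Equal $p$ is broken by larger $k_s$, then by
  lexicographic gene symbol. Ties do occur on sparse synthetic graphs,
  and this rule makes rankings bit-reproducible.
* **Seed weight.** An optional weight $\alpha$ multiplies the
  contribution of the original seeds ($k_s^{\mathrm{eff}} = \alpha
  k_{s_0} + k_{\mathrm{added}}$ with the population enlarged by
  $s_0(\alpha-1)$). The default $\alpha = 1$ is plain counting, which is
  the procedure as normally described; the knob exists because the
  original algorithm family defines it.

Because $s$ grows with every iteration, $p$ values from different
iterations are not comparable, and the ranking by itself does not say
where to stop.

## The biological criterion (boundary selection)

`seed_enriched_terms()` finds the gene-set terms enriched in the seeds
(one-sided hypergeometric test, Benjamini–Hochberg adjusted $p \le
0.05$). A window of size equal to the number of in-network seeds slides
along the ranking; at iteration $t$ it holds positions $\max(1,
t-w+1) \ldots t$ (a shrinking head window for $t < w$, so the profile is
defined from the first iteration). Window members annotated to any
seed-enriched term are true positives, and the enrichment $p$ at $t$ is
the hypergeometric upper tail of drawing that many annotated genes in
$w$ draws from the background. `select_module_boundary()` returns the
*last* iteration with $p \le 0.01$: beyond it, candidates no longer
carry the seeds' functional fingerprint. The background universe is the
set of interactome genes annotated in the collection — the conservative
standard choice; it is a parameter, not a constant.

## Switch genes in the co-expression network

`differential_expression()` performs a per-gene two-sided Welch $t$-test
on log-scale values with BH correction. The defaults FDR $\le 0.001$
and linear fold-change threshold $1$ deserve a note: a fold-change
threshold of $1$ is a no-op (every ratio or its reciprocal is $\ge 1$),
which is deliberate — in blood-based array data of this kind the
retained log fold-changes are tiny (order 0.01–0.03), and the FDR alone
drives the selection. Both are exposed.

The DEGs define a correlation network: all pairwise signed Pearson
coefficients are computed (over the case samples by default — the
network is meant to be phenotype-specific; `samples = "all"` is
available), the threshold is a percentile (default 83) of the $|r|$
distribution over all unordered DEG pairs with linear interpolation
(`quantile` type 7, so the threshold is bit-reproducible), and an edge
requires $|r| >$ threshold. `connectivity_profile()` exposes the
fraction of genes in the largest component as a function of the
threshold, the plot used to judge that a threshold keeps the network
intact yet sparse.

Nodes are clustered by k-means on their rows of the signed correlation
matrix (the feature space is not dictated by the qualitative method
description; correlation rows make nodes with similar co-expression
profiles cluster together regardless of direct adjacency). `k` may be
fixed or chosen by the elbow of the within-cluster dispersion curve
over $k = 2..10$. k-means is seeded from the configuration, making
labels deterministic.

Topological roles then follow the heat-cartography scheme:

* hubs are nodes with degree $> 5$;
* APCC is the mean signed correlation between a hub and its network
  neighbours; the hub classes are *fight-club* (APCC $< 0$), *party*
  (APCC $\ge 0.5$) and *date* (otherwise);
* within-module degree $z_i = (\kappa_i - \bar\kappa_{c(i)}) /
  \sigma_{\kappa_{c(i)}}$ (set to 0 when the cluster's $\kappa$ has
  zero spread) and clusterphobic coefficient $K_{\pi,i} = 1 -
  (\kappa_i/k_i)^2$, where $\kappa_i$ counts links inside node $i$'s own
  cluster;
* **switch genes** are fight-club hubs with $K_\pi > 0.8$ and $z < 2.5$.

The APCC boundary 0.5 and the switch thresholds follow the original
switch-miner methodology; the source analysis states only the
qualitative definitions, so these are configuration parameters with
those conventional defaults.

## Intersection and module validation

`filter_switch_candidates()` keeps switch genes with the requested
regulation direction and, by default, those in the single cluster
holding most of them (the published analyses pick "the" coherent
cluster by inspection; the majority rule encodes that choice
reproducibly, with an explicit cluster override). The signature is the
intersection with the bounded candidate list, seeds excluded.

`module_significance()` validates seeds + signature: the observed LCC
size, LCC edges and total induced edges are compared with $n_{\rm rep} =
1000$ random gene sets of the same size and degree distribution.
"Same degree distribution" is operationalized by logarithmic degree
bins (edges doubling: 1, 2, 3–4, 5–8, …) with sampling without
replacement within bins — the standard practice for heavy-tailed
interactomes, configurable to exact-degree matching. The headline $p$
is the one-sided upper-tail normal approximation $P(Z \ge z)$ (module
enrichment has a direction); the add-one-smoothed empirical tail
fraction is always reported alongside, and is the only $p$ reported
when a null distribution degenerates to zero spread. Random sets may
include members of the tested set (an exclusion flag exists, default
off, since exclusion can empty sparse degree bins).

# The synthetic-data module

The generators are first-class, tested code: they define the study
conditions under which every stage is scored.

* `generate_interactome()` plants a `module_size`-gene community wired
  at `module_density` inside an Erdős–Rényi background of given mean
  degree. The background is deliberately *not* scale-free: degree bins
  must be populated for degree-preserving sampling to have genuine
  choice, and at desk scale a heavy tail would leave the planted
  module alone in its bins. The `paper-small` preset (600 genes, mean
  degree 10, 30-gene module at density 0.35) places module degrees
  (~20) in bins the background occupies.
* `generate_expression()` builds genes as latent-factor blocks
  ($x = a f_b + \sigma\varepsilon$, loadings $a \sim U(0.6, 1.1)$ at
  $\sigma = 1$, i.e. planted within-block correlations of roughly
  0.25–0.55), planted DEGs as mean shifts on the case samples, and
  *connectors* as the negative of an equal mixture of $\ge 2$ block
  factors — so each connector correlates negatively with the genes of
  several blocks at $|r|$ comparable to the within-block values, which
  is exactly the geometry a switch gene is defined by. Per-gene batch
  shifts (and optional scales) are applied last. Connectors are always
  planted DEGs; otherwise they could not enter the DEG-restricted
  network at all.
* `generate_bundle()` ties the namespaces together: the expression
  connectors are the non-seed members of the planted interactome
  module, making them the recoverable ground-truth overlap, and the
  gene-set collection contains one term holding module + seeds (so the
  seeds are enriched and module members count as annotated) plus
  random decoy terms.

What the generator does *not* emulate: scale-free degree structure,
probe-level artifacts, heteroscedastic or heavy-tailed expression
noise, correlated null genes, or annotation bias in the gene-set
collection. Passing the planted-truth tests therefore demonstrates
correctness of the machinery under the stated statistical model, not
performance on any particular real dataset.

# Numerical choices and degenerate inputs

* All hypergeometric tails go through `phyper(lower.tail = FALSE)`
  (log-space internals, stable to $10^{-300}$); $k_s = 0$ returns
  exactly 1. An exhaustive enumeration oracle checks all $N \le 25$ in
  the tests.
* BH adjustment is `p.adjust(method = "BH")`, checked against an
  independent step-up implementation.
* ComBat (via `sva`) is the default batch correction; a per-batch
  location-scale standardization mode exists for when the
  empirical-Bayes machinery is unwanted. Genes with zero variance
  inside a batch get a location-only adjustment with a warning; a batch
  with one sample is a hard error.
* Zero-variance genes in the Welch test get $p = 1$ (no evidence, not
  NaN). Constant-$\kappa$ clusters get $z = 0$ rather than NaN.
* Seeds missing from the interactome are dropped with a warning
  (expansion operates on the mapped subset); candidate-pool exhaustion
  truncates the ranking with a warning rather than failing.
* Gene symbols are taken verbatim (case-sensitive); nothing attempts
  to repair symbols, so a malformed seed symbol simply fails to map.

# Problem sizes

The shipped analyses and tests run at desk scale, chosen so the full
suite completes in a few minutes on one core: 600-gene interactomes
(~3,300 edges), 100 expansion iterations, 120-sample expression
matrices, 1,000 randomization replicates for headline module
significance and 200 for the 100-draw null-calibration study. All sizes
are ordinary function arguments; the machinery is the same at
interactome scale (13k nodes, 140k edges, 500 iterations), where the
expansion is the dominant cost and remains a few minutes.

# Known limitations

* The boundary criterion inherits the annotation collection: with a
  sparse or biased collection the seed-enrichment step can fail
  (hard error) or bound the list too early.
* LCC *size* is a weak statistic for small modules — degree-matched
  nulls of two dozen well-connected genes often assemble a sizeable
  component by chance, so its $p$ fluctuates near 0.05 at desk scale
  while the edge-count metrics separate sharply. On real interactomes
  the three metrics are reported together for this reason.
* k-means on correlation rows assumes roughly convex clusters in that
  space; community-detection alternatives are out of scope.
* The Welch test is unmoderated; with very few samples per group a
  variance-moderated test would be preferable, but the target designs
  (hundreds of samples) do not need it.
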