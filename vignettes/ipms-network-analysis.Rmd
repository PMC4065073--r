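---
title: "Network analysis of IP-MS hit lists: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network analysis of IP-MS hit lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipmsnet)
```

## The problem

An immuno-precipitation mass-spectrometry (IP-MS) screen pulls down a bait
protein together with cross-linked partners and identifies them from peptide
spectra. The result is a *hit list*: protein symbols, some of which are
genuine complex members and some nonspecific binders. `ipmsnet` evaluates
such a list against a background protein–protein interaction (PPI) network
compiled from literature resources, through four linked questions:

1. Do the hits interact with each other more densely than chance predicts?
2. Is that density explained by a few promiscuous hubs?
3. Do the hits organise into communities resembling protein complexes, and
   what functions are those communities enriched for?
4. Do two independent screens of the same bait overlap beyond chance?

## Data model and symbol namespace

All identifiers are *normalized symbols*: trimmed, upper-cased, internal
whitespace removed. This folds murine-style (`Myh9`) and human-style
(`MYH9`) spellings onto one namespace, which matches the common situation
where murine spectra are searched against a human sequence database and both
screens report in effectively human symbol space. Normalization is
idempotent; an explicit ortholog map (two-column TSV) can be supplied when
the namespaces genuinely differ, and is applied to the second hit list
before overlap testing.

The background network is an undirected *simple* graph: direction in source
files is ignored, self-loops are dropped, and duplicate reports collapse to
one edge whose `sources` records every contributing resource. Networks from
several resources merge by set union on nodes and edges. Identifier
reconciliation across resources is symbol-level only — accession-level
cross-referencing is out of scope and must happen upstream.

## Interaction-density significance

For hit set $S$ matched to the network, the observed statistic is the edge
count of the induced subgraph. The null is generated by drawing $n$ uniform
random node sets of size $|S|$ *without* degree matching, and the empirical
p-value uses the add-one convention

$$p = \frac{1 + \#\{\text{null counts} \ge \text{observed}\}}{n + 1},$$

whose smallest attainable value at $n = 10^5$ is just below $10^{-5}$ —
reported as $p < 10^{-5}$ when no null sample reaches the observed count.
The add-one form is never exactly zero and is super-uniform under the null
(verified by simulation in the test suite). Uniform (rather than
degree-matched) sampling is deliberate: hub effects are addressed
separately, by comparing the induced subnetwork's degree distribution to
the whole network's with a two-sample Kolmogorov–Smirnov test. The KS test
is distribution-free and needs no binning; the verdict string flags
"hub over-representation not detected" when $p > 0.05$.

Two parameters matter here:

* `n_samples` (default $10^5$) — resolution of the attainable minimum
  p-value; reduce for exploratory runs.
* `set_size_policy` (default `"matched"`) — random sets have the size of
  the *matched* hit set, since symbols absent from the background cannot
  contribute edges; `"total"` uses the full list size, which is more
  conservative when coverage is low.

## Community detection

Communities are found by greedy agglomerative modularity maximization.
With communities $i = 1..k$, modularity is

$$Q = \sum_i (e_{ii} - a_i^2),$$

where $e_{ii}$ is the fraction of edges with both endpoints in community
$i$ and $a_i$ the fraction of edge *ends* attached to it (degree sum over
$2m$). Each node starts as its own community; at every step the connected
pair with the largest merge gain $\Delta Q = 2(e_{ij} - a_i a_j)$ is merged,
and the maximum-$Q$ state along the path is returned with the full merge
history. Some descriptions render $a_i$ as the fraction of edges *leaving*
community $i$; we use the classical degree-fraction definition above, which
is the one consistent with $\Delta Q$ and with reference implementations.

Numerical and determinism choices:

* Ties in $\Delta Q$ (within $10^{-15}$) are broken by the lexicographically
  smallest community-index pair, making the algorithm seed-free and exactly
  reproducible.
* Only *connected* pairs are merge candidates — merging disconnected
  communities cannot increase $Q$ — so disconnected components never fuse
  and isolated nodes stay singletons.
* $Q$ is undefined for edgeless networks (error, not NA).
* The merge trace satisfies $Q_{t+1} = Q_t + \Delta Q_t$ to $10^{-9}$, and
  the returned partition always has $Q \ge \max(Q_{\text{singletons}},
  Q_{\text{one community}}) = \max(Q_0, 0)$.
* The implementation keeps a dense community-pair matrix, which is the right
  trade-off for hit-list-induced subnetworks (tens to a few thousand
  nodes); it is not intended for whole-interactome clustering.

`order_by_community()` sorts nodes by (community, degree descending,
symbol) and reports block boundaries, producing the community-ordered
adjacency matrix used for heatmap display.

Greedy agglomeration is a heuristic with known behaviours that the test
suite quantifies rather than hides: on small planted-partition benchmarks
its recovered partition can differ from the planted one exactly when the
*maximum-modularity* partition differs (the information limit of any
modularity method), and on denser scenarios it sometimes fuses two planted
modules through early merges and absorbs a few contaminants into a module's
community. The tests score greedy recovery against exact modularity
maximization (via integer programming on small graphs) and against the
planted truth; the adjusted Rand index (ARI) is computed, for each planted
module, between the binary partitions "module vs rest" and "best-overlap
community vs rest" over the induced subnetwork's nodes.

## Enrichment statistics

Enrichment of a query (hit list or community) against a GMT library term is
the one-sided Fisher exact test: with universe size $N$, term size $K$,
query size $s$ and overlap $k$, $p = P(X \ge k)$ for hypergeometric $X$.
Only enrichment is tested — screens report over-representation, not
depletion. P-values are Benjamini–Hochberg adjusted *within* one library
(terms of different libraries are not comparable hypotheses); raw p-values
are always emitted alongside.

The default universe is the library's own universe (union of its term
sets): it is the only background guaranteed consistent with the library's
annotation coverage, and it is overridable (`universe =`) for users with a
defined assay background. The cross-screen `overlap_test()` instead defaults
to `universe_size = 20000` — protein-coding-genome scale — because two
screens of the same proteome share that natural background; the value is
explicitly configurable and always reported with the result. Communities
smaller than `min_cluster_size` (default 3; a 2-node "community" can only
trivially overlap terms) are skipped with a notice. The disease lookup is
deliberately statistic-free: a membership table of which hits appear under
which disease term.

## What the synthetic generators emulate — and what they do not

The generators stand in for the real inputs (screen hit lists and a
literature PPI compendium) with known ground truth:

* `generate_background_network()` — Erdős–Rényi G(n, p) for a neutral
  background, or a Chung–Lu expected-degree graph with weights
  $w_i \propto (i + i_0)^{-1/(\gamma-1)}$ (default $\gamma = 2.5$) scaled to
  the requested mean degree for a heavy-tailed, hub-containing one. Chung–Lu
  was chosen over configuration-model stub matching because discarding
  multi-edges/self-loops biases realized degrees; the expected-degree form
  keeps the realized mean within 10% of the request for $n \ge 500$ (a
  tested contract).
* `generate_planted_partition()` — stochastic block model: within-community
  pairs edged with `p_in`, between with `p_out`. Chosen over LFR-style
  benchmarks because every property used in testing then has a closed-form
  expectation.
* `generate_hit_list()` — a planted module plus uniform contaminants
  (`contamination` = the fraction of the list that is noise). Contaminants
  are degree-uniform by design: the hub analysis is supposed to come out
  negative on clean synthetic data.
* `generate_two_species_lists()` — two lists sharing a planted core, with
  disjoint remainders, so intersection equals the core exactly.
* `generate_gmt()` — planted terms inserted verbatim among uniform decoys.

All generators are seed-deterministic and their output round-trips through
the package's file formats. What they do **not** emulate: peptide-level
identification noise, abundance-dependent detection, degree-biased
contamination (stubbed off by default), correlated annotation structure in
real GO/CORUM libraries, and the ascertainment bias of literature PPI
networks (well-studied proteins have more recorded edges). Passing the
synthetic suite therefore validates the *statistical machinery*, not the
biological fidelity of any particular real-data result.

## Study scenarios used by the tests and acceptance script

Problem sizes were fixed once, as representative of the application at desk
scale: the permutation-calibration scenario uses G(200, 0.05) with sets of
30 at $10^4$ samples; the community benchmark uses 3 planted communities of
10 ($p_{in} = 0.5$, $p_{out} = 0.02$) over 20 seeds; the end-to-end
pull-down re-enactment uses a 2000-node background at edge probability 0.01
with nine planted 15-node modules ($p_{in} = 0.5$), a 20%-contaminated hit
list of 169, and a 39-term library with the nine module terms planted,
over 10 seeds. The exhaustive modularity oracle enumerates every labelled
connected graph on 3–5 nodes plus seeded random graphs on 6–8 nodes,
comparing against brute-force maximization over all set partitions.

## Known limitations

* Greedy modularity has the resolution and early-merge pathologies shared
  by all CNM-family implementations (quantified above); no Louvain/Leiden
  or spectral alternatives are provided, by design.
* The dense merge matrix bounds community detection to subnetworks of a few
  thousand nodes.
* Symbol-level identity is the only cross-resource reconciliation.
* Edge lists cannot represent isolated nodes, so file round-trips are exact
  only for networks with minimum degree 1.
* Enrichment treats terms as independent within a library for BH purposes;
  hierarchical term structure (e.g. ontology ancestry) is not modelled.
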