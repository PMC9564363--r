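---
title: "From abundance profiles to hub genes: the papnet methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From abundance profiles to hub genes: the papnet methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(papnet)
library(dplyr)
```

papnet reimplements, as a tested and seeded pipeline, a network-based
analysis of differential proteomics data from mechanically bent poplar
taproots. The experimental design crosses three 5-cm root sectors — above
the bend (ABS), at the bend (BS) and below it (BBS) — with the two sides of
the bend, convex/tension (cx) and concave/compression (cv), giving the six
conditions returned by `pap_conditions()`. Sixty-six differentially
represented protein spots are carried through five computational stages:

1. abundance-profile normalization and k-means clustering with
   sector assignment;
2. high-confidence protein–protein interaction (PPI) filtering and
   first-neighbour subnetwork construction;
3. per-namespace GO enrichment with Bonferroni control;
4. REVIGO-style semantic redundancy reduction;
5. shared/specific term partitioning and Maximal Clique Centrality (MCC)
   hub ranking.

This vignette explains each model, its assumptions, the tunable parameters,
and the design decisions taken where the method description left choices
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Abundance profiles and clustering

Raw spot densities $x_i$ (arbitrary 2-DE units, strictly positive) are
normalized per protein to

$$X_i = \log_2\!\left(\frac{x_i}{\bar{x}_\text{protein}}\right),$$

where $\bar{x}_\text{protein}$ is the protein's mean density over the six
conditions. The resulting protein abundance profile (PAP) is scale-free —
multiplying a row by any positive constant leaves it unchanged — and
satisfies $\operatorname{mean}_i 2^{X_i} = 1$ exactly, which the suite
asserts to $10^{-9}$.

```{r}
normalize_abundance(tibble::tibble(
  protein = "spot1",
  `ABS-cx` = 8, `BS-cx` = 2, `BBS-cx` = 2,
  `ABS-cv` = 2, `BS-cv` = 2, `BBS-cv` = 2
))
```

PAPs are clustered by k-means (squared Euclidean distance, Lloyd
iterations). The reference analysis reports six clusters without
documenting how k was chosen, so `k = 6` is a configuration default, not a
fitted quantity. Because the tool originally used for clustering restarts
from random centers and is not reproducible, papnet prioritizes
determinism: k-means++ seeding, `n_init = 25` restarts keeping the lowest
total within-cluster sum of squares, nearest-centroid ties broken toward
the lowest cluster index, and clusters emptied during iteration reseeded
from the farthest point. Labels are re-indexed in decreasing size order so
they are stable across runs; the original I–VI labels are arbitrary.
`stats::kmeans` (Lloyd) started from the fitted centroids serves as an
independent cross-check of the objective in the test suite.

A cluster *characterizes* a sector/side when its centroid value reaches the
score threshold (default 0.3 log2 units) in that condition; a cluster may
characterize several conditions or none. On the package's built-in
reference centroid matrix this reproduces the published sector sets for
all six clusters:

```{r}
sector_sets(assign_sectors(reference_centroids(), threshold = 0.3))
```

Only sector-assigned clusters seed subnetworks; proteins in a never
assigned cluster keep their cluster membership but do not propagate
downstream.

## High-confidence PPI subnetworks

STRING-style combined scores are integers on the 0–1000 scale; the
conventional "high confidence" cut of 0.7 is implemented as
`combined_score >= 700` (boundary inclusive). Reading an edge list
canonicalizes it to a simple undirected graph: self-loops are dropped with
a warning and duplicate undirected pairs keep the *maximum* score, the
conservative choice with respect to the confidence filter.

A cluster-related subnetwork is the cluster's seed proteins plus their
first neighbours, with **all** parent-network edges among that node set
(the induced subgraph). The original description does not state whether
neighbour–neighbour edges were kept; papnet includes them, matching the
select-first-neighbours-then-create-subnetwork behaviour of interactive
network tools, and because MCC on star-only graphs would degenerate to
degree and make hub ranking uninformative. Seeds absent from the
interactome are recorded in the subnetwork's provenance rather than
silently dropped (identifier mapping losses are real but unquantified in
the source analysis); seeds present but isolated after filtering stay in
the node list and are excluded from hub ranking.

## GO enrichment

Annotations are closed over `is_a` ancestors (the true-path rule) before
testing. For a study set of $n$ genes from a background universe of $N$
genes, a term annotating $K$ background genes and $k$ study genes gets the
upper-tail hypergeometric probability

$$p = \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}.$$

Design decisions, each a documented assumption where the source left the
setting unstated:

* **Test family** = one subnetwork × one namespace; the three namespaces
  are reported separately per subnetwork, so Bonferroni's $m$ counts the
  terms tested in that family only.
* **Background universe** defaults to all genes with at least one
  propagated annotation in the namespace (the "annotated genes" default of
  common enrichment services); it is configurable.
* Only terms with $k \ge 1$ enter $m$, keeping $m$ reproducible from the
  data; namespace roots (always $K = N$) are excluded.
* `p_adj = min(1, m p)`; significance is `p_adj < alpha` with the
  degenerate threshold `alpha = 1` retaining every tested term (capped
  values equal 1 exactly and a strict inequality would otherwise discard
  them, contradicting the intent of a pass-through threshold).

Only `is_a` edges are honoured in the ontology; `part_of` and other
relationship types are counted and ignored. The OBO reader is a minimal
purpose-built 1.2 stanza parser covering exactly the fields this pipeline
consumes (id, name, namespace, is_a, is_obsolete).

## Semantic reduction

Redundant significant terms are collapsed per namespace with a
REVIGO-style greedy procedure at similarity cutoff 0.5 (stringent
grouping). papnet uses Lin similarity,

$$\mathrm{sim}(t_1,t_2) =
\frac{2\,\mathrm{IC}(\mathrm{MICA})}{\mathrm{IC}(t_1)+\mathrm{IC}(t_2)},
\qquad \mathrm{IC}(t) = -\ln p(t),$$

with $p(t)$ the propagated annotation frequency in the corpus and MICA the
common ancestor of maximal IC. Two deliberate departures from the original
web tool, whose exact configuration is unrecoverable: the similarity
measure is Lin rather than SimRel (the tool names only a cutoff, not a
measure; SimRel is left as an extension point), and the IC corpus is the
pipeline's own annotation set rather than an external association
database, keeping the artifact self-contained. The discard rule within a
merging pair is deterministic: larger adjusted p goes first, ties broken
toward the larger annotation frequency (the more general term), then the
lexicographically larger identifier. Equivalence with the original
reduced term lists is therefore not claimed; the invariants that are
enforced — survivors' pairwise similarity never exceeds the cutoff, output
never grows, identical input gives identical output — are asserted in the
suite.

## Term partitioning

Across the six per-subnetwork term sets (per namespace), a term occurring
in exactly one set is *subnetwork-specific*; in two or more, *shared*. The
conservation identity $\sum\text{specific} + \text{shared} =
\text{unique total}$ holds by construction and is asserted on every run.
Applied to the published subnetwork-specific GO identifier lists shipped
in `extdata`, the counting operations return 74 (BP), 49 (MF) and 33 (CC)
specific terms, and adding the published shared counts (91/28/26)
reproduces the published unique totals 165/77/59 — the same arithmetic the
acceptance script recomputes.

## Hub ranking by Maximal Clique Centrality

$$\mathrm{MCC}(v) = \sum_{C \in S(v)} (|C|-1)!$$

with $S(v)$ the maximal cliques containing $v$. When a node's neighbours
share no edges every maximal clique through it is a single edge and MCC
equals degree — asserted on verified triangle-free graphs. Maximal cliques
are enumerated completely (size ≥ 2, igraph's Bron–Kerbosch-family
implementation) and ordered deterministically; an exhaustive-subset oracle
checks the enumeration and the scores on hundreds of random graphs.
Scores are accumulated in double precision, which represents integers
exactly below $2^{53}$ — i.e. for maximal cliques up to size 19 — covering
the magnitudes (~$10^{13}$) seen in realistic PPI subnetworks; this
exactness domain is the package's stated numerical contract. Ranking ties
break by degree, then node identifier (the source shows three-way MCC
ties without stating a rule, so determinism is imposed here). The top
three nodes are the hub genes, and the pipeline reports — without
asserting, since it is data-dependent — whether they are pairwise
connected, i.e. form a triangle. MCC is always computed per subnetwork,
never on the global interactome, and ignores edge scores (topology only).

## The synthetic-data generator

Because the original spot table and the 2022 database releases are not
reproducible inputs, every downstream stage is validated against
synthetic data with *planted, recoverable structure*. The generator's
defaults are the study conditions themselves:

* **Abundance**: 66 proteins in six clusters of sizes 12/4/11/3/16/20,
  with the built-in reference centroid matrix as the planted cluster
  means. Rows are drawn in normalized log2 space as centroid + i.i.d.
  Gaussian noise, recentred so $\operatorname{mean} 2^X = 1$ holds exactly
  (the recentring constant is $\log_2 \operatorname{mean} 2^{c+\epsilon}$,
  small at the default noise), then back-transformed around a 1000-unit
  base level — guaranteeing positivity and making the normalization the
  exact inverse of the generator. The default `noise_sd = 0.3` log2 units
  is a realistic spot-density log-ratio spread; no distributional
  description of the real densities exists, so Gaussian-in-log2 is a
  stated assumption. Recovery tests use `noise_sd = 0.1`, where the
  minimum centroid separation (≈ 2.3 log2 units) exceeds ten times the
  noise and the adjusted Rand index of recovery is exactly 1.
* **PPI**: one designated hub per cluster sits in planted high-score
  cliques (default three cliques of size 5) that pairwise overlap *only*
  at the hub, so the hub's planted MCC is $\sum (\text{size}-1)!$ in
  closed form. Clique slots are filled round-robin with the cluster's
  seed proteins and padded with filler nodes, so every clique touches a
  seed and survives first-neighbour extraction. An Erdős–Rényi background
  (default probability 0.05 over background nodes and seeds) carries
  scores strictly below the confidence threshold, so the filter separates
  planted from background edges exactly. Evidence-channel score
  combination is not modelled — only the combined score.
* **GO**: per namespace, a layered `is_a` tree of depth 4 with a 0.2
  chance of a second parent (diamonds), genes annotated to leaves at
  baseline probability 0.05, and one leaf per (cluster, namespace)
  over-annotated at 0.9 among that cluster's subnetwork genes.

One integer seed drives all three components through deterministic
sub-streams, so adding one component does not shift another's draws and
identical configurations are byte-identical on disk. What the generator
does **not** emulate: 2-DE spot detection artefacts, missing values,
technical replicates, or STRING's evidence structure — so green recovery
tests demonstrate the correctness of the pipeline's logic, not the
recoverability of structure from real bent-root data.

## Problem sizes and runtime choices

The validation suite sizes its simulations for tight feedback: random
graphs on ≤ 8 nodes against the exhaustive-subset oracle (where $2^n$
enumeration is itself exact), exhaustive hypergeometric enumeration for
backgrounds up to $N = 12$, 200 no-signal corpora of 75 terms × 60 genes
for the family-wise error check, and 100 seeded replicates for hub and
planted-term recovery. These sizes were chosen as the smallest at which
the checked properties are non-trivial; all scale linearly in the obvious
way if enlarged.

## Known limitations

* Spot-to-interactome identifier mapping is out of scope: the pipeline
  requires pre-mapped protein identifiers and reports unmapped seeds per
  subnetwork instead of resolving them.
* The published enriched-term identities and hub-gene identities depend on
  specific database releases and are not reproduction targets; the
  package reproduces the *procedures* and the printed worked-example
  arithmetic.
* Bonferroni is the only multiple-testing correction offered, matching the
  source procedure; alternatives would change which terms reach the
  reduction stage.
* The reduction stage's agreement with any particular REVIGO run is not
  claimed (measure and tie-breaking differ; see above).

## A complete run

```{r, eval = FALSE}
run <- run_pipeline(pipeline_config(seed = 1))
run                      # stage counts
tidy(run$clustering)     # centroids, sizes, withinss
run$hubs[["1"]]          # MCC hub ranking of the largest cluster
autoplot(run$clustering) # profile panels per cluster
```
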