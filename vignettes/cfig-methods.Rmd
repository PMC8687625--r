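---
title: "Quantitative network pharmacology with cfig: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative network pharmacology with cfig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfig)
```

## The problem

Multi-herb preparations act through many ingredients hitting many protein
targets at once. Given (i) a table of candidate chemical ingredients with
ADME properties, (ii) predicted ingredient–target associations, (iii) a
disease gene set with literature evidence (report counts and relevance
scores), and (iv) a base protein–protein interactome, `cfig` asks two
questions:

1. **Which proteins carry the response?** Build the merged disease–target
   network, score every node with a betweenness-derived importance measure
   (*Nim*), and keep the high-importance subgraph — the *functional response
   space* (FRS). Its gene nodes are the *key response proteins*.
2. **Which small group of ingredients is sufficient?** Rank ingredients by
   their marginal contribution to covering the key response proteins (the
   *ICP* model) and cut the ranking at a coverage target. The selected,
   ordered set is the *critical functional ingredients group* (CFIG).

The package also ships a synthetic-study generator with *planted* critical
ingredients, so the full chain is testable against a known ground truth
without any database access.

## Pipeline stages and their models

### ADME admission

An ingredient passes the ADME rule when Caco-2 permeability is **strictly**
greater than −0.4 and drug-likeness (DL) is **at least** 0.18 — the
asymmetry (strict vs. inclusive) follows the rule as conventionally printed.
Compounds chemically detected in the preparation and reported in the
literature are whitelisted regardless of ADME values; the retained set is
the *union* of the two routes, so a literature compound with poor or missing
ADME values (several rows of the packaged reference tables have none) is
still admitted. A record missing either ADME value fails the ADME route:
absence of evidence for permeability is treated as failure, not as a pass.

### Weighted disease network

Evidence genes are mapped onto the base interactome; unmappable genes are
reported, not silently dropped. Each mapped gene's weight is

> degree in the induced disease subgraph × relevance score × report count.

A missing relevance score or a zero report count is replaced by 1, the
multiplicative identity, so one missing evidence channel never annihilates
the weight. The weight is reported per node (it is the reading aid for the
network) but deliberately does **not** enter the importance score, which is
purely topological; conflating literature visibility with topological
position would double-count the hub bias already present in curated
evidence.

### Merged disease–target network

The merge is the node and edge union of the disease network and the
bipartite ingredient–target network, with gene nodes merged by identifier
(disease weights win) and ingredient nodes kept with their own role. When
the base interactome is supplied, its edges among **all** mapped genes are
retained — also between target genes outside the disease set. Without this,
non-disease targets dangle off ingredient nodes alone, ingredient nodes
become the only bridges, and the importance ranking degenerates into a
ranking of ingredient target counts.

### Node importance (Nim)

For a node $s$ in a network with node set $U$ and community $C(s)$:

$$
\mathrm{Nim}(s) \;=\;
\underbrace{\sum_{a \ne b \ne s} \frac{\sigma_{ab}(s)}{\sigma_{ab}}}_{\text{betweenness term}}
\times
\underbrace{\left[
  \frac{|C(s)|}{|U|} \cdot
  \frac{\sum_{w \in C(s),\, w \ne s} \bigl(\Delta_s + 1 - d(s,w)\bigr)}{\max_{w \in C(s)} d(s,w)}
\right]^2}_{\text{community-proximity factor}}
$$

where $\sigma_{ab}$ counts shortest $a$–$b$ paths, $\sigma_{ab}(s)$ those
through $s$, $d(\cdot,\cdot)$ is the shortest-path distance, and
$\Delta_s = \max_{w \in C(s)} d(s,w)$ is the eccentricity of $s$ within its
community. The betweenness term rewards brokers; the squared factor rewards
nodes close to many members of a large community.

Interpretation choices made here, stated openly because the formula leaves
them open:

* **$C(s)$ is the connected component of $s$** by default (Louvain
  modularity communities are available as an option). The distance terms
  require reachability, and components are the only parameter-free total
  assignment with that property. Distances across communities would be
  infinite, so such terms are excluded by construction.
* **$w$ ranges over $C(s) \setminus \{s\}$**: including $s$ itself would add
  a constant $\Delta_s + 1$ that the structure of the sum does not motivate.
* **$\Delta_s$ is the within-community eccentricity of $s$.** The quantity
  it stands for ("the maximum distance … passing through the node") has no
  direct graph-theoretic reading; eccentricity is the closest well-defined
  one.
* **Unordered pairs** in the betweenness term (the network is undirected);
  pairs in different components are skipped.
* A node whose community contains no other reachable member gets factor 0.

Worked examples (verified in the tests by exhaustive path enumeration): the
center of a 3-path scores $1 \times [(3/3) \cdot 2/1]^2 = 4$; the center of
a 4-star scores $6 \times [(5/5)\cdot 4/1]^2 = 96$; every leaf scores 0.

The betweenness term is computed by Brandes accumulation written in the
package and is cross-checked in the test suite against two independent
routes: explicit enumeration of all shortest paths (every connected graph
on ≤ 5 nodes in all labelings, all 112 isomorphism classes on 6 nodes,
random graphs on 7–8), and the reference implementation in `igraph`.

### FRS threshold

The literal selection rule is the **midpoint** of the score range,
$(\min + \max)/2$, and that is the default of `select_frs()`. On a
heavy-tailed score, however, the midpoint keeps only the few most extreme
hubs, whereas the verbal form of the rule — keep nodes above the *average*
importance — and the roughly half-and-half splits seen in practice point to
a central threshold. Both readings are provided (`mean`, `median`) and the
choice is surfaced as an explicit argument, never resolved silently. Ties
at the threshold are kept (≥). All three modes keep at least one node on
any nonempty input; all-equal scores keep everything.

Kept gene nodes are subtyped: in both the disease set and the target set →
*essential common*; disease only → *disease-specific*; targets only →
*ingredient-specific*. A kept gene in neither set is labelled
ingredient-specific only when it is reachable from an ingredient node,
otherwise it is flagged with a warning.

### Enrichment and the three indicators

Term enrichment is the exact hypergeometric upper tail
$P(X \ge k)$ with the term clipped to the background; significance is
strict ($p < \alpha$, default $\alpha = 0.05$) on **raw** p-values —
no multiple-testing correction by default, since the validation compares
two enrichment runs under the same regime rather than making per-term
claims; Benjamini–Hochberg is available by flag. The background defaults to
the gene nodes of the merged network: the least arbitrary closed universe,
and configurable.

The FRS is validated against the *un-optimized effective targets* (UET),
the plain intersection of disease genes and ingredient targets, with three
indicators: (1) the fraction of UETs among the key response proteins;
(2, 3) the fraction of UET-enriched terms recovered by key-protein-enriched
terms, for a pathway-like and a GO-like collection. At the scale of the
packaged synthetic studies (25 terms) the term-based indicators are noisy —
with only a handful of significant reference terms a single miss moves the
indicator by tens of percentage points — so they are reported but the
structural claims rest on the gene-level indicator and the planted-recovery
benchmark.

### ICP selection

The selection is **marginal-gain greedy**: starting from the candidates
sorted by descending raw target count, repeatedly pick the ingredient
adding the most *uncovered* key response proteins, stopping at the coverage
target (default 0.90) or when no ingredient adds anything. Ties break by
higher raw target count, then lexicographic identifier, so the selection is
deterministic. This is the central interpretive decision of the module: a
pure target-count ranking is observably wrong (an ingredient whose targets
duplicate an earlier pick contributes nothing and is skipped even when its
raw count is high), while greedy marginal coverage reproduces exactly that
behaviour and carries the classical $(1 - 1/e)$ worst-case guarantee
against the optimal same-size selection — verified in the tests against the
exhaustively enumerated optimum on instances of up to 12 ingredients.

## The synthetic-study generator

`generate_study()` draws a complete study from one seeded RNG stream:

* **Base interactome**: preferential attachment (3 edges per new node,
  200 genes by default), reproducing the hub-dominated degree structure of
  curated PPI networks (the tests assert max degree ≥ 3× median).
* **Disease module** (60 genes): the top quarter of the module is the top
  of the degree distribution outright, the rest a degree-squared-weighted
  sample. This encodes two facts about curated disease sets in inflammatory
  disease: evidence accrues preferentially to well-connected genes, and the
  interactome's principal hubs are themselves pathogenetic.
* **Evidence**: report counts are a shifted negative binomial (most genes
  1–2 reports, a long tail with many), relevance scores log-normal.
* **Ingredients** (30, of which 5 planted critical): each planted
  ingredient owns an exclusive slice of a module core that jointly covers
  ≥ 90% of the module, plus a generic tail; decoys draw uniformly from all
  genes. Target-set sizes are Poisson with mean 8 — about 4% of the gene
  universe, the same per-ingredient density as real ingredient–target
  networks (tens of targets against a universe of a thousand-plus). About
  30% of decoys are drawn to fail the ADME filter; planted ingredients
  always pass it.
* **Annotations**: 25 terms of 3–15 genes from 2-step network
  neighborhoods, half centered inside the module.

Earlier drafts of the generator used a denser ingredient layer (35 targets
per ingredient against 200 genes); that makes the ingredient–target edges a
multiple of their real share of the merged network, and gene centrality is
then an artifact of which genes happen to be targeted. The final defaults
keep the *proportions* of the full-size setting rather than its absolute
counts.

What the generator does **not** emulate: correlated target prediction
errors across databases, herb-level pharmacological families, edge
confidence scores, directionality of regulation, and annotation-term
overlap structure. Passing the planted-recovery benchmark therefore shows
that the chain recovers a planted coverage structure under realistic
density and skew — not that it would rank real ingredients correctly under
real prediction noise.

## The recovery benchmark

`planted_recovery_benchmark()` runs the whole chain on 20 independent
studies and scores (a) the fraction of planted ingredients among the first
five picks and (b) whether the module's top-3 hubs reach the top decile of
gene importance. Two harness choices, fixed with the study conditions:

* the FRS step uses the **mean** threshold — the key-protein space must be
  large enough that several ingredients are needed to cover it, and on a
  heavy-tailed score the mean keeps the informative upper tail while the
  midpoint collapses to a handful of extreme hubs;
* ICP runs to exhaustion (`coverage_target = 1`) so the greedy trace is
  long enough to score five picks;
* the hub-decile rank is computed among gene nodes: ingredient nodes score
  on a different scale of the importance measure (they are pure brokers),
  and the claim is about proteins.

## Numerical and degenerate-input choices

* Networks are simple and undirected throughout: self-loops dropped (with a
  warning at I/O), duplicate edges in either orientation collapsed,
  canonical `from ≤ to` storage for deterministic output files.
* Gene symbols are normalized at every I/O boundary: Greek letters
  transliterated via a packaged mapping table, upper-cased, hyphens
  stripped (`IL-1β` → `IL1B`). Purely syntactic; no alias resolution.
* `—`, `–`, `-`, `""`, and `NA` all parse as missing in numeric columns.
* Empty query or background in `enrich()`, an empty Nim table, an empty
  key-protein set, or an empty planted set are errors; an empty *reference*
  coverage set yields coverage 0 with a warning; an unreachable ICP
  coverage target returns all positive-gain picks with an `unreachable`
  flag rather than failing.
* All tabular outputs are plain TSV; the run report is JSON and its counts
  are re-derived from the written intermediates before the report is
  written (a failed cross-check aborts the run).
* Problem sizes used by the shipped analyses and tests — 200-gene studies,
  20-seed benchmarks, exhaustive oracles up to 6-node graphs, 15-gene
  enrichment backgrounds, 12-ingredient exhaustive optima — were chosen so
  each oracle remains exactly enumerable.

## Known limitations

* The importance score is defined for unweighted shortest paths; edge
  confidences are out of scope.
* Activation vs. inhibition is ignored: the network is undirected, so the
  selection can cover a protein with an ingredient that regulates it in the
  "wrong" direction.
* The greedy ICP selection is a heuristic; the $(1-1/e)$ bound is its
  worst case, and the optimal fixed-size group is NP-hard to compute in
  general (the tests enumerate it only at toy scale).
* Dose is not modelled: an ingredient counts as covering a target
  regardless of the concentration needed to engage it.
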