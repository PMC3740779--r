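---
title: "Mining hidden key molecules: the model behind keyminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining hidden key molecules: the model behind keyminer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keyminer)
```

## The problem

Pathway and interaction databases describe tens of thousands of
relationships among genes and proteins, but a typical experiment hands
you only a short gene list: the ligands and transcription factors of a
pathway, or the genes somatically mutated in a tumour cohort. The
molecules that *relay* information between those genes — receptors,
adaptors, scaffolds — are often not on the list at all, and they are
easy to miss precisely because they have far fewer interaction partners
than the famous hubs (TP53, EGFR, ...) that dominate any global
centrality ranking. `keyminer` looks for these **hidden key molecules**:
nodes that are statistically central *to the input set's shortest-path
traffic*, regardless of how peripheral they are globally.

## Background network construction

The input is a tab-separated table of binary interactions annotated
with the source databases that report each one (the dialect of an
aggregated pathway-resource export). `build_network()` collapses the
records into a simple, undirected, unweighted graph, keeping a gene
pair only when the **union of distinct source databases** across all of
its records reaches `min_sources` (default 2). Counting distinct
databases rather than records matters: the same database listed twice
is still one piece of evidence. Requiring two independent sources
removes the promiscuous mega-nodes that aggregation artefacts create
and restores a clean power-law degree distribution. Self-interactions
(e.g. multimer records) are pruned, redundant records collapse to
single edges, and `largest_component()` discards the tiny disconnected
fragments, with a deterministic tie-break (the component containing
the lexicographically smallest symbol) for the degenerate equal-size
case that real networks never hit but tests must pin down.

Interaction direction and type play no role in the graph itself — the
model is undirected and unweighted — but the type is carried along as
an edge annotation for the Cytoscape export.

## Node-limited betweenness centrality

Let $G=(V,E)$ be the background network, $U \subseteq V$ the mapped
input genes with positive weights $w(x)$, $\sigma_{st}$ the number of
shortest paths between $s$ and $t$, and $\sigma_{st}(v)$ those passing
through $v$ as an interior node ($v \ne s,t$). Then

$$
\mathrm{nlBC}(v) \;=\; \frac{1}{w} \sum_{\{s,t\} \subseteq U,\, s\neq t}
 \bigl(w(s)+w(t)\bigr)\,\frac{\sigma_{st}(v)}{\sigma_{st}},
\qquad
w \;=\; \sum_{\{s,t\}} \bigl(w(s)+w(t)\bigr).
$$

Compared with classical betweenness, the sum runs only over pairs of
*input* nodes, so shortest paths concentrated on hubs unrelated to the
inputs contribute nothing; and each pair's contribution is weighted by
the sum of its endpoint weights, so e.g. mutation frequencies can tilt
the ranking toward the neighbourhood of heavily mutated genes.

Design choices worth making explicit:

* **Interior-only counting.** The endpoint condition $s \ne v \ne t$ of
  classical betweenness is kept: an input node scores only through
  paths between *other* input pairs. Counting endpoints themselves
  would push every input node's value toward 1 and destroy the
  ranking.
* **Unordered pairs.** On an undirected graph the ordered sum is
  exactly twice the unordered sum in both numerator and normalizer, so
  the value is identical; unordered is the canonical contract and the
  implementation divides the ordered accumulation by the ordered
  normalizer $2(|U|-1)\sum_x w(x)$.
* **Range and invariances.** $0 \le \mathrm{nlBC}(v) \le 1$, with 1
  reached only by a node interior to every shortest path of every
  input pair; rescaling all weights by a common factor cancels. With
  uniform weights the statistic reduces to the pair-averaged
  restricted betweenness, and with $U=V$ it reduces to
  $BC(v)/\binom{|V|}{2}$ — both are exercised as tests.
* **Disconnected pairs.** If two mapped inputs have no connecting path
  (possible only on a disconnected graph), the pair contributes 0 to
  the numerator while its weight term still counts in $w$. The default
  pipeline works on the largest component, where the case cannot
  arise.
* **Input symbols absent from the network** are dropped with a warning
  and recorded, not treated as errors: real gene lists always contain
  unmapped symbols.

### Algorithm

`compute_nlbc()` runs one BFS plus backward dependency accumulation
per input source (the single-source scheme that avoids enumerating
paths), carrying two dependencies at once — the unweighted one and the
target-weight-carrying one — combined as
$w(s)\,\delta^1_s(v) + \delta^w_s(v)$ and summed over sources. The
accumulation is $O(|U|\,(|V|+|E|))$ and implemented in C++; path
counts are exact (integers represented in doubles, exact below
$2^{53}$), the dependency sums are floating point.
`brute_force_nlbc()` is the deliberately independent oracle: it
enumerates every shortest path of every input pair over the BFS
predecessor DAG in pure R and accumulates the defining sum literally.
The two routes agree to $10^{-12}$ on hundreds of random graphs; the
oracle is guarded to small networks because path enumeration grows
exponentially.

## Simulated p-values

A large nlBC value is not significant per se — nodes near any gene set
pick up some traffic. `simulate_null()` recomputes the centrality for
`n` random input sets of the same size as $U$, sampled uniformly
without replacement from all network nodes, with the original multiset
of weights mapped onto each sample in random order (the paper-style
permutation null; no degree matching, since nothing in the sampling
model conditions on degree). For each node the replicate values form
its own empirical null distribution, and

$$ P_v = \frac{r+1}{n+1}, $$

where $r$ counts replicates whose value reached the observed one. The
add-one estimator is never 0; the smallest attainable value is
$1/(n+1)$ — about $5.0\times10^{-5}$ at the default $n=20{,}000$. Only
nodes with observed nlBC $>0$ are *tracked* (their counters updated
streamingly, memory staying flat unless `keep_null_samples = TRUE`
retains the replicate values for diagnostic boxplots); every other
node has $P_v = 1$ by construction, because a replicate value of 0
always ties an observed 0.

**Calibration and the tracking selection effect.** Each $P_v$ is a
valid Monte-Carlo p-value: with a *random* input set (the null being
true), the fraction of all assessed nodes reaching $P_v < 0.05$ sits
at 0.05, and the acceptance suite verifies this. Note that the
fraction computed over tracked nodes only is much larger (roughly
$0.05 / \Pr(\mathrm{nlBC}>0)$): conditioning on a positive observed
value selects the upper tail of each node's null distribution. That is
a property of any valid p-value under selection, not an inflation of
the test — the denominator for calibration must include the $P_v=1$
nodes.

Reproducibility: every replicate's node sample and weight permutation
is pre-drawn from the single user seed in a fixed order, so a given
(network, gene list, `n`, seed) fixes every p-value bit for bit, and
the C++ loop's execution order cannot change the result.

No multiple-testing correction is applied; results are thresholded on
the raw simulated p-values (strictly below `alpha`, default 0.05), and
the result table reports each node's degree in the *background*
network — degree in the extracted subgraph would understate how busy a
node really is.

## Subgraph extraction and visualization

`extract_subgraph()` returns $H$, the union of all shortest paths
between all input pairs — exactly the nodes eligible for nonzero nlBC
plus the input endpoints that anchor the paths. It is computed by
walking each source's BFS predecessor DAG backward from every
reachable input target, which collects the shortest-path edge set in
linear time without enumerating paths; $H$ is invariant to the input
weights. `export_cytoscape()` writes $H$ as a SIF file plus three
plain-text node-attribute files (simulated p-value, input weight with
0 marking non-inputs, nlBC) in the one-attribute-per-file Cytoscape
2.x format. Layout and rendering are Cytoscape's job.

## The synthetic fixture

No pinned release of the original interaction aggregate is shipped or
downloaded; instead `synthetic_pathway_spec()` and friends generate
data with the structure the method assumes, so every claim the test
suite makes is recomputable from code:

* a **preferential-attachment background** (default 1000 nodes, 3
  edges per node) — connected and heavy-tailed like a source-filtered
  pathway aggregate; every synthetic record carries two source names
  so the default filter keeps it;
* a **planted motif** mirroring a receptor-tyrosine-kinase pathway's
  geometry at the scale of the original validation: 10 ligands and 30
  transcription factors as the input list, 4 receptors as the hidden
  keys. Ligands attach only to their (round-robin) receptor; receptors
  bridge to a random half of the transcription factors — chosen among
  the highest-degree background nodes so ligand-to-TF paths must cross
  the planted bridges into a realistic hub tangle — plus 3 random
  background nodes each, keeping receptor degree (~20) well below hub
  degree (~60+).

All randomness flows from the spec's single seed. What the fixture
does *not* emulate: real mutation-frequency weight distributions,
identifier noise, and the literature biases of curated interactions —
so passing tests demonstrate the algorithmic properties (recovery,
calibration, hub avoidance), not fidelity to any particular biological
release.

Problem sizes used by the checks were chosen so the full suite
recomputes everything from scratch in a few minutes: oracle agreement
on 200 random graphs of up to 30 nodes; calibration with 20 random
input sets at 1000 replicates on a 300-node background; recovery over
20 generator seeds at 1000 replicates on the default 1000-node
fixture. The default `nsim = 20000` matches the method's intended
production setting and is exercised once end to end.

## Known limitations

* Shortest paths are hop counts; confidence- or affinity-weighted
  edges are out of scope, as are directed interactions.
* The null samples nodes uniformly; a degree-preserving null would ask
  a different (harsher) question and is a possible extension, not
  implemented.
* When the same gene pair appears with different interaction types in
  different sources, sources are pooled across types when counting
  support; the types are concatenated in the edge annotation.
* Path counts $\sigma_{st}$ overflow double precision only on graphs
  far larger and denser than the intended use; no big-integer
  arithmetic is attempted.
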