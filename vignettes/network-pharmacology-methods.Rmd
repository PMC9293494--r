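---
title: "Methods: network pharmacology screening with herbnetpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network pharmacology screening with herbnetpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnetpharm)
```

## The analysis model

`herbnetpharm` implements the standard herb–compound–target workflow of
network pharmacology. The analysis proceeds through five stages, each of
which is an exported function family so any stage can be run alone:

1. an **activity (ADME) screen** on the compound table,
2. **network construction** (compound–target bipartite network; induced
   PPI subnetworks; the merged compound/disease network),
3. a **key-target screen** on six topological centrality measures,
4. **dense-module detection** (MCODE),
5. **over-representation analysis** of the key targets.

The pipeline makes two structural assumptions throughout: interactions
are **undirected and unweighted** (the curated PPI sources feeding such
studies carry no direction that the downstream statistics would use), and
gene identity is **symbol-based** — uppercase, trimmed, optionally mapped
through a user-supplied alias table. A full identifier service is out of
scope by design; symbol canonicalization is deterministic and offline,
which we consider more valuable for reproducibility than best-effort
remote lookups.

## Activity screen

A compound is active when OB ≥ `ob_min` (percent, default 30) **and**
DL ≥ `dl_min` (dimensionless, default 0.18). Both comparisons are
inclusive by default: known active herbal ingredients sit very close to
these boundaries (the packaged *Cassiae semen* table contains quinizarin
at DL 0.19 and aurantio-obtusin at OB 31.55), so an exclusive reading
would silently drop borderline literature compounds. Compounds that pass
the screen but have no target associations stay in the *active* list and
are reported separately (`compounds_without_targets`); they simply
contribute no edges.

## Network construction

`induced_ppi_subgraph()` restricts a background interactome to a seed
set, keeping exactly the seed–seed edges; no neighbour expansion is
performed. Expansion through first-shell interactors (as some Cytoscape
plugins do) multiplies the network size by database-dependent factors and
makes results a function of the snapshot rather than of the seed
biology; seed-only induction is the conservative, reproducible choice.
Nodes without any connection are removed by default, matching the usual
practice of drawing disease PPI networks "after removing nodes without
any connection"; the flag `drop_isolated = FALSE` keeps them.

## The six-measure key-target screen

For every node the pipeline computes degree (DC), closeness (CC),
betweenness (BC), eigenvector (EC), local average connectivity (LAC) and
edge-clustering network centrality (NC); a node is a **key target** when
it exceeds the arithmetic mean of *every* measure (strict `>`; a `>=`
variant is available). The AND-rule over six heterogeneous measures is
deliberately stringent — on vertex-transitive graphs (cliques, stars with
respect to LAC) it correctly returns an empty set.

Numerical conventions, chosen to match the CytoNCA family of tools:

* **CC** is component-restricted: `cc(v) = (|C_v|−1) / Σ d(v,u)` over
  `v`'s component, 0 for isolates. Means are taken over all nodes of the
  screened (isolate-free) graph.
* **BC** is unnormalized, each unordered pair counted once, computed by
  Brandes' O(VE) accumulation. Normalization is a reporting option only;
  the screen compares each measure to its own mean, so any per-measure
  positive rescaling leaves the key set unchanged (asserted as a test).
* **EC** is the principal eigenvector of the adjacency matrix,
  L2-normalized, from power iteration with tolerance 1e-10 and cap
  10,000. Plain power iteration does not converge on bipartite graphs
  (their spectrum is symmetric, so the iterate oscillates between the
  two sides); we therefore iterate on **A + I**, which has the same
  principal eigenvector but a strictly dominant eigenvalue.
  Non-convergence is flagged on the result and warned about, never
  silent.
* **LAC** `= 2·e(N(v))/|N(v)|` and **NC** `= Σ ECC(u,v)` with
  `ECC(u,v) = z_uv / min(d_u−1, d_v−1)`; when the denominator is 0 (a
  degree-1 endpoint) the edge contributes 0, the usual convention for
  this statistic.

The screen is applied once; no iterative re-screening of the central
network is performed.

## Module detection

`mcode_find_modules()` follows the original MCODE scheme: each node is
weighted by `k × density` of the highest k-core of its closed
neighbourhood; seeds are taken in decreasing weight (ties by id, for
reproducibility) and expanded breadth-first through unassigned neighbours
whose weight is at least `(1 − vwp)` of the seed's. Defaults are the
published tool defaults (`vwp = 0.2`, haircut on, fluff off,
`min_size = 3`), since studies using the Cytoscape plugin rarely report
changing them. Haircut is implemented as the module's 2-core. The module
score is `density × n` with the simple-graph density `2E/(n(n−1))` — the
only definition under which a 6-node module missing a single edge scores
5.60, the canonical printed value this statistic is checked against:

```{r score}
k6 <- interaction_graph(edges = t(combn(paste0("N", 1:6), 2)))
g <- interaction_graph(nodes = k6$nodes, edges = k6$edges[-1, ])
module_score(g, g$nodes)
```

## Enrichment

`enrich_gene_set()` is a one-sided hypergeometric over-representation
test, evaluated in log space via `lchoose()` so genome-scale counts do
not overflow. The universe defaults to the union of annotated genes in
the collection — the only background derivable offline — and an explicit
universe is supported. The EASE variant (overlap `k − 1`), the default
statistic of the DAVID service, is provided as an option; the plain tail
is the package default because it is exactly testable against
combinatorics. Selection follows the common reporting rule: raw
p < 0.05 strictly, then the top 10 (GO) or top 20 (pathways) terms.
Benjamini–Hochberg adjustment is computed and reported but does not
drive selection unless requested, mirroring how such studies report raw
p-values.

## The synthetic-data generators

Because the upstream databases (compound catalogues, disease gene
portals, interactome aggregates) are commercial or versioned web
services, the package tests itself on generated data with planted ground
truth. `simulate_study()` emulates:

* **Compounds** (default n = 30): OB ~ Normal(35, 12) truncated at 0,
  DL ~ Beta(2, 5). Both distributions straddle the activity thresholds,
  so a screen on simulated data exercises all four pass/fail outcomes;
  the true active set is computed analytically from the drawn values.
* **Interactome** (default 250 backbone genes): preferential attachment
  with `attach_m = 3`. A heavy-tailed degree distribution is essential
  here — in a uniform random graph almost no node beats the mean on all
  six measures and the key-target screen would be vacuous.
* **Hubs** (default 5 nodes, 30 extra edges each): partners drawn half
  uniformly, half proportionally to current degree. Pure
  degree-proportional wiring welds the top of the degree distribution
  into a single dense cluster that can out-score the planted module;
  pure uniform wiring leaves hubs with so few triangles that their LAC
  and NC stay near the graph mean. The mixture gives hubs the triangle
  structure of real hub proteins while keeping the planted module the
  densest object in the graph.
* **Module** (default 6 nodes at density 14/15, i.e. score 5.60): fresh
  genes wired among themselves to the target density, each attached to
  the backbone by at most one edge (so haircut can separate it cleanly).
* **Annotations** (default 50 terms): one planted term containing the
  hub and module genes padded to 15, the rest uniform draws of 10–40
  genes.
* **Disease list** (default 60 genes): the planted module and hubs, a
  30 % overlap share drawn from the compound-target pool, and random
  backbone genes.

All generators are pure functions of the integer seed (one master seed,
fixed per-stream offsets), so partial re-runs and end-to-end runs are
byte-reproducible. These defaults are study conditions, not tuning
knobs: the recovery tests (hub sensitivity, module Jaccard, planted-term
rank over 20 seeds) are run at exactly these values.

What the simulation does **not** emulate: realistic chemistry (no
structures, no docking), database-specific record formats, literature
bias in target annotation, and the correlated noise of real curation.
Passing the recovery tests shows the algorithms detect the structures
they are defined to detect — it does not validate any biological claim
about a real herb.

## Problem sizes and degenerate inputs

Test and simulation sizes (250-gene interactomes, 20-seed recovery
loops, ≤ 8-node oracle graphs) were chosen so the whole suite runs in
well under a minute on one core while still giving the property checks
real resolution; all algorithms are written for graphs of a few thousand
nodes at most, the scale of merged target networks in practice.
Degenerate inputs are defined, not errors, wherever a convention exists:
empty key sets, empty module lists on edgeless graphs, `ECC = 0` at
degree-1 endpoints, closeness 0 for isolates, `p = 1` at overlap 0.
Errors are reserved for contract violations: eigenvector centrality on
an edgeless graph, modules of fewer than two nodes, hypergeometric
parameters out of range, empty seed sets.

## Known limitations

* Gene symbol canonicalization cannot resolve true synonym conflicts
  without an alias table; two symbols for one protein stay two nodes.
* The key-target screen's strict AND-rule is sensitive to the network's
  degree heterogeneity; on near-regular graphs it returns few or no
  nodes (by design, but worth knowing).
* MCODE results depend on deterministic tie-breaking by node id; a
  relabelled isomorphic graph can yield a different (equally valid)
  module assignment when weights tie exactly.
* The enrichment universe is the annotated union unless supplied;
  p-values are therefore conditional on the collection, as with any
  offline over-representation analysis.
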